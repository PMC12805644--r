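#' Summarize a multi-seed benchmark
#'
#' @param results Tibble from [run_benchmark()].
#' @return A one-row tibble with the mean test metric per method, the mean
#'   selected omega/epoch, and the fraction of replicates whose selected
#'   omega lies strictly inside (0, 1).
#' @export
summarize_benchmark <- function(results) {
  results |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      dplyr::across(c("single_aux", "single_tgt", "combined", "transfer",
                      "omega", "epoch"), mean),
      omega_interior = mean(.data$omega > 0 & .data$omega < 1))
}
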