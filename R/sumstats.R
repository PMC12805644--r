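# GWAS summary statistics live in plain tibbles with columns
# snp_id, chrom, pos_bp, effect_allele, other_allele, beta (per standardized
# genotype unit), and optionally se, p_value, n_gwas. Cohort-level fields
# (ancestry label, case/control counts, harmonization status) ride along as
# attributes so dplyr verbs keep working on the rows.

#' Construct a summary-statistics table
#'
#' @param x Data frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`; `chrom`, `pos_bp`, `se`, `p_value`, `n_gwas`
#'   are carried when present.
#' @param ancestry Ancestry label for the cohort.
#' @param n_cases,n_controls Case/control counts for binary-trait GWAS
#'   (`NA` for quantitative traits).
#' @param aligned Logical; whether effect alleles are already harmonized to
#'   a genotype panel.
#' @return A tibble of class `sumstats`.
#' @export
sumstats <- function(x, ancestry = "unknown", n_cases = NA_integer_,
                     n_controls = NA_integer_, aligned = FALSE) {
  x <- tibble::as_tibble(x)
  req <- c("snp_id", "effect_allele", "other_allele", "beta")
  if (!all(req %in% names(x))) {
    stop("summary statistics need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$snp_id)) stop("duplicate snp ids", call. = FALSE)
  if (any(!is.finite(x$beta))) stop("non-finite beta values", call. = FALSE)
  if ("p_value" %in% names(x)) {
    bad <- !is.na(x$p_value) & (x$p_value < 0 | x$p_value > 1)
    if (any(bad)) stop("p-values outside [0, 1]", call. = FALSE)
  }
  structure(x, class = c("sumstats", class(x)),
            ancestry = ancestry, n_cases = n_cases, n_controls = n_controls,
            aligned = isTRUE(aligned))
}

#' Read summary statistics from a tab-separated file
#'
#' Expects the header columns `SNP`, `CHR`, `BP`, `A1`, `A2`, `BETA` and
#' optionally `SE`, `P`, `N` (`A1` is the effect allele).
#'
#' @param path File path.
#' @inheritParams sumstats
#' @return A `sumstats` tibble.
#' @export
read_sumstats <- function(path, ancestry = "unknown", n_cases = NA_integer_,
                          n_controls = NA_integer_) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "BETA")
  if (!all(need %in% names(d))) {
    stop("missing required columns in ", path, ": ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    snp_id = as.character(d$SNP),
    chrom = if ("CHR" %in% names(d)) as.character(d$CHR) else NA_character_,
    pos_bp = if ("BP" %in% names(d)) as.integer(d$BP) else NA_integer_,
    effect_allele = toupper(d$A1), other_allele = toupper(d$A2),
    beta = as.numeric(d$BETA))
  if ("SE" %in% names(d)) out$se <- as.numeric(d$SE)
  if ("P" %in% names(d)) out$p_value <- as.numeric(d$P)
  if ("N" %in% names(d)) out$n_gwas <- as.integer(d$N)
  aligned <- "ALIGNED" %in% names(d) && all(d$ALIGNED %in% c(1, "1", TRUE, "TRUE"))
  sumstats(out, ancestry = ancestry, n_cases = n_cases,
           n_controls = n_controls, aligned = aligned)
}

#' Write summary statistics as a tab-separated file
#'
#' @param stats A `sumstats` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(stats, path) {
  d <- data.frame(SNP = stats$snp_id,
                  CHR = if ("chrom" %in% names(stats)) stats$chrom else NA,
                  BP = if ("pos_bp" %in% names(stats)) stats$pos_bp else NA,
                  A1 = stats$effect_allele, A2 = stats$other_allele,
                  BETA = stats$beta)
  for (nm in c("se", "p_value", "n_gwas")) {
    if (nm %in% names(stats)) d[[c(se = "SE", p_value = "P", n_gwas = "N")[nm]]] <- stats[[nm]]
  }
  if (isTRUE(attr(stats, "aligned"))) d$ALIGNED <- 1L
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize summary statistics to a genotype panel's reference alleles
#'
#' Aligns each summary-statistic row to the effect allele of the matching
#' SNP in the genotype panel: identical allele pairs are kept, swapped
#' pairs flip the sign of `beta`, strand-complement pairs are resolved
#' the same way after complementing, and strand-ambiguous (A/T, C/G) or
#' irreconcilable SNPs are dropped. SNPs absent from either side are
#' dropped. The result is ordered as in the genotype panel.
#'
#' @param stats A `sumstats` tibble.
#' @param snps A [genotype_matrix()] or a data frame with `snp_id`,
#'   `effect_allele`, `other_allele` (reference alleles).
#' @return A `sumstats` tibble with attribute `aligned = TRUE`; the number
#'   of dropped SNPs (by reason) is in attribute `dropped`.
#' @export
harmonize_sumstats <- function(stats, snps) {
  if (inherits(snps, "genotype_matrix")) snps <- snps$snps
  snps <- tibble::as_tibble(snps)
  m <- match(snps$snp_id, stats$snp_id)
  present <- !is.na(m)
  if (!any(present)) stop("no SNPs shared between summary statistics and genotypes",
                          call. = FALSE)
  ref <- snps[present, ]
  st <- stats[m[present], ]
  ea <- toupper(st$effect_allele); oa <- toupper(st$other_allele)
  rea <- toupper(ref$effect_allele); roa <- toupper(ref$other_allele)
  cea <- unname(.complement[ea]); coa <- unname(.complement[oa])
  # A/T and C/G pairs equal their own strand flip: unresolvable without
  # frequency information, so always dropped; non-ACGT alleles likewise
  ambiguous <- is.na(cea) | is.na(coa) | ea == coa
  same <- ea == rea & oa == roa
  swap <- ea == roa & oa == rea
  csame <- !is.na(cea) & !is.na(coa) & cea == rea & coa == roa
  cswap <- !is.na(cea) & !is.na(coa) & cea == roa & coa == rea
  # exact-strand matches take precedence; ambiguous pairs are never resolvable
  keep_same <- !ambiguous & (same | (!swap & csame))
  keep_swap <- !ambiguous & !same & (swap | (!csame & cswap))
  keep <- keep_same | keep_swap
  out <- st[keep, ]
  out$effect_allele <- rea[keep]
  out$other_allele <- roa[keep]
  out$beta <- ifelse(keep_swap[keep], -st$beta[keep], st$beta[keep])
  dropped <- c(absent = sum(!present) + sum(!stats$snp_id %in% snps$snp_id),
               ambiguous = sum(ambiguous),
               irreconcilable = sum(!ambiguous & !keep))
  sumstats(out, ancestry = attr(stats, "ancestry"),
           n_cases = attr(stats, "n_cases"),
           n_controls = attr(stats, "n_controls"), aligned = TRUE) |>
    structure(dropped = dropped)
}
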