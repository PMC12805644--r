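#' Read a phenotype table
#'
#' Expects tab-separated columns `FID`, `IID`, `PHENO` (quantitative real or
#' 0/1 binary). Sample ids are `FID_IID`, matching [read_plink()].
#'
#' @param path File path.
#' @return A tibble with columns `sample_id` and `value`.
#' @export
read_phenotype <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("FID", "IID", "PHENO")
  if (!all(need %in% names(d))) {
    stop("phenotype file needs columns FID, IID, PHENO", call. = FALSE)
  }
  tibble::tibble(sample_id = ifelse(d$FID == d$IID, as.character(d$IID),
                                    paste(d$FID, d$IID, sep = "_")),
                 value = as.numeric(d$PHENO))
}

#' Write a phenotype table
#'
#' @param pheno Tibble with `sample_id`, `value` (as from [read_phenotype()]),
#'   or an [ls_impute()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotype <- function(pheno, path) {
  if (inherits(pheno, "imputed_trait")) pheno <- tidy(pheno)
  ids <- pheno$sample_id
  fid <- sub("_.*$", "", ids); iid <- sub("^[^_]*_", "", ids)
  no_us <- !grepl("_", ids)
  fid[no_us] <- ids[no_us]; iid[no_us] <- ids[no_us]
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(FID = fid, IID = iid, PHENO = pheno$value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align a phenotype tibble to a genotype matrix's samples; errors on mismatch
.align_pheno <- function(g, pheno) {
  if (is.numeric(pheno)) {
    if (length(pheno) != length(g$sample_ids)) {
      stop("phenotype length does not match sample count", call. = FALSE)
    }
    return(as.numeric(pheno))
  }
  m <- match(g$sample_ids, pheno$sample_id)
  if (anyNA(m)) stop("phenotype missing for some genotyped samples", call. = FALSE)
  as.numeric(pheno$value[m])
}
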