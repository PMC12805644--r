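# PLINK 1 binary triplet (.bed/.bim/.fam), SNP-major layout.
# .bed: magic 0x6c 0x1b, mode byte 0x01, then ceiling(n/4) bytes per SNP,
# two bits per sample (LSB-first): 00 = 2 copies of allele-1, 01 = missing,
# 10 = 1 copy, 11 = 0 copies. Allele-1 is taken as the effect allele.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: dosage of allele-1 for each 2-bit field of a byte
.bed_lut <- local({
  codes <- matrix(0, 256, 4)
  map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  for (b in 0:255) {
    for (k in 0:3) codes[b + 1, k + 1] <- map[as.character(bitwAnd(bitwShiftR(b, 2 * k), 3L))]
  }
  codes
})

#' Read a PLINK 1 binary genotype triplet
#'
#' @param bed_path,bim_path,fam_path Paths to the `.bed`, `.bim` and `.fam`
#'   files. `bim_path`/`fam_path` default to `bed_path` with the extension
#'   swapped.
#' @return A [genotype_matrix()] with raw dosages counting the bim allele-1
#'   (the effect allele); missing genotypes are `NA`.
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (f in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  if (ncol(bim) != 6) stop("malformed .bim: expected 6 columns", call. = FALSE)
  names(bim) <- c("chrom", "snp_id", "cm", "pos_bp", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  if (ncol(fam) != 6) stop("malformed .fam: expected 6 columns", call. = FALSE)
  n <- nrow(fam); p <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic[1:2])) {
    stop("not a PLINK .bed file (magic bytes mismatch)", call. = FALSE)
  }
  if (raw[3] != .bed_magic[3]) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  body <- raw[-(1:3)]
  if (length(body) != bpv * p) {
    stop("bed payload size (", length(body), " bytes) inconsistent with .bim/.fam (",
         bpv * p, " expected)", call. = FALSE)
  }
  ints <- as.integer(body) + 1L
  # decode all bytes at once: (bpv*p) x 4 dosages, then trim per-SNP padding
  dec <- .bed_lut[ints, , drop = FALSE]
  full <- matrix(t(dec), nrow = 4 * bpv)  # (4*bpv) x p, column = SNP
  X <- full[seq_len(n), , drop = FALSE]
  snps <- tibble::tibble(
    snp_id = bim$snp_id, chrom = bim$chrom, pos_bp = as.integer(bim$pos_bp),
    effect_allele = bim$a1, other_allele = bim$a2
  )
  ids <- ifelse(fam[[1]] == fam[[2]], fam[[2]],
                paste(fam[[1]], fam[[2]], sep = "_"))
  genotype_matrix(X, snps, ids)
}

#' Write a genotype matrix as a PLINK 1 binary triplet
#'
#' @param g A raw [genotype_matrix()].
#' @param prefix Output path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return Invisibly, the three paths written.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$standardized) stop("write_plink needs raw dosages", call. = FALSE)
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  X <- g$dosages
  n <- nrow(X); p <- ncol(X)
  bpv <- ceiling(n / 4)
  # per-sample 2-bit codes: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11; padding 00
  code <- matrix(0L, 4 * bpv, p)
  codes_obs <- matrix(c(3L, 2L, 0L)[X + 1L], n, p)  # NA propagates
  codes_obs[is.na(codes_obs)] <- 1L
  code[seq_len(n), ] <- codes_obs
  shifts <- rep(c(0L, 2L, 4L, 6L), bpv)
  shifted <- code * bitwShiftL(1L, shifts)  # == bitwShiftL(code, shifts)
  bytes <- rowsum(shifted, group = rep(seq_len(bpv), each = 4))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(bytes), con)
  ids <- g$sample_ids
  fid <- sub("_.*$", "", ids); iid <- sub("^[^_]*_", "", ids)
  no_us <- !grepl("_", ids)
  fid[no_us] <- ids[no_us]; iid[no_us] <- ids[no_us]
  utils::write.table(
    data.frame(fid, iid, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$snps$chrom, g$snps$snp_id, 0, g$snps$pos_bp,
               g$snps$effect_allele, g$snps$other_allele),
    paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
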