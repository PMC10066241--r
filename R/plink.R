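# PLINK1 binary fileset codec (.bed/.bim/.fam), variant-major only.
#
# 2-bit genotype codes within each byte, sample index increasing from the
# least-significant bit pair: 00 = two copies of allele_1, 01 = missing,
# 10 = one copy, 11 = zero copies. Each variant's bytes are padded to
# ceiling(n_samples / 4).

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_MODE_VARIANT_MAJOR <- as.raw(0x01)

# code (0..3) -> dosage; 256 x 4 table gives the four dosages packed in a byte
.code_to_dosage <- c(2L, NA_integer_, 1L, 0L)

.byte_decode_table <- local({
  tab <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      tab[b + 1L, k + 1L] <- .code_to_dosage[code + 1L]
    }
  }
  tab
})

.dosage_to_code <- function(d) {
  # dosage {2, 1, 0, NA} -> code {0, 2, 3, 1}
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  code
}

#' Read a PLINK1 binary fileset
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` into a
#' [genotype_dataset]. Only the variant-major layout (mode byte `0x01`) is
#' supported, and dosages count copies of the .bim A1 allele.
#'
#' An optional sidecar table (`r2_file`) supplies per-variant imputation
#' quality, since the .bim format has no such column; it must be delimited
#' text with header columns `id` and `imputation_r2`.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @param r2_file optional path to a delimited imputation-r2 sidecar.
#' @return a `genotype_dataset`.
#' @export
read_plink <- function(prefix, r2_file = NULL) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing file: ", p)

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "allele_1", "allele_2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "sample_id", "pat", "mat",
                                         "sex_code", "pheno"))
  n_samples <- nrow(fam)
  n_variants <- nrow(bim)

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], BED_MAGIC))
    stop("not a PLINK1 .bed file (bad magic bytes): ", paths[1])
  if (raw[3] != BED_MODE_VARIANT_MAJOR)
    stop("only variant-major .bed files are supported: ", paths[1])
  bpv <- ceiling(n_samples / 4)
  expected <- 3 + bpv * n_variants
  if (length(raw) != expected)
    stop(".bed length mismatch: expected ", expected, " bytes, found ",
         length(raw))

  body <- as.integer(raw[-(1:3)])
  if (n_variants > 0 && n_samples > 0) {
    # decode all bytes at once: (4 * bpv) rows per variant, trim padding
    dec <- .byte_decode_table[body + 1L, , drop = FALSE] # (bpv*n_variants) x 4
    geno <- matrix(t(dec), nrow = 4L * bpv)              # per-variant columns
    dosage <- geno[seq_len(n_samples), , drop = FALSE]
  } else {
    dosage <- matrix(integer(0), nrow = n_samples, ncol = n_variants)
  }

  sex <- c("male", "female")[match(fam$sex_code, 1:2)]
  sex[is.na(sex)] <- "unknown"
  samples <- data.frame(sample_id = as.character(fam$sample_id), sex = sex,
                        stringsAsFactors = FALSE)
  variants <- bim[, c("id", "chrom", "pos", "allele_1", "allele_2")]

  if (!is.null(r2_file)) {
    r2 <- utils::read.table(r2_file, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("id", "imputation_r2") %in% names(r2)))
      stop("r2 sidecar must have columns 'id' and 'imputation_r2'")
    variants$imputation_r2 <- r2$imputation_r2[match(variants$id, r2$id)]
  }

  genotype_dataset(dosage = dosage, variants = variants, samples = samples)
}

#' Write a PLINK1 binary fileset
#'
#' Writes a [genotype_dataset] to `prefix.bed` / `.bim` / `.fam` in the
#' variant-major layout. `read_plink(write_plink(ds, p))` is the identity on
#' dosage, variant ids and alleles.
#'
#' @param ds a `genotype_dataset`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix) {
  validate_genotype_dataset(ds)
  n_samples <- nrow(ds$samples)
  n_variants <- nrow(ds$variants)
  bpv <- ceiling(n_samples / 4)

  con <- file(paste0(prefix, ".bed"), open = "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_MODE_VARIANT_MAJOR), con)
  if (n_variants > 0 && bpv > 0) {
    codes <- matrix(1L, nrow = 4L * bpv, ncol = n_variants) # pad = missing code
    codes[seq_len(n_samples), ] <- apply(ds$dosage, 2L, .dosage_to_code)
    # pad bit pairs are conventionally zero
    if (4L * bpv > n_samples)
      codes[(n_samples + 1L):(4L * bpv), ] <- 0L
    shifts <- rep(c(0L, 2L, 4L, 6L), bpv)
    shifted <- codes * as.integer(2^shifts)
    grp <- rep(seq_len(bpv), each = 4L)
    bytes <- rowsum(shifted, grp)
    writeBin(as.raw(bytes), con)
  }

  sex_code <- match(ds$samples$sex, c("male", "female"))
  sex_code[is.na(sex_code)] <- 0L
  if (is.null(ds$samples$sex)) sex_code <- rep(0L, n_samples)
  fam <- data.frame(ds$samples$sample_id, ds$samples$sample_id,
                    rep(0L, n_samples), rep(0L, n_samples),
                    sex_code, rep(-9L, n_samples))
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bim <- data.frame(ds$variants$chrom, ds$variants$id,
                    rep(0, n_variants), ds$variants$pos,
                    ds$variants$allele_1, ds$variants$allele_2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}
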