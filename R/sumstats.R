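#' Read GWAS summary statistics from delimited text
#'
#' Parses a whitespace- or tab-delimited file with header into a summary
#' statistics table usable as polygenic-score weights. `column_map` names
#' the file's columns for each required field; either a `beta` or an `or`
#' (odds ratio, converted via `beta = log(OR)`) entry must be supplied.
#'
#' Rows with a p-value outside `(0, 1]`, missing alleles, non-ACGT alleles,
#' or identical effect/other alleles are dropped; the counts of each drop
#' reason are returned alongside the table.
#'
#' @param path path to the delimited file.
#' @param column_map named list/vector mapping fields `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `pvalue`, and one of `beta` or `or`
#'   to column names in the file. `chrom`/`pos` are optional.
#' @param sep field separator passed to [utils::read.table()] (default any
#'   whitespace).
#' @return list with elements `table` (data.frame: `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `pvalue`) and `report`
#'   (named integer vector of drop counts).
#' @export
read_sumstats <- function(path, column_map, sep = "") {
  if (!file.exists(path)) stop("missing file: ", path)
  column_map <- as.list(column_map)
  required <- c("id", "effect_allele", "other_allele", "pvalue")
  miss <- setdiff(required, names(column_map))
  if (length(miss))
    stop("column_map lacks required fields: ", paste(miss, collapse = ", "))
  if (!any(c("beta", "or") %in% names(column_map)))
    stop("column_map must provide 'beta' or 'or'")

  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (fld in unlist(column_map))
    if (!fld %in% names(raw)) stop("mapped column not in file: ", fld)

  tab <- data.frame(
    id = as.character(raw[[column_map$id]]),
    chrom = if (!is.null(column_map$chrom))
      as.character(raw[[column_map$chrom]]) else NA_character_,
    pos = if (!is.null(column_map$pos))
      as.integer(raw[[column_map$pos]]) else NA_integer_,
    effect_allele = toupper(as.character(raw[[column_map$effect_allele]])),
    other_allele = toupper(as.character(raw[[column_map$other_allele]])),
    pvalue = as.numeric(raw[[column_map$pvalue]]),
    stringsAsFactors = FALSE
  )
  tab$beta <- if (!is.null(column_map$beta)) {
    as.numeric(raw[[column_map$beta]])
  } else {
    log(as.numeric(raw[[column_map$or]]))
  }

  acgt <- c("A", "C", "G", "T")
  bad_p <- is.na(tab$pvalue) | tab$pvalue <= 0 | tab$pvalue > 1
  bad_allele <- is.na(tab$effect_allele) | is.na(tab$other_allele) |
    !(tab$effect_allele %in% acgt) | !(tab$other_allele %in% acgt)
  same_allele <- !bad_allele & tab$effect_allele == tab$other_allele
  bad_beta <- is.na(tab$beta) | !is.finite(tab$beta)
  drop <- bad_p | bad_allele | same_allele | bad_beta
  report <- c(
    dropped_invalid_p = sum(bad_p),
    dropped_bad_allele = sum(bad_allele | same_allele),
    dropped_bad_beta = sum(bad_beta & !bad_p & !bad_allele & !same_allele),
    n_input = nrow(tab),
    n_kept = sum(!drop)
  )
  tab <- tab[!drop, c("id", "chrom", "pos", "effect_allele", "other_allele",
                      "beta", "pvalue")]
  rownames(tab) <- NULL
  if (anyDuplicated(tab$id))
    stop("duplicate variant ids in summary statistics: ",
         paste(utils::head(unique(tab$id[duplicated(tab$id)]), 5), collapse = ", "))
  list(table = tab, report = report)
}

#' Read a gene-by-sample counts matrix and sample metadata
#'
#' Counts are delimited text with genes as rows (first column = gene id)
#' and samples as columns; metadata is delimited text keyed by `sample_id`.
#' Samples are matched by id and returned in the counts' column order.
#'
#' @param counts_path delimited counts matrix file.
#' @param meta_path delimited sample metadata file with a `sample_id` column.
#' @param sep field separator (default tab).
#' @return list of class `expression_dataset`: `counts` (integer matrix,
#'   genes x samples), `samples` (data.frame aligned to columns).
#' @export
read_expression <- function(counts_path, meta_path, sep = "\t") {
  cts <- utils::read.table(counts_path, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE)
  cts <- as.matrix(cts)
  if (any(cts < 0)) stop("counts must be nonnegative")
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata lacks sample_id column")
  idx <- match(colnames(cts), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(utils::head(colnames(cts)[is.na(idx)], 5), collapse = ", "))
  expression_dataset(cts, meta[idx, , drop = FALSE])
}

#' Construct an expression dataset
#'
#' @param counts nonnegative gene-by-sample count matrix (row names = gene
#'   ids, column names = sample ids).
#' @param samples data.frame of per-sample covariates aligned to columns,
#'   with a `sample_id` column.
#' @return an object of class `expression_dataset` with elements `counts`,
#'   `samples`, and `lib_size` (column sums).
#' @export
expression_dataset <- function(counts, samples) {
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (ncol(counts) != nrow(samples))
    stop("counts column count != sample count")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, samples = samples,
                 lib_size = colSums(counts)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  invisible(x)
}
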