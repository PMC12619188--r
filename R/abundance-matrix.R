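#' Sample-by-metabolite abundance matrix with metadata
#'
#' The container every preprocessing stage transforms. `values` holds
#' nonnegative abundances (missing allowed) with samples in rows and
#' metabolites in columns; `sample_meta` carries per-sample metadata
#' (`sample_id`, `batch_id`, `is_qc`, `label`); `metabolite_meta` carries
#' per-metabolite metadata (`metabolite`, `dataset`, `class`, `kegg_id`).
#' Pooled-QC injections live in the same matrix, distinguished by the
#' `is_qc` flag; their `label` is `NA`.
#'
#' @param values numeric matrix, samples x metabolites. Column names must be
#'   unique metabolite names.
#' @param sample_meta data.frame with columns `sample_id` (unique),
#'   `batch_id`, `is_qc` (logical) and optionally `label` (0/1, `NA` for QC
#'   rows); one row per row of `values`.
#' @param metabolite_meta data.frame with columns `metabolite` (matching
#'   `colnames(values)`), `dataset` (one of `"polar"`, `"nonpolar_pos"`,
#'   `"nonpolar_neg"`), and optionally `class` and `kegg_id`.
#'
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_meta, metabolite_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(colnames(values)))
    stopf("`values` must have metabolite column names")
  if (anyDuplicated(colnames(values)))
    stopf("metabolite names must be unique within a matrix")
  if (nrow(sample_meta) != nrow(values))
    stopf("`sample_meta` must have one row per sample (%d != %d)",
          nrow(sample_meta), nrow(values))
  req <- c("sample_id", "batch_id", "is_qc")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) stopf("`sample_meta` lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    stopf("sample_ids must be unique")
  if (!"label" %in% names(sample_meta)) sample_meta$label <- NA_integer_
  if (is.null(metabolite_meta)) {
    metabolite_meta <- data.frame(metabolite = colnames(values),
                                  dataset = NA_character_,
                                  stringsAsFactors = FALSE)
  }
  if (!identical(metabolite_meta$metabolite, colnames(values)))
    stopf("`metabolite_meta$metabolite` must match colnames(values) in order")
  if (any(values < 0, na.rm = TRUE) && !isTRUE(attr(values, "transformed")))
    stopf("abundances must be nonnegative before transformation")
  rownames(values) <- sample_meta$sample_id
  structure(list(values = values,
                 sample_meta = as.data.frame(sample_meta),
                 metabolite_meta = as.data.frame(metabolite_meta)),
            class = "abundance_matrix")
}

## internal constructor skipping the nonnegativity check (post-log stages)
abundance_matrix_transformed <- function(values, sample_meta, metabolite_meta) {
  attr(values, "transformed") <- TRUE
  m <- abundance_matrix(values, sample_meta, metabolite_meta)
  attr(m$values, "transformed") <- NULL
  m
}

#' @export
print.abundance_matrix <- function(x, ...) {
  nqc <- sum(x$sample_meta$is_qc)
  cat(sprintf("<abundance_matrix> %d samples (%d biological + %d QC) x %d metabolites\n",
              nrow(x$values), nrow(x$values) - nqc, nqc, ncol(x$values)))
  cat(sprintf("  missing: %.1f%%; datasets: %s\n",
              100 * mean(is.na(x$values)),
              paste(unique(x$metabolite_meta$dataset), collapse = ", ")))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by samples and/or metabolites
#'
#' @param x an `abundance_matrix`.
#' @param samples,metabolites logical, integer or character index vectors.
#' @return An `abundance_matrix`.
#' @export
am_subset <- function(x, samples = NULL, metabolites = NULL) {
  si <- seq_len(nrow(x$values))
  mi <- seq_len(ncol(x$values))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$sample_meta$sample_id) else si[samples]
  }
  if (!is.null(metabolites)) {
    mi <- if (is.character(metabolites)) match(metabolites, colnames(x$values)) else mi[metabolites]
  }
  if (anyNA(si) || anyNA(mi)) stopf("subset refers to unknown samples/metabolites")
  abundance_matrix_transformed(x$values[si, mi, drop = FALSE],
                               x$sample_meta[si, , drop = FALSE],
                               x$metabolite_meta[mi, , drop = FALSE])
}

#' Biological (non-QC) subset of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return An `abundance_matrix` containing only non-QC samples.
#' @export
biological_samples <- function(x) am_subset(x, samples = !x$sample_meta$is_qc)

#' Write / read an abundance matrix as delimited text
#'
#' The matrix is persisted as three tab-separated files sharing a prefix:
#' `<prefix>_values.tsv` (samples x metabolites, first column `sample_id`),
#' `<prefix>_samples.tsv` and `<prefix>_metabolites.tsv` (the two metadata
#' sidecars).
#'
#' @param x an `abundance_matrix`.
#' @param prefix file path prefix.
#' @return `write_abundance_matrix` returns the prefix invisibly;
#'   `read_abundance_matrix` returns an `abundance_matrix`.
#' @export
write_abundance_matrix <- function(x, prefix) {
  vals <- data.frame(sample_id = x$sample_meta$sample_id, x$values,
                     check.names = FALSE)
  utils::write.table(vals, paste0(prefix, "_values.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(x$sample_meta, paste0(prefix, "_samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(x$metabolite_meta, paste0(prefix, "_metabolites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(prefix) {
  vals <- utils::read.delim(paste0(prefix, "_values.tsv"), check.names = FALSE)
  smeta <- utils::read.delim(paste0(prefix, "_samples.tsv"))
  mmeta <- utils::read.delim(paste0(prefix, "_metabolites.tsv"))
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$sample_id
  abundance_matrix_transformed(m, smeta, mmeta)
}
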