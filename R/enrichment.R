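#' Load a local pathway annotation table
#'
#' Reads a TSV with one pathway per line: `pathway_id`, `pathway_name`,
#' then the member compound IDs as additional tab-separated fields (a
#' local, version-pinned stand-in for live KEGG list/link retrieval).
#'
#' @param path file path.
#' @return data.frame: `pathway_id`, `pathway_name`, `compounds` (list
#'   column of member IDs).
#' @export
load_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("annotation file is empty: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3L)
      stopf("malformed annotation row at line %d: need pathway_id, name and >= 1 compound", i)
    parts[[i]] <- f
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stopf("duplicate pathway_id at line %d: %s",
          which(duplicated(ids))[1L], ids[duplicated(ids)][1L])
  data.frame(pathway_id = ids,
             pathway_name = vapply(parts, `[[`, "", 2L),
             compounds = I(lapply(parts, function(f) unique(f[-(1:2)]))),
             stringsAsFactors = FALSE)
}

#' Write a pathway annotation table as TSV
#'
#' @param annotations data.frame as returned by [load_annotations()] or
#'   [generate_pathway_db()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(seq_len(nrow(annotations)), function(i)
    paste(c(annotations$pathway_id[i], annotations$pathway_name[i],
            annotations$compounds[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

## One-sided (enrichment-direction) Fisher exact p for the 2x2 table
## (k, n-k, K-k, N-K-n+k) = hypergeometric upper tail at k.
hyper_tail_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis (Fisher exact)
#'
#' For each pathway, tests whether the input compound set overlaps the
#' pathway's members (restricted to the background universe) more than
#' chance, using the one-sided Fisher exact test -- equivalently the
#' hypergeometric upper tail of the 2x2 table (k, n-k, K-k, N-K-n+k)
#' where k = |input & pathway|, K = |pathway & universe|, n = |input|,
#' N = |universe|. P values are BH-adjusted across tested pathways.
#'
#' @param input character vector of significant compound IDs. IDs outside
#'   the universe are dropped with a warning.
#' @param universe character vector of background compound IDs (e.g. all
#'   measured metabolites carrying an ID).
#' @param annotations pathway table ([load_annotations()] /
#'   [generate_pathway_db()]). Pathways with no member in the universe
#'   are not tested.
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame sorted by `fdr_p` (ties by `pathway_id`):
#'   `pathway_id`, `pathway_name`, `k`, `K`, `n`, `N`, `fisher_p`,
#'   `fdr_p`, `significant`.
#' @export
fisher_enrichment <- function(input, universe, annotations, alpha = 0.05) {
  universe <- unique(universe[!is.na(universe)])
  input <- unique(input[!is.na(input)])
  if (!length(input) || !length(universe)) stopf("input and universe must be non-empty")
  outside <- setdiff(input, universe)
  if (length(outside)) {
    warning(sprintf("%d input compound(s) outside the universe dropped", length(outside)))
    input <- intersect(input, universe)
    if (!length(input)) stopf("no input compounds remain inside the universe")
  }
  N <- length(universe); n <- length(input)
  members <- lapply(annotations$compounds, intersect, universe)
  K <- lengths(members)
  keep <- K > 0L
  k <- vapply(members[keep], function(m) length(intersect(m, input)), 0L)
  p <- hyper_tail_p(k, K[keep], n, N)
  fdr <- adjust_bh(p)
  out <- data.frame(pathway_id = annotations$pathway_id[keep],
                    pathway_name = annotations$pathway_name[keep],
                    k = k, K = K[keep], n = n, N = N,
                    fisher_p = p, fdr_p = fdr,
                    significant = fdr < alpha,
                    stringsAsFactors = FALSE)
  out[order(out$fdr_p, out$pathway_id), , drop = FALSE]
}

#' Top pathways for a dot-plot style report
#'
#' @param records data.frame from [fisher_enrichment()].
#' @param top_n number of rows (default 10); ties in `fdr_p` are ordered
#'   by `pathway_id`.
#' @return data.frame: `pathway_id`, `pathway_name`, `neglog10_fdr`,
#'   `count` (overlap k).
#' @export
enrichment_report <- function(records, top_n = 10L) {
  ord <- order(records$fdr_p, records$pathway_id)
  top <- records[ord, , drop = FALSE][seq_len(min(top_n, nrow(records))), , drop = FALSE]
  data.frame(pathway_id = top$pathway_id, pathway_name = top$pathway_name,
             neglog10_fdr = -log10(top$fdr_p), count = top$k,
             stringsAsFactors = FALSE, row.names = NULL)
}
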