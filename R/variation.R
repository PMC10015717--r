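#' Per-gene pairwise expression variation
#'
#' The core per-gene statistic: for every gene, the average over a pair set
#' of the absolute log-scale expression difference `|x_i - x_k|`. Over
#' sex-matched sibling pairs this measures developmental stability of the
#' gene's expression (lower = more stable); over all pairs of hybrid
#' descendants or cross-population pairs it measures expression diversity.
#' `mean_expression` is the average log expression over all individuals the
#' pair set references, used later to correct for mean dependence.
#'
#' @param m An `expr_matrix` on the log10 scale.
#' @param pairs A `pair_set`.
#' @return Data.frame of class `gene_variation` with columns `gene_id`,
#'   `mean_expression`, `raw_variation`, `pairset_kind`, `stage`.
#' @export
pairwise_variation <- function(m, pairs) {
  d <- pair_differences(m, pairs)  # validates units, members, non-emptiness
  ids <- unique(c(pairs$sample_a, pairs$sample_b))
  structure(
    data.frame(gene_id = rownames(m),
               mean_expression = rowMeans(unclass(m)[, ids, drop = FALSE]),
               raw_variation = rowMeans(d),
               pairset_kind = attr(pairs, "kind"),
               stage = attr(pairs, "stage"),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("gene_variation", "data.frame"))
}

#' Running-median correction of variation for mean expression
#'
#' Absolute expression level confounds expression variation: the per-gene
#' statistic is therefore corrected by sorting genes by mean expression and
#' subtracting, from each gene's raw variation, the running median of raw
#' variation over the genes with neighbouring mean expression (window 501,
#' i.e. +/- 250 genes). Within the top or bottom 250 positions the window
#' shrinks to an equal number of genes on each side, down to the gene
#' itself at the extremes. Corrected values may be negative; gene order of
#' the input is restored on output.
#'
#' Ties in mean expression are broken by gene id (stable, deterministic).
#'
#' @param tab A `gene_variation` table from [pairwise_variation()].
#' @param window Odd window size >= 3, default 501 genes.
#' @return `tab` with an added `corrected_variation` column; the applied
#'   window is stored as attribute `window`.
#' @export
running_median_correction <- function(tab, window = 501L) {
  if (window %% 2L == 0L || window < 3L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  n <- nrow(tab)
  if (n < 1L) stop("empty variation table", call. = FALSE)
  o <- order(tab$mean_expression, tab$gene_id)
  r <- tab$raw_variation[o]
  hmax <- (window - 1L) / 2L
  h <- pmin(hmax, seq_len(n) - 1L, n - seq_len(n))
  med <- numeric(n)
  interior <- h == hmax
  if (any(interior) && n >= window) {
    # stats::runmed computes the same centred odd-window running median
    rm_full <- stats::runmed(r, k = window, endrule = "keep")
    med[interior] <- rm_full[interior]
  }
  for (i in which(!interior))
    med[i] <- stats::median(r[(i - h[i]):(i + h[i])])
  corrected <- numeric(n)
  corrected[o] <- r - med
  tab$corrected_variation <- corrected
  attr(tab, "window") <- as.integer(window)
  tab
}

#' Write a gene variation table as TSV
#' @param tab A `gene_variation` table.
#' @param path Output path.
#' @export
write_variation <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
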