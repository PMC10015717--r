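#' Whole-transcriptome variance between two embryos
#'
#' The per-pair stage statistic: with `y_j = x_j^i - x_j^k` the per-gene
#' log-expression difference between embryos i and k, the statistic is the
#' population variance (divisor N, the number of genes analysed)
#' `V = (1/N) * sum_j (y_j - mean(y))^2`. Low V means the two whole
#' embryonic transcriptomes are similar; over sibling pairs it measures
#' stage stability, over hybrid pairs stage diversity.
#'
#' @param m An `expr_matrix` on the log10 scale.
#' @param i,k Sample ids.
#' @param genes Optional gene-id subset (default all genes in `m`).
#' @return The variance value (squared log10 units).
#' @export
pair_variance <- function(m, i, k, genes = NULL) {
  .assert_log10(m, "pair_variance()")
  miss <- setdiff(c(i, k), colnames(m))
  if (length(miss))
    stop("sample(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(genes)) genes <- rownames(m)
  miss_g <- setdiff(genes, rownames(m))
  if (length(miss_g))
    stop("gene(s) not in matrix: ", paste(utils::head(miss_g, 5),
                                          collapse = ", "), call. = FALSE)
  if (length(genes) < 2L)
    stop("need at least 2 genes to compute a variance", call. = FALSE)
  y <- unclass(m)[genes, i] - unclass(m)[genes, k]
  mean((y - mean(y))^2)
}

#' Per-pair transcriptome variances for a stage
#'
#' One V value per pair of a pair set, assembled with stage and group
#' labels for the stage-level comparisons.
#'
#' @param m An `expr_matrix` on the log10 scale.
#' @param pairs A `pair_set`.
#' @param genes Optional gene-id subset.
#' @param group Group label to carry in the output (e.g. `"F0"`, `"F3"`).
#' @return Data.frame with `group`, `stage`, `sample_a`, `sample_b`, `v`,
#'   `n_genes`.
#' @export
stage_variances <- function(m, pairs, genes = NULL, group = NA_character_) {
  if (nrow(pairs) == 0L) stop("empty pair set", call. = FALSE)
  if (is.null(genes)) genes <- rownames(m)
  v <- vapply(seq_len(nrow(pairs)), function(j)
    pair_variance(m, pairs$sample_a[j], pairs$sample_b[j], genes),
    numeric(1))
  data.frame(group = group, stage = attr(pairs, "stage"),
             sample_a = pairs$sample_a, sample_b = pairs$sample_b,
             v = v, n_genes = length(genes), stringsAsFactors = FALSE)
}
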