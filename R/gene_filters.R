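#' Per-pair absolute expression differences
#'
#' For each gene, the absolute difference of log-scale expression within
#' every pair of a pair set: the raw material of both the variation
#' statistics and the technical-error filter.
#'
#' @param m An `expr_matrix` on the log10 scale.
#' @param pairs A `pair_set`.
#' @return Numeric matrix, genes x pairs, of `|x_i - x_k|`.
#' @export
pair_differences <- function(m, pairs) {
  .assert_log10(m, "pair_differences()")
  miss <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)), colnames(m))
  if (length(miss))
    stop("pair member(s) absent from expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(pairs) == 0L) stop("empty pair set", call. = FALSE)
  d <- abs(unclass(m)[, pairs$sample_a, drop = FALSE] -
           unclass(m)[, pairs$sample_b, drop = FALSE])
  colnames(d) <- paste(pairs$sample_a, pairs$sample_b, sep = "|")
  d
}

#' Technical-error difference matrix
#'
#' Builds, per gene, the technical-error sample the sibling differences are
#' tested against. `mode = "raw"` pools the pairwise replicate differences
#' of every replicated condition (four replicates give six values per
#' condition); `mode = "averaged"` averages the six combinations within each
#' condition first, giving one value per condition (and therefore needs at
#' least two replicated conditions to be testable).
#'
#' @param m An `expr_matrix` on the log10 scale.
#' @param tech_pairs A list of `pair_set`s as returned by
#'   [technical_pairs()].
#' @param mode `"raw"` or `"averaged"`.
#' @return Numeric matrix, genes x values.
#' @export
technical_diffs <- function(m, tech_pairs, mode = c("raw", "averaged")) {
  mode <- match.arg(mode)
  if (inherits(tech_pairs, "pair_set")) tech_pairs <- list(tech_pairs)
  per_cond <- lapply(tech_pairs, function(p) pair_differences(m, p))
  if (mode == "raw") {
    do.call(cbind, per_cond)
  } else {
    out <- vapply(per_cond, rowMeans, numeric(nrow(m)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
    rownames(out) <- rownames(m)
    out
  }
}

.filter_report <- function(gene_id, statistic, p_value, alpha, filter_name) {
  data.frame(gene_id = gene_id, statistic = statistic, p_value = p_value,
             passed = !is.na(p_value) & p_value < alpha,
             filter_name = filter_name, stringsAsFactors = FALSE)
}

#' Technical-error gene filter
#'
#' Selects genes whose expression deviation between sibling embryos
#' significantly exceeds the deviation between technical replicates: per
#' gene, a one-sided rank-sum test of sibling differences being
#' stochastically larger than technical differences, passed when
#' p < alpha. Genes with fewer than two usable values on either side are
#' flagged untestable (p = NA, not passed).
#'
#' @param sib_diffs Genes x pairs matrix of sibling absolute differences
#'   (see [pair_differences()]).
#' @param tech_diffs Genes x values matrix of technical differences (see
#'   [technical_diffs()]).
#' @param alpha Per-gene significance level, default 0.01.
#' @return Data.frame with `gene_id`, `statistic` (Mann-Whitney U),
#'   `p_value`, `passed`, `filter_name`.
#' @export
technical_error_filter <- function(sib_diffs, tech_diffs, alpha = 0.01) {
  if (!is.matrix(sib_diffs)) sib_diffs <- as.matrix(sib_diffs)
  if (!is.matrix(tech_diffs)) tech_diffs <- as.matrix(tech_diffs)
  if (nrow(sib_diffs) != nrow(tech_diffs))
    stop("sibling and technical matrices disagree on gene count",
         call. = FALSE)
  if (ncol(sib_diffs) < 1L || ncol(tech_diffs) < 2L)
    stop("need >= 1 sibling difference and >= 2 technical values per gene",
         call. = FALSE)
  n <- ncol(sib_diffs); m <- ncol(tech_diffs)
  if (max(n, m) <= 8L) {
    res <- lapply(seq_len(nrow(sib_diffs)), function(i) {
      a <- sib_diffs[i, ][is.finite(sib_diffs[i, ])]
      b <- tech_diffs[i, ][is.finite(tech_diffs[i, ])]
      if (length(a) < 2L || length(b) < 2L)
        return(list(statistic = NA_real_, p.value = NA_real_))
      rank_sum_test(a, b, alternative = "greater")
    })
    p <- vapply(res, `[[`, numeric(1), "p.value")
    u <- vapply(res, `[[`, numeric(1), "statistic")
  } else {
    p <- .row_ranksum_p(sib_diffs, tech_diffs, alternative = "greater")
    u <- rep(NA_real_, length(p))
  }
  .filter_report(rownames(sib_diffs) %||% as.character(seq_along(p)),
                 u, p, alpha, "technical_error")
}

#' Differential-mean gene filter
#'
#' Two-sided rank-sum test per gene between the per-individual expression
#' values of two populations (all individuals, regardless of sex or sibling
#' relationship); genes with significantly different expression levels pass.
#' Both matrices must share one gene universe.
#'
#' @param m_a,m_b `expr_matrix` objects on the log10 scale (columns =
#'   individuals of each population).
#' @param alpha Per-gene significance level, default 0.01.
#' @return Data.frame as in [technical_error_filter()], with
#'   `filter_name = "differential_mean"`.
#' @export
differential_mean_filter <- function(m_a, m_b, alpha = 0.01) {
  .assert_log10(m_a, "differential_mean_filter()")
  .assert_log10(m_b, "differential_mean_filter()")
  if (!identical(rownames(m_a), rownames(m_b)))
    stop("gene universes differ between the two populations", call. = FALSE)
  A <- unclass(m_a); B <- unclass(m_b)
  n <- ncol(A); m <- ncol(B)
  if (max(n, m) <= 8L) {
    res <- lapply(seq_len(nrow(A)), function(i)
      rank_sum_test(A[i, ], B[i, ], alternative = "two.sided"))
    p <- vapply(res, `[[`, numeric(1), "p.value")
    u <- vapply(res, `[[`, numeric(1), "statistic")
  } else {
    p_g <- .row_ranksum_p(A, B, alternative = "greater")
    p <- pmin(1, 2 * pmin(p_g, 1 - p_g))
    u <- rep(NA_real_, length(p))
  }
  .filter_report(rownames(A), u, p, alpha, "differential_mean")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
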