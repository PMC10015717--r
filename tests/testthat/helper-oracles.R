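# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (full enumeration, pair counting, two-pass sums) so
# they share no code path with the package implementations they check.

# Exact one- or two-sided rank-sum p-value by enumerating every assignment
# of the pooled values to the first sample, with U computed by direct pair
# counting (wins + half ties), never via ranks.
oracle_ranksum_p <- function(x, y, alternative = "greater") {
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) u <- u + sum(ai > b) + 0.5 * sum(ai == b)
    u
  }
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  u_obs <- u_of(x, y)
  cmb <- utils::combn(N, n)
  u_null <- apply(cmb, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  p_ge <- mean(u_null >= u_obs - eps)
  p_le <- mean(u_null <= u_obs + eps)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Two-pass population variance of the per-gene differences between two
# expression columns.
oracle_pair_variance <- function(xi, xk) {
  y <- xi - xk
  m <- sum(y) / length(y)
  s <- 0
  for (v in y) s <- s + (v - m)^2
  s / length(y)
}

# Naive running-median correction: explicit loop with symmetric window
# shrink, sort by (mean_expression, gene_id).
oracle_runmed_correction <- function(mean_expr, raw, gene_id, window) {
  o <- order(mean_expr, gene_id)
  r <- raw[o]; n <- length(r)
  hmax <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(hmax, i - 1, n - i)
    out[i] <- r[i] - median(r[(i - h):(i + h)])
  }
  res <- numeric(n); res[o] <- out
  res
}

# Minimal metadata table builder.
make_meta <- function(sample_id, stage = "s1", group = "F0", sex = NA,
                      sibling_group = NA, replicate_of = NA) {
  data.frame(sample_id = sample_id,
             stage = rep_len(as.character(stage), length(sample_id)),
             group = rep_len(group, length(sample_id)),
             sex = rep_len(as.character(sex), length(sample_id)),
             sibling_group = rep_len(as.character(sibling_group),
                                     length(sample_id)),
             replicate_of = rep_len(as.character(replicate_of),
                                    length(sample_id)),
             stringsAsFactors = FALSE)
}

# Small log-scale expression matrix from a genes x samples value matrix.
make_expr <- function(values, genes = NULL, samples = NULL,
                      units = "log10") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  rownames(values) <- genes; colnames(values) <- samples
  expression_matrix(values, units = units)
}
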