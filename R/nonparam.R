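#' Spearman correlation with test of no correlation
#'
#' Midrank-based Spearman rho with a p-value from the t approximation
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom), the
#' appropriate form at the gene-set sizes the pipeline works with. An exact
#' permutation p-value is available for n <= 8 (oracle use).
#'
#' @param x,y Paired numeric vectors (e.g. per-gene corrected variation and
#'   corrected diversity), length >= 3.
#' @param exact Use exact permutation enumeration (only n <= 8).
#' @return List with `rho`, `p.value`, `n`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant input: rho undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact mode limited to n <= 8", call. = FALSE)
    perms <- .permutations(n)
    rho_null <- apply(perms, 1L, function(ix) stats::cor(rx, ry[ix]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p.value = p, n = n)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' (number of groups - 1) degrees of freedom. Thin wrapper around
#' [stats::kruskal.test()] presenting the interface the stage-level
#' comparisons use.
#'
#' @param groups A list of >= 2 non-empty numeric vectors.
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("empty group", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Steel-Dwass all-pairs comparisons
#'
#' Nonparametric analogue of Tukey's HSD, controlling the familywise error
#' over all unordered group pairs. For each pair only the two groups are
#' pooled and midranked; the tie-corrected standardised Mann-Whitney
#' statistic z is referred to the studentized range distribution with k
#' groups and infinite degrees of freedom:
#' `p = P(Q_{k,Inf} >= sqrt(2) * |z|)` (the standard large-sample form).
#'
#' @param groups A named list of >= 2 numeric vectors, each of length >= 2.
#' @return Data.frame with `group_a`, `group_b`, `statistic` (z) and
#'   `p_value`, one row per unordered pair.
#' @export
steel_dwass <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L))
    stop("every group needs >= 2 values (violated by: ",
         paste(names(groups)[sizes < 2L], collapse = ", "), ")",
         call. = FALSE)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- as.character(seq_len(k))
  cmb <- utils::combn(k, 2L)
  out <- lapply(seq_len(ncol(cmb)), function(j) {
    ia <- cmb[1L, j]; ib <- cmb[2L, j]
    a <- groups[[ia]]; b <- groups[[ib]]
    na <- length(a); nb <- length(b); N <- na + nb
    r <- rank(c(a, b))
    U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    V <- na * nb / 12 * ((N + 1) - .tie_term(r) / (N * (N - 1)))
    z <- if (V > 0) (U - na * nb / 2) / sqrt(V) else 0
    p <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    data.frame(group_a = names(groups)[ia], group_b = names(groups)[ib],
               statistic = z, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
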