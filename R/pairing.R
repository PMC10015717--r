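#' Construct a pair set
#'
#' A pair set is the explicit list of unordered sample pairs a variation or
#' variance statistic is averaged over. No self pairs, no duplicated
#' unordered pairs.
#'
#' @param sample_a,sample_b Character vectors of sample ids.
#' @param kind One of `"sibling"`, `"technical"`, `"hybrid_all_pairs"`,
#'   `"cross_population"`.
#' @param stage Stage label the pairs belong to.
#' @return A data.frame of class `pair_set` with columns `sample_a`,
#'   `sample_b` and attributes `kind` and `stage`.
#' @export
pair_set <- function(sample_a, sample_b,
                     kind = c("sibling", "technical", "hybrid_all_pairs",
                              "cross_population"),
                     stage = NA_character_) {
  kind <- match.arg(kind)
  if (length(sample_a) != length(sample_b))
    stop("sample_a and sample_b differ in length", call. = FALSE)
  if (any(sample_a == sample_b))
    stop("self-pair (i,i) not allowed", call. = FALSE)
  key <- paste(pmin(sample_a, sample_b), pmax(sample_a, sample_b))
  if (anyDuplicated(key))
    stop("duplicate unordered pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  structure(
    data.frame(sample_a = sample_a, sample_b = sample_b,
               stringsAsFactors = FALSE),
    kind = kind, stage = as.character(stage),
    class = c("pair_set", "data.frame"))
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> kind=%s stage=%s n=%d\n",
              attr(x, "kind"), attr(x, "stage"), nrow(x)))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

.meta_at <- function(meta, stage, group = NULL) {
  sel <- meta$stage == as.character(stage)
  if (!is.null(group)) sel <- sel & meta$group == group
  meta[sel & !is.na(sel), , drop = FALSE]
}

#' Sex-matched sibling pairs
#'
#' Forms within-sibling-group, sex-matched pairs among the inbred (F0)
#' embryos of one stage. By default all sex-matched pairs a sibling group
#' admits are formed; with `disjoint = TRUE` members are consumed
#' sequentially so every sample appears in at most one pair. Samples with
#' unknown sex are never matched.
#'
#' @param meta Sample metadata.
#' @param stage Stage label.
#' @param group Group label of the inbred generation (default `"F0"`).
#' @param disjoint Restrict to disjoint pairs (default FALSE).
#' @return A `pair_set` of kind `"sibling"`.
#' @export
sibling_pairs <- function(meta, stage, group = "F0", disjoint = FALSE) {
  md <- .meta_at(meta, stage, group)
  if (nrow(md) == 0L)
    stop("no ", group, " samples at stage ", stage, call. = FALSE)
  usable <- !is.na(md$sex) & !is.na(md$sibling_group)
  md <- md[usable, , drop = FALSE]
  a <- character(0); b <- character(0)
  if (nrow(md) >= 2L) {
    cells <- split(md$sample_id, list(md$sibling_group, md$sex), drop = TRUE)
    for (ids in cells) {
      ids <- sort(ids)
      if (length(ids) < 2L) next
      if (disjoint) {
        n2 <- (length(ids) %/% 2L) * 2L
        a <- c(a, ids[seq(1L, n2, by = 2L)])
        b <- c(b, ids[seq(2L, n2, by = 2L)])
      } else {
        cmb <- utils::combn(ids, 2L)
        a <- c(a, cmb[1L, ]); b <- c(b, cmb[2L, ])
      }
    }
  }
  if (length(a) == 0L) {
    n_unsexed <- sum(!usable)
    stop("no valid sibling pair at stage ", stage, ": ",
         if (n_unsexed) paste0(n_unsexed, " sample(s) with unknown ",
                               "sex/sibling_group; "),
         "remaining groups hold no two sex-matched members", call. = FALSE)
  }
  pair_set(a, b, kind = "sibling", stage = stage)
}

#' All unordered pairs within a group at a stage
#'
#' For n samples, returns the n(n-1)/2 unordered pairs; this is the design
#' used to quantify expression diversity among hybrid descendants.
#'
#' @param meta Sample metadata.
#' @param stage Stage label.
#' @param group Group label (e.g. `"F3"`).
#' @return A `pair_set` of kind `"hybrid_all_pairs"`.
#' @export
all_pairs <- function(meta, stage, group) {
  md <- .meta_at(meta, stage, group)
  if (nrow(md) < 2L)
    stop("need at least 2 ", group, " samples at stage ", stage,
         " (found ", nrow(md), ")", call. = FALSE)
  ids <- sort(md$sample_id)
  cmb <- utils::combn(ids, 2L)
  pair_set(cmb[1L, ], cmb[2L, ], kind = "hybrid_all_pairs", stage = stage)
}

#' Sex-matched cross-population pairs
#'
#' Full sex-matched bipartite product between two populations at one stage:
#' every pair of same-sex individuals spanning the populations. Samples with
#' unknown sex are excluded.
#'
#' @param meta Sample metadata.
#' @param stage Stage label.
#' @param pop_a,pop_b Population group labels.
#' @return A `pair_set` of kind `"cross_population"`.
#' @export
cross_population_pairs <- function(meta, stage, pop_a, pop_b) {
  ma <- .meta_at(meta, stage, pop_a)
  mb <- .meta_at(meta, stage, pop_b)
  if (nrow(ma) == 0L || nrow(mb) == 0L)
    stop("population(s) missing at stage ", stage, ": ",
         paste(c(pop_a, pop_b)[c(nrow(ma) == 0L, nrow(mb) == 0L)],
               collapse = ", "), call. = FALSE)
  a <- character(0); b <- character(0)
  for (sx in intersect(unique(ma$sex[!is.na(ma$sex)]),
                       unique(mb$sex[!is.na(mb$sex)]))) {
    ia <- sort(ma$sample_id[!is.na(ma$sex) & ma$sex == sx])
    ib <- sort(mb$sample_id[!is.na(mb$sex) & mb$sex == sx])
    grid <- expand.grid(a = ia, b = ib, stringsAsFactors = FALSE)
    a <- c(a, grid$a); b <- c(b, grid$b)
  }
  if (length(a) == 0L)
    stop("no sex-matched cross-population pair at stage ", stage,
         call. = FALSE)
  pair_set(a, b, kind = "cross_population", stage = stage)
}

#' Technical-replicate pairs
#'
#' All unordered pairs among the technical replicates of each replicated
#' condition at a stage (four replicates give the six combinations the
#' technical-error estimate is built from).
#'
#' @param meta Sample metadata.
#' @param stage Stage label.
#' @param group Group label of the technical replicates (default
#'   `"technical"`).
#' @return A named list of `pair_set`s of kind `"technical"`, one per
#'   replicated condition.
#' @export
technical_pairs <- function(meta, stage, group = "technical") {
  md <- .meta_at(meta, stage, group)
  md <- md[!is.na(md$replicate_of), , drop = FALSE]
  if (nrow(md) < 2L)
    stop("no technical replicates at stage ", stage, call. = FALSE)
  out <- lapply(split(md$sample_id, md$replicate_of), function(ids) {
    if (length(ids) < 2L) return(NULL)
    cmb <- utils::combn(sort(ids), 2L)
    pair_set(cmb[1L, ], cmb[2L, ], kind = "technical", stage = stage)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L)
    stop("no replicated condition with >= 2 technical replicates at stage ",
         stage, call. = FALSE)
  out
}

#' Serialize pair sets to TSV
#' @param pairs A `pair_set` or list of them.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  if (inherits(pairs, "pair_set")) pairs <- list(pairs)
  rows <- do.call(rbind, lapply(pairs, function(p)
    data.frame(kind = attr(p, "kind"), stage = attr(p, "stage"),
               sample_a = p$sample_a, sample_b = p$sample_b,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
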