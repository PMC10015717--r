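.subset_expr <- function(m, genes = NULL, samples = NULL) {
  v <- unclass(m)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, units = expr_units(m))
}

.as_log10 <- function(expression) {
  if (identical(expr_units(expression), "tpm")) log_transform(expression)
  else expression
}

.ids_at <- function(metadata, stage, group)
  metadata$sample_id[metadata$stage == stage & metadata$group == group]

.say <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Gene-level stability-versus-diversity analysis
#'
#' Runs, for each developmental stage, the full gene-level pipeline:
#' log transform, low-expression exclusion per dataset (gene universe =
#' intersection of the inbred and descendant sets), technical-error gene
#' filter, optional differential-mean selection, per-gene sibling variation
#' and descendant all-pairs diversity with running-median correction, and
#' the Spearman test of no correlation between corrected variation and
#' corrected diversity.
#'
#' @param expression An `expr_matrix` (TPM or log10 scale).
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param stages Stage labels to process; default: all stages with both
#'   groups present.
#' @param threshold Low-expression cutoff on the log10 scale.
#' @param alpha Per-gene filter level.
#' @param window Running-median window (odd).
#' @param tech_mode `"raw"` (six replicate-pair differences per condition)
#'   or `"averaged"` (one averaged value per condition; needs >= 2
#'   conditions).
#' @param use_technical_filter Apply the technical-error filter when
#'   technical replicates exist (default TRUE).
#' @param apply_differential_mean Additionally keep only genes with
#'   significantly different mean expression between the two generations
#'   (off by default; see the methods vignette).
#' @param f0_group,f3_group Metadata group labels.
#' @param outdir Optional directory; when given, all intermediates and the
#'   correlation report are written as TSV.
#' @param verbose Log gene counts after every filter.
#' @return List with one element per processed stage (`f0`/`f3` variation
#'   tables, `correlation`, `counts`, `filter` report) plus a `correlations`
#'   summary data.frame.
#' @export
run_gene_level <- function(expression, metadata, stages = NULL,
                           threshold = 0.1, alpha = 0.01, window = 501L,
                           tech_mode = c("raw", "averaged"),
                           use_technical_filter = TRUE,
                           apply_differential_mean = FALSE,
                           f0_group = "F0", f3_group = "F3",
                           outdir = NULL, verbose = FALSE) {
  tech_mode <- match.arg(tech_mode)
  m <- .as_log10(expression)
  if (is.null(stages)) stages <- unique(metadata$stage)
  results <- list()
  for (st in stages) {
    f0_ids <- .ids_at(metadata, st, f0_group)
    f3_ids <- .ids_at(metadata, st, f3_group)
    if (length(f0_ids) < 2L || length(f3_ids) < 2L) {
      warning("stage ", st, " skipped: missing ",
              if (length(f0_ids) < 2L) f0_group else f3_group, " samples",
              call. = FALSE)
      next
    }
    genes_f0 <- rownames(filter_low_expression(.subset_expr(m, samples = f0_ids),
                                               threshold))
    genes_f3 <- rownames(filter_low_expression(.subset_expr(m, samples = f3_ids),
                                               threshold))
    universe <- intersect(genes_f0, genes_f3)
    .say(verbose, "stage %s: %d/%d genes expressed (F0/F3), universe %d",
         st, length(genes_f0), length(genes_f3), length(universe))
    mu_st <- .subset_expr(m, genes = universe)
    sib <- sibling_pairs(metadata, st, group = f0_group)
    filt <- NULL
    genes_used <- universe
    has_tech <- any(metadata$stage == st & metadata$group == "technical")
    if (use_technical_filter && has_tech) {
      tp <- technical_pairs(metadata, st)
      sib_d <- pair_differences(mu_st, sib)
      tech_d <- technical_diffs(mu_st, tp, mode = tech_mode)
      filt <- technical_error_filter(sib_d, tech_d, alpha = alpha)
      genes_used <- filt$gene_id[filt$passed]
      .say(verbose, "stage %s: technical-error filter keeps %d/%d genes",
           st, length(genes_used), length(universe))
    }
    if (apply_differential_mean) {
      dm <- differential_mean_filter(.subset_expr(m, universe, f0_ids),
                                     .subset_expr(m, universe, f3_ids),
                                     alpha = alpha)
      genes_used <- intersect(genes_used, dm$gene_id[dm$passed])
      filt <- rbind(filt, dm)
      .say(verbose, "stage %s: differential-mean filter leaves %d genes",
           st, length(genes_used))
    }
    if (length(genes_used) < 3L) {
      warning("stage ", st, " skipped: fewer than 3 genes survive filtering",
              call. = FALSE)
      next
    }
    mg <- .subset_expr(m, genes = genes_used)
    tab_f0 <- running_median_correction(pairwise_variation(mg, sib), window)
    f3p <- all_pairs(metadata, st, f3_group)
    tab_f3 <- running_median_correction(pairwise_variation(mg, f3p), window)
    ct <- spearman_test(tab_f0$corrected_variation, tab_f3$corrected_variation)
    .say(verbose, "stage %s: rho = %.3f (p = %.3g, n = %d)",
         st, ct$rho, ct$p.value, ct$n)
    results[[st]] <- list(
      f0 = tab_f0, f3 = tab_f3, correlation = ct, filter = filt,
      counts = c(n_genes = nrow(m), n_f0_expressed = length(genes_f0),
                 n_f3_expressed = length(genes_f3),
                 n_universe = length(universe), n_used = length(genes_used)))
  }
  if (length(results) == 0L)
    stop("no stage could be processed", call. = FALSE)
  correlations <- do.call(rbind, lapply(names(results), function(st)
    data.frame(stage = st, rho = results[[st]]$correlation$rho,
               p_value = results[[st]]$correlation$p.value,
               n_genes = results[[st]]$correlation$n,
               stringsAsFactors = FALSE)))
  out <- list(stages = results, correlations = correlations,
              window = as.integer(window))
  if (!is.null(outdir)) .write_gene_level(out, outdir)
  out
}

.write_gene_level <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(out$stages)) {
    s <- out$stages[[st]]
    write_variation(s$f0, file.path(outdir,
                                    sprintf("variation_f0_%s.tsv", st)))
    write_variation(s$f3, file.path(outdir,
                                    sprintf("variation_f3_%s.tsv", st)))
    if (!is.null(s$filter))
      utils::write.table(s$filter,
                         file.path(outdir, sprintf("filters_%s.tsv", st)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  correlations <- out$correlations
  correlations$window <- out$window
  utils::write.table(correlations, file.path(outdir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Hybrid-descendant versus wild-population diversity
#'
#' Per stage: corrected all-pairs diversity among the descendants against
#' corrected sex-matched cross-population diversity between two wild
#' populations, compared by the Spearman test of no correlation on the
#' gene-universe intersection.
#'
#' @inheritParams run_gene_level
#' @param pop_a,pop_b Wild population group labels.
#' @return As [run_gene_level()]: per-stage tables (`f3`, `wild`) and a
#'   `correlations` summary.
#' @export
run_wild_comparison <- function(expression, metadata, stages = NULL,
                                pop_a = "Kasasa", pop_b = "Oura",
                                threshold = 0.1, alpha = 0.01,
                                window = 501L, f3_group = "F3",
                                outdir = NULL, verbose = FALSE) {
  m <- .as_log10(expression)
  if (is.null(stages)) stages <- unique(metadata$stage)
  results <- list()
  for (st in stages) {
    f3_ids <- .ids_at(metadata, st, f3_group)
    wa <- .ids_at(metadata, st, pop_a); wb <- .ids_at(metadata, st, pop_b)
    if (length(f3_ids) < 2L || length(wa) < 1L || length(wb) < 1L) {
      warning("stage ", st, " skipped: missing F3 or wild samples",
              call. = FALSE)
      next
    }
    genes_f3 <- rownames(filter_low_expression(
      .subset_expr(m, samples = f3_ids), threshold))
    genes_w <- rownames(filter_low_expression(
      .subset_expr(m, samples = c(wa, wb)), threshold))
    universe <- intersect(genes_f3, genes_w)
    if (length(universe) < 3L) {
      warning("stage ", st, " skipped: gene universe too small",
              call. = FALSE)
      next
    }
    mg <- .subset_expr(m, genes = universe)
    f3p <- all_pairs(metadata, st, f3_group)
    wp <- cross_population_pairs(metadata, st, pop_a, pop_b)
    tab_f3 <- running_median_correction(pairwise_variation(mg, f3p), window)
    tab_w <- running_median_correction(pairwise_variation(mg, wp), window)
    ct <- spearman_test(tab_f3$corrected_variation, tab_w$corrected_variation)
    .say(verbose, "stage %s: F3-vs-wild rho = %.3f (p = %.3g, n = %d)",
         st, ct$rho, ct$p.value, ct$n)
    results[[st]] <- list(f3 = tab_f3, wild = tab_w, correlation = ct,
                          counts = c(n_universe = length(universe),
                                     n_wild_pairs = nrow(wp)))
  }
  if (length(results) == 0L)
    stop("no stage could be processed", call. = FALSE)
  correlations <- do.call(rbind, lapply(names(results), function(st)
    data.frame(stage = st, rho = results[[st]]$correlation$rho,
               p_value = results[[st]]$correlation$p.value,
               n_genes = results[[st]]$correlation$n,
               stringsAsFactors = FALSE)))
  out <- list(stages = results, correlations = correlations,
              window = as.integer(window))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (st in names(results)) {
      write_variation(results[[st]]$f3,
                      file.path(outdir, sprintf("diversity_f3_%s.tsv", st)))
      write_variation(results[[st]]$wild,
                      file.path(outdir, sprintf("diversity_wild_%s.tsv", st)))
    }
    utils::write.table(correlations,
                       file.path(outdir, "correlations_wild.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Stage-level stability and diversity comparison
#'
#' Computes the per-pair whole-transcriptome variance V for every sibling
#' pair (stability, inbred generation) and every descendant pair
#' (diversity) at each stage, then compares stages per group with a
#' Kruskal-Wallis omnibus test followed by Steel-Dwass all-pairs
#' comparisons. The gene set per group and stage is the group's
#' low-expression-filtered set, optionally intersected with the
#' technical-error filter (default), or a common set across groups.
#'
#' @inheritParams run_gene_level
#' @param common_gene_set Force one gene set (the intersection) for both
#'   groups at each stage.
#' @return List with one element per group, each holding the per-pair
#'   variance `table`, the `omnibus` Kruskal-Wallis result, and the
#'   `pairwise` Steel-Dwass table.
#' @export
run_stage_level <- function(expression, metadata, stages = NULL,
                            threshold = 0.1, alpha = 0.01,
                            tech_mode = c("raw", "averaged"),
                            use_technical_filter = TRUE,
                            common_gene_set = FALSE,
                            f0_group = "F0", f3_group = "F3",
                            outdir = NULL, verbose = FALSE) {
  tech_mode <- match.arg(tech_mode)
  m <- .as_log10(expression)
  if (is.null(stages)) stages <- unique(metadata$stage)
  rows <- list()
  for (st in stages) {
    f0_ids <- .ids_at(metadata, st, f0_group)
    f3_ids <- .ids_at(metadata, st, f3_group)
    if (length(f0_ids) < 2L && length(f3_ids) < 2L) {
      warning("stage ", st, " skipped: no usable group", call. = FALSE)
      next
    }
    tech_passed <- NULL
    has_tech <- any(metadata$stage == st & metadata$group == "technical")
    if (use_technical_filter && has_tech && length(f0_ids) >= 2L) {
      sib <- sibling_pairs(metadata, st, group = f0_group)
      genes_f0 <- rownames(filter_low_expression(
        .subset_expr(m, samples = f0_ids), threshold))
      mu_st <- .subset_expr(m, genes = genes_f0)
      filt <- technical_error_filter(
        pair_differences(mu_st, sib),
        technical_diffs(mu_st, technical_pairs(metadata, st),
                        mode = tech_mode), alpha = alpha)
      tech_passed <- filt$gene_id[filt$passed]
    }
    gene_set <- function(ids) {
      g <- rownames(filter_low_expression(.subset_expr(m, samples = ids),
                                          threshold))
      if (!is.null(tech_passed)) g <- intersect(g, tech_passed)
      g
    }
    gs <- list()
    if (length(f0_ids) >= 2L) gs[[f0_group]] <- gene_set(f0_ids)
    if (length(f3_ids) >= 2L) gs[[f3_group]] <- gene_set(f3_ids)
    if (common_gene_set && length(gs) == 2L)
      gs <- lapply(gs, function(.) Reduce(intersect, gs))
    if (length(f0_ids) >= 2L) {
      sib <- sibling_pairs(metadata, st, group = f0_group)
      rows[[length(rows) + 1L]] <-
        stage_variances(m, sib, genes = gs[[f0_group]], group = f0_group)
    }
    if (length(f3_ids) >= 2L) {
      f3p <- all_pairs(metadata, st, f3_group)
      rows[[length(rows) + 1L]] <-
        stage_variances(m, f3p, genes = gs[[f3_group]], group = f3_group)
    }
    .say(verbose, "stage %s: %s", st,
         paste(vapply(gs, length, integer(1)), collapse = "/"))
  }
  if (length(rows) == 0L)
    stop("no stage could be processed", call. = FALSE)
  tab <- do.call(rbind, rows)
  out <- list()
  for (grp in unique(tab$group)) {
    sub <- tab[tab$group == grp, , drop = FALSE]
    groups <- split(sub$v, factor(sub$stage, levels = unique(sub$stage)))
    if (length(groups) < 2L)
      stop("need >= 2 stages with pairs in group ", grp, call. = FALSE)
    out[[grp]] <- list(table = sub,
                       omnibus = kruskal_wallis(groups),
                       pairwise = steel_dwass(groups))
    .say(verbose, "%s: Kruskal-Wallis p = %.3g", grp,
         out[[grp]]$omnibus$p.value)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(outdir, "stage_variances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pw <- do.call(rbind, lapply(names(out), function(g)
      cbind(group = g, out[[g]]$pairwise)))
    utils::write.table(pw, file.path(outdir, "stage_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    om <- do.call(rbind, lapply(names(out), function(g)
      data.frame(group = g, H = out[[g]]$omnibus$statistic,
                 df = out[[g]]$omnibus$df,
                 p_value = out[[g]]$omnibus$p.value)))
    utils::write.table(om, file.path(outdir, "stage_omnibus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Re-derive the gene-level report from serialized intermediates
#'
#' Audit step: reads the variation tables written by [run_gene_level()],
#' recomputes the corrected values from the raw columns and the Spearman
#' correlations from the corrected columns, and checks them against the
#' serialized `correlations.tsv`.
#'
#' @param outdir Directory written by `run_gene_level(..., outdir = )`.
#' @param tol Numeric tolerance.
#' @return TRUE invisibly on success; stops with a message on mismatch.
#' @export
verify_gene_level <- function(outdir, tol = 1e-8) {
  rep_file <- file.path(outdir, "correlations.tsv")
  rep <- utils::read.table(rep_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rep))) {
    st <- rep$stage[i]
    f0 <- utils::read.table(file.path(outdir,
                                      sprintf("variation_f0_%s.tsv", st)),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    f3 <- utils::read.table(file.path(outdir,
                                      sprintf("variation_f3_%s.tsv", st)),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (tb in list(f0, f3)) {
      rc <- running_median_correction(tb, window = rep$window[i])
      if (max(abs(rc$corrected_variation - tb$corrected_variation)) > tol)
        stop("stage ", st, ": corrected values do not re-derive from raw",
             call. = FALSE)
    }
    ct <- spearman_test(f0$corrected_variation, f3$corrected_variation)
    if (abs(ct$rho - rep$rho[i]) > tol ||
        abs(ct$p.value - rep$p_value[i]) > tol)
      stop("stage ", st, ": correlation does not re-derive from tables",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Re-derive the stage-level report from serialized intermediates
#'
#' Reads `stage_variances.tsv` and recomputes the Kruskal-Wallis and
#' Steel-Dwass results, checking them against the serialized reports.
#'
#' @param outdir Directory written by `run_stage_level(..., outdir = )`.
#' @param tol Numeric tolerance.
#' @return TRUE invisibly on success; stops with a message on mismatch.
#' @export
verify_stage_level <- function(outdir, tol = 1e-8) {
  tab <- utils::read.table(file.path(outdir, "stage_variances.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  pw <- utils::read.table(file.path(outdir, "stage_pairwise.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  om <- utils::read.table(file.path(outdir, "stage_omnibus.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tab$stage <- as.character(tab$stage)
  pw$group_a <- as.character(pw$group_a)
  pw$group_b <- as.character(pw$group_b)
  for (grp in unique(tab$group)) {
    sub <- tab[tab$group == grp, ]
    groups <- split(sub$v, factor(sub$stage, levels = unique(sub$stage)))
    kw <- kruskal_wallis(groups)
    if (abs(kw$p.value - om$p_value[om$group == grp]) > tol)
      stop("group ", grp, ": omnibus p does not re-derive", call. = FALSE)
    sd_new <- steel_dwass(groups)
    sd_old <- pw[pw$group == grp, ]
    key <- function(d) paste(d$group_a, d$group_b)
    sd_old <- sd_old[match(key(sd_new), key(sd_old)), ]
    if (max(abs(sd_new$p_value - sd_old$p_value)) > tol)
      stop("group ", grp, ": pairwise p does not re-derive", call. = FALSE)
  }
  invisible(TRUE)
}
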