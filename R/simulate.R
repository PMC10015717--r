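#' Generator configuration for the sibling / hybrid / wild design
#'
#' Defines a synthetic study with the statistical structure the analysis
#' assumes: four developmental stages; sex-matched inbred sibling pairs
#' with technical replicates; hybrid descendant (F3) embryos compared in
#' all pairs; two wild populations compared through sex-matched
#' cross-population pairs; a mean-dependent component of expression
#' variability (noise floor) so the running-median correction has work to
#' do; a stage-dependent biological noise scale with one minimal-variance
#' stage (the hourglass); and a planted rank correlation `rho_star` between
#' per-gene stability in the inbred generation and per-gene diversity in
#' the descendants.
#'
#' Per gene j the model on the log10(TPM+1) scale is
#' `x = mu_j + s_stage * scale_j * eps + sigma_tech * eps'`, truncated at 0,
#' where the per-gene biological difference scale is additive in its two
#' components: `scale_j = floor(mu_j) + bio_scale * stability_j` for inbred
#' siblings and `floor(mu_j) + bio_scale * inflation_j` for descendants and
#' wild fish, with `floor(mu) = noise_floor_intercept +
#' noise_floor_slope * mu`. `stability_j` and `inflation_j` are mean-one
#' log-normals coupled by a Gaussian copula so that their Spearman
#' correlation equals `rho_star` exactly (`r = 2 sin(pi * rho_star / 6)`).
#' The additive floor makes the running-median correction separable: the
#' floor cancels and corrected values rank genes by their stability
#' (inbred) or inflation (descendants) component.
#'
#' @param n_genes Number of genes.
#' @param stages Stage labels.
#' @param stage_scale Per-stage multiplier of the biological noise scale;
#'   the default profile has the third stage (the putative phylotypic
#'   stage) at half the scale of the others.
#' @param n_sibling_pairs,n_f3,n_wild Per-stage design sizes: sex-matched
#'   inbred sibling pairs, hybrid embryos, wild individuals per population.
#' @param n_tech_replicates,n_tech_conditions Technical replicates per
#'   replicated condition and number of replicated conditions per stage.
#' @param mean_shape,mean_scale Gamma parameters of the per-gene mean
#'   log10(TPM+1) expression level.
#' @param frac_below_detection Fraction of genes below detection (all
#'   samples at 0 TPM).
#' @param noise_floor_intercept,noise_floor_slope Mean-dependent component
#'   of the per-gene difference scale (log10 units and units per log10
#'   unit).
#' @param bio_scale Scale of the gene-specific biological component
#'   (log10 units).
#' @param stability_sdlog SD of log stability/inflation across genes.
#' @param rho_star Planted Spearman correlation between stability and
#'   inflation, in [-1, 1].
#' @param sigma_tech Technical noise SD (log10 units).
#' @param wild_offset_sd SD of the per-gene mean offset between the two
#'   wild populations (log10 units).
#' @param noise `"gaussian"` (default) or `"t"` (scaled Student t,
#'   heavier-tailed robustness option).
#' @param t_df Degrees of freedom for `noise = "t"`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 10000L,
                             stages = c("15", "23.5", "28", "hatching"),
                             stage_scale = c(1, 1, 0.5, 1),
                             n_sibling_pairs = c(23L, 24L, 25L, 13L),
                             n_tech_replicates = 4L,
                             n_tech_conditions = 1L,
                             n_f3 = c(5L, 6L, 6L, 6L),
                             n_wild = c(4L, 4L, 4L, 2L),
                             mean_shape = 2, mean_scale = 0.75,
                             frac_below_detection = 0.10,
                             noise_floor_intercept = 0.02,
                             noise_floor_slope = 0.12,
                             bio_scale = 0.7,
                             stability_sdlog = 1.3,
                             rho_star = 0.4,
                             sigma_tech = 0.03,
                             wild_offset_sd = 0.08,
                             noise = c("gaussian", "t"),
                             t_df = 5,
                             seed = 1L) {
  noise <- match.arg(noise)
  ns <- length(stages)
  rec <- function(x) if (length(x) == 1L) rep(x, ns) else x
  stage_scale <- rec(stage_scale); n_sibling_pairs <- rec(n_sibling_pairs)
  n_f3 <- rec(n_f3); n_wild <- rec(n_wild)
  if (length(stage_scale) != ns || length(n_sibling_pairs) != ns ||
      length(n_f3) != ns || length(n_wild) != ns)
    stop("per-stage vectors must match the number of stages", call. = FALSE)
  if (anyDuplicated(stages)) stop("duplicate stage labels", call. = FALSE)
  if (abs(rho_star) > 1) stop("rho_star must lie in [-1, 1]", call. = FALSE)
  stopifnot(n_genes >= 1, all(stage_scale >= 0), all(n_sibling_pairs >= 0),
            all(n_f3 >= 0), all(n_wild >= 0), n_tech_replicates >= 0,
            n_tech_conditions >= 0, sigma_tech >= 0, bio_scale >= 0,
            stability_sdlog >= 0, frac_below_detection >= 0,
            frac_below_detection < 1, wild_offset_sd >= 0)
  structure(as.list(environment())[c(
    "n_genes", "stages", "stage_scale", "n_sibling_pairs",
    "n_tech_replicates", "n_tech_conditions", "n_f3", "n_wild",
    "mean_shape", "mean_scale", "frac_below_detection",
    "noise_floor_intercept", "noise_floor_slope", "bio_scale",
    "stability_sdlog", "rho_star", "sigma_tech", "wild_offset_sd",
    "noise", "t_df", "seed")], class = "generator_config")
}

#' Simulate a full study
#'
#' Generates the expression matrix (TPM units), the sample metadata, and a
#' per-gene truth record (mean level, stability and inflation components,
#' total difference scales, wild offset) from a [generator_config()].
#'
#' @param cfg A `generator_config`.
#' @param seed Overrides `cfg$seed` when given.
#' @return List with elements `expression` (`expr_matrix`, TPM),
#'   `metadata` (data.frame) and `truth` (data.frame with attributes
#'   `rho_star`, `stages`, `stage_scale`).
#' @export
simulate_study <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  G <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(G))
  ns <- length(cfg$stages)

  reps <- if (cfg$noise == "t") {
    function(n) stats::rt(n, df = cfg$t_df) / sqrt(cfg$t_df / (cfg$t_df - 2))
  } else stats::rnorm

  mu <- stats::rgamma(G, shape = cfg$mean_shape, scale = cfg$mean_scale)
  below <- seq_len(G) <= round(cfg$frac_below_detection * G)
  below <- sample(below)           # which genes are below detection
  mu[below] <- 0
  delta <- stats::rnorm(G, 0, cfg$wild_offset_sd)   # Oura - Kasasa offset
  r_cop <- 2 * sin(pi * cfg$rho_star / 6)
  z1 <- stats::rnorm(G)
  z2 <- r_cop * z1 + sqrt(1 - r_cop^2) * stats::rnorm(G)
  sl <- cfg$stability_sdlog
  stability <- exp(sl * z1 - sl^2 / 2)   # mean-one log-normals
  inflation <- exp(sl * z2 - sl^2 / 2)
  floorv <- cfg$noise_floor_intercept + cfg$noise_floor_slope * mu
  tau <- floorv + cfg$bio_scale * stability   # inbred difference scale
  div <- floorv + cfg$bio_scale * inflation   # descendant/wild scale

  cols <- list(); meta <- list()
  draw <- function(center, scale, n_col, id_fun, md_fun) {
    if (n_col == 0L) return(invisible(NULL))
    x <- center + matrix(reps(G * n_col), G, n_col) * scale +
      matrix(stats::rnorm(G * n_col, 0, cfg$sigma_tech), G, n_col)
    x[below, ] <- 0
    x <- pmin(pmax(x, 0), 6)   # log10 scale is bounded: TPM <= 1e6
    colnames(x) <- id_fun(seq_len(n_col))
    cols[[length(cols) + 1L]] <<- x
    meta[[length(meta) + 1L]] <<- md_fun(colnames(x))
  }

  for (si in seq_len(ns)) {
    st <- cfg$stages[si]; sc <- cfg$stage_scale[si]
    np <- cfg$n_sibling_pairs[si]
    if (np > 0L) {
      sexes <- rep(c("F", "M"), length.out = np)
      for (half in c("a", "b"))
        draw(mu, sc * tau, np,
             function(p) sprintf("F0_%s_p%02d%s", st, p, half),
             function(ids) data.frame(
               sample_id = ids, stage = st, group = "F0", sex = sexes,
               sibling_group = sprintf("%s_p%02d", st, seq_len(np)),
               replicate_of = NA_character_, stringsAsFactors = FALSE))
    }
    if (cfg$n_tech_conditions > 0L && cfg$n_tech_replicates > 0L) {
      for (cc in seq_len(cfg$n_tech_conditions)) {
        cond <- sprintf("T_%s_c%d", st, cc)
        base <- mu + reps(G) * sc * tau   # one embryo, measured repeatedly
        draw(base, 0, cfg$n_tech_replicates,
             function(r) sprintf("%s_r%d", cond, r),
             function(ids) data.frame(
               sample_id = ids, stage = st, group = "technical",
               sex = NA_character_, sibling_group = NA_character_,
               replicate_of = cond, stringsAsFactors = FALSE))
      }
    }
    if (cfg$n_f3[si] > 0L) {
      nf <- cfg$n_f3[si]
      draw(mu, sc * div, nf,
           function(e) sprintf("F3_%s_e%d", st, e),
           function(ids) data.frame(
             sample_id = ids, stage = st, group = "F3",
             sex = rep(c("F", "M"), length.out = nf),
             sibling_group = NA_character_, replicate_of = NA_character_,
             stringsAsFactors = FALSE))
    }
    if (cfg$n_wild[si] > 0L) {
      nw <- cfg$n_wild[si]
      for (pop in c("Kasasa", "Oura")) {
        center <- if (pop == "Oura") mu + delta else mu
        draw(center, sc * div, nw,
             function(i) sprintf("%s_%s_i%d", toupper(substr(pop, 1, 3)),
                                 st, i),
             function(ids) data.frame(
               sample_id = ids, stage = st, group = pop, sex = "F",
               sibling_group = NA_character_, replicate_of = NA_character_,
               stringsAsFactors = FALSE))
      }
    }
  }

  x <- do.call(cbind, cols)
  rownames(x) <- gene_ids
  tpm <- 10^x - 1
  tpm[tpm < 0] <- 0                 # guard rounding at the x = 0 boundary
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  truth <- data.frame(gene_id = gene_ids, mu = mu, below_detection = below,
                      stability = stability, inflation = inflation,
                      tau = tau, div = div, wild_offset = delta,
                      stringsAsFactors = FALSE)
  attr(truth, "rho_star") <- cfg$rho_star
  attr(truth, "stages") <- cfg$stages
  attr(truth, "stage_scale") <- cfg$stage_scale
  list(expression = expression_matrix(tpm, units = "tpm"),
       metadata = metadata, truth = truth)
}

#' Write a simulated study to a directory
#'
#' Writes `expression.tsv`, `metadata.tsv`, `truth.tsv` and a one-line
#' `config.tsv` so a simulated study can be re-read through the standard
#' input path.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
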