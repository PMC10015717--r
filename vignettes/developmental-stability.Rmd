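---
title: "Measuring developmental stability and evolutionary diversity of embryonic transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring developmental stability and evolutionary diversity of embryonic transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Developmental stability is the ability of a genotype to produce the same
phenotype under the same environment. For gene expression it can be
measured directly: raise highly inbred sibling embryos together, quantify
each gene in each embryo, and treat the expression difference between
sex-matched siblings as the gene's instability. The scientific question
this package addresses is whether that stability predicts *evolutionary*
behaviour: do genes (and developmental stages) that are stable in an
ancestral, isogenic generation stay conserved once genetic variation is
re-introduced — in hybrid descendants of a cross between distant
populations, and between wild populations that diverged naturally?

The design the package models has four components per developmental
stage:

* **F0 inbred sibling pairs** (13–25 sex-matched pairs per stage, two
  embryos each) measuring stability;
* **technical replicates** (4 libraries of one embryo, giving the 6
  replicate-pair combinations) measuring the technical noise floor;
* **F3 hybrid embryos** (5–6 per stage, compared in all
  $n(n-1)/2$ pairs) measuring diversity after two generations of
  intercrossing;
* **two wild populations** (2–4 fish each, compared through all
  sex-matched cross-population pairs) anchoring the laboratory cross to
  natural divergence.

Four stages are modelled, one of which (stage 28, the putative
phylotypic stage) is expected to be the most stable — the
developmental-hourglass profile.

## Statistics implemented

All analyses work on $x_j^i = \log_{10}(\mathrm{TPM}+1)$ for gene $j$ in
individual $i$. Genes with $x_j^i < 0.1$ in *every* individual of a
dataset are excluded; the analysis is insensitive to this cutoff over
0–1.5.

**Per-gene variation / diversity.** For a pair set $P$ (siblings, all F3
pairs, or cross-population pairs),
$$\mathrm{var}_j = \frac{1}{|P|}\sum_{(i,k)\in P} |x_j^i - x_j^k|.$$

**Technical-error filter.** Per gene, a one-sided Wilcoxon rank-sum test
asks whether the sibling differences are stochastically larger than the
technical-replicate differences ($\alpha = 0.01$); only genes whose
biological signal exceeds the measurement floor are analysed further.

**Running-median correction.** Absolute expression level confounds
variation measures, so genes are sorted by mean expression and the running
median of the raw statistic over a 501-gene window ($\pm 250$ neighbours;
symmetric shrink toward the edges) is subtracted. Corrected values may be
negative; they rank genes by how much more or less variable they are than
genes of equal expression.

**Stage statistic.** For two embryos $i,k$ and the $N$ analysed genes,
with $y_j = x_j^i - x_j^k$,
$$V^{ik} = \frac{1}{N}\sum_j \left(y_j - \bar y\right)^2$$
(population variance, divisor $N$). Per stage this yields one value per
sibling pair (stability) and per hybrid pair (diversity).

**Inference.** Spearman's rank correlation with the $t$-approximation
test of no correlation relates corrected F0 variation to corrected F3
diversity per stage; Kruskal–Wallis compares $V^{ik}$ across stages; the
Steel–Dwass procedure (pairwise tie-corrected standardised rank-sum
statistic referred to the studentized range with $k$ groups and infinite
degrees of freedom) performs the all-pairs stage comparisons with
familywise control.

## Numerical and design choices

* **Rank-sum flavour.** Midranks everywhere; exact enumeration of all
  assignments when both sides have at most 8 values, otherwise the
  tie-corrected normal approximation *without* continuity correction. The
  uncorrected approximation was chosen because, at the design's typical
  sample sizes (e.g. 13 sibling differences against 6 technical
  differences), it reproduces the exact rejection level at
  $\alpha = 0.01$ exactly (0.0084, the largest attainable level below
  0.01), whereas the continuity-corrected version is conservative
  (0.0062).
* **Technical-error sample.** By default the 6 raw replicate-pair
  differences per replicated condition enter the test (`tech_mode =
  "raw"`); a mode that first averages the 6 combinations within each
  condition is available but needs at least two replicated conditions to
  be testable, and a single replicated condition per stage is the common
  design.
* **Differential-mean selection.** A two-sided rank-sum filter that keeps
  only genes whose mean expression *differs* between generations is
  implemented (`apply_differential_mean`), but is off by default:
  selecting changed genes before a conservation analysis discards the
  stable genes the question is about, and under the generator's
  conditions (no generation-level mean shifts) it would retain only the
  $\sim\alpha$ null rejections.
* **Gene universes.** Low-expression filtering is applied per dataset;
  every cross-dataset statistic uses the intersection of the surviving
  sets, because each side of the statistic must be defined. Filtering
  precedes the running-median correction, mirroring the order
  select-genes-then-evaluate-stability; gene counts after each step are
  logged. For the stage statistic each group uses its own filtered set by
  default (`common_gene_set` forces the intersection).
* **Ties and determinism.** Sorting by mean expression breaks ties by
  gene id; all procedures are deterministic given their inputs, and the
  pipeline writes every intermediate so each reported number can be
  re-derived (`verify_gene_level()`, `verify_stage_level()`).
* **Sibling pairing.** All sex-matched within-group pairs are formed by
  default (a flag restricts to disjoint pairs); unknown sex never
  matches. Cross-population pairing is the full sex-matched bipartite
  product, which reproduces the published pair counts
  ($4+4 \to 16$, $2+2 \to 4$).

## What the generator emulates

`generator_config()` / `simulate_study()` produce TPM tables, metadata
and a per-gene truth record. On the log scale each measurement is
$$x = \mu_j + s_\mathrm{stage}\,\mathrm{scale}_j\,\varepsilon
      + \sigma_\mathrm{tech}\,\varepsilon',$$
truncated to $[0, 6]$ (TPM cannot be negative nor exceed $10^6$), with
$\mu_j \sim \Gamma(2, 0.75)$ and 10% of genes below detection. The
per-gene biological difference scale is additive in two components:
$$\mathrm{scale}_j = \underbrace{0.02 + 0.12\,\mu_j}_{\text{noise floor}}
  + 0.7\,S_j,$$
where $S_j$ is a mean-one log-normal ($\mathrm{sdlog} = 1.3$): the
*stability* component for F0 siblings, the *inflation* component for F3
and wild individuals. Stability and inflation are coupled by a Gaussian
copula with latent correlation $2\sin(\pi\rho^*/6)$, so their Spearman
correlation equals the planted $\rho^*$ exactly (default 0.4, the
magnitude reported for this kind of design). Wild populations share the
inflation component and differ by a per-gene mean offset
($\mathrm{sd} = 0.08$). Stage scales default to $(1, 1, 0.5, 1)$: one
mid-embryonic stage at half the biological noise of the others, the
hourglass the stage-level analysis should recover.

Two structural choices matter:

* The mean–variance trend is *additive in the difference scale* rather
  than multiplicative. Under the running-median correction an additive
  floor cancels exactly, so corrected values rank genes by their
  stability/inflation components; a multiplicative trend leaves a
  residual envelope that re-correlates corrected values with mean
  expression.
* The log-normal spread across genes ($\mathrm{sdlog} = 1.3$, a
  geometric SD of $\sim$3.7) reflects how widely per-gene expression
  variability differs between genes; it also determines how well the
  noisy per-gene estimates preserve gene ranks.

**What it does not emulate:** count-level sampling noise (technical noise
is homoscedastic on the log scale), expression correlation between genes,
generation-level mean shifts, temporal or spatial expression changes
within an embryo, and sequence evolution of any kind. Passing tests
therefore certify the statistical machinery under the design's structure,
not performance on any real dataset.

## Recovery limits the tests make explicit

With the design's sample sizes the per-gene statistics are noisy
estimates: the all-pairs mean absolute difference from 6 embryos has a
relative SD of about 0.33, and averaging 24 sibling pairs about 0.15.
Rank correlations computed from such estimates are attenuated by a factor
of roughly
$\sigma_L/\sqrt{\sigma_L^2 + \sigma_\delta^2}$ per side (log-scale signal
spread $\sigma_L$ against estimation noise $\sigma_\delta$), about
0.93 on the F3 side and 0.98 on the F0 side here, with small further
losses from the correction and the technical filter. A planted
$\rho^* = 0.4$ is therefore recovered as $\approx 0.33$, and planted 0
and 0.2 as $\approx 0.03$ and $\approx 0.18$ — the recovery-versus-truth
tests document exactly this: unbiased near zero, increasingly attenuated
with effect size. Disattenuation is deliberately not applied because the
published analysis reports raw Spearman coefficients.

Similarly, the stage-level tests quantify the accuracy of the asymptotic
Steel–Dwass form at the design's group sizes: against the exact
permutation null of the maximal standardised pairwise statistic (4 groups
of 10), the studentized-range approximation is accurate to about 0.005 in
the decision-relevant tail ($p \le 0.1$) but deviates by up to
$\sim$0.03 around $p \approx 0.4$, where the discreteness of the rank
statistic is coarsest. Significance calls at $\alpha = 0.01$ are
unaffected.

## Problem sizes used by the test-suite

The property checks run at the sizes the analyses are designed for:
10,000 genes for calibration, decorrelation and recovery checks (20 seeds
per planted correlation); 2,000 genes and 100 replicates for the
hourglass recovery, which exercises the full stage-level pipeline; 20,000
draws for the Steel–Dwass null. These sizes are the package's choices for
tight Monte-Carlo intervals at interactive runtimes.

## Limitations

* Technical noise is constant on the log scale, while real RNA-seq
  replicate noise grows at low counts; the technical-error filter is
  correspondingly less selective against lowly expressed genes on
  simulated data than on real data.
* The generator plants no differential means between generations, so the
  optional differential-mean selection can only be exercised for its
  null behaviour.
* The running-median correction removes mean dependence only up to
  within-window trend variation; with very steep trends relative to
  between-gene spread a small residual correlation remains.
* Heavier-tailed noise is available (`noise = "t"`), but all defaults
  are Gaussian on the log scale.
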