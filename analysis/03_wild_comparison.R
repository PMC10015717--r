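#!/usr/bin/env Rscript
# Does diversity generated by the laboratory cross mirror naturally
# occurring intra-species diversity? Per stage: hybrid (F3) all-pairs
# diversity against sex-matched cross-population diversity between the
# two wild populations.

suppressPackageStartupMessages({
  library(devstab)
  library(optparse)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--studydir", type = "character", default = "results/study"),
  make_option("--outdir", type = "character",
              default = "results/wild_comparison")
)))

expr <- read_expression(file.path(opt$studydir, "expression.tsv"))
meta <- read_metadata(file.path(opt$studydir, "metadata.tsv"))

res <- run_wild_comparison(expr, meta, outdir = opt$outdir, verbose = TRUE)

cat("\nHybrid-descendant versus wild-population diversity correlations:\n")
print(res$correlations, row.names = FALSE)
cat(sprintf("\nTables written under %s\n", opt$outdir))
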