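#!/usr/bin/env Rscript
# Build the analysis inputs under results/inputs/:
#  - the deterministic 9-SNP GDF-15 candidate-instrument fixture with its
#    LD matrix and nine synthetic outcome studies (the consortium GWAS
#    behind the published analysis are not redistributable; these carry
#    the published rsIDs and per-outcome effect scales), and
#  - one simulated 50-SNP exposure/outcome pair with known causal effect
#    for sanity-checking the estimators on data with ground truth.

library(gdfmr)

dir <- "results/inputs"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

fx <- gdf15_fixture()
write_sumstats(fx$exposure, file.path(dir, "gdf15_exposure.tsv"))
write_ld_matrix(fx$ld, file.path(dir, "gdf15_ld.tsv"))
for (name in names(fx$outcomes)) {
  write_sumstats(fx$outcomes[[name]],
                 file.path(dir, sprintf("outcome_%s.tsv", name)))
}
writeLines("# no instruments flagged by the pleiotropy screen",
           file.path(dir, "exclusions.txt"))
cat(sprintf("fixture: %d candidate SNPs, %d outcome studies\n",
            nrow(fx$exposure), length(fx$outcomes)))

sim <- simulate_pair(sim_config(n_snps = 50, theta = 0.1, seed = 20260926))
write_sumstats(sim$exposure, file.path(dir, "sim_exposure.tsv"))
write_sumstats(sim$outcome, file.path(dir, "sim_outcome.tsv"))
write.table(sim$truth, file.path(dir, "sim_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("simulated pair: 50 SNPs, true causal effect 0.1 (truth table written)\n")
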