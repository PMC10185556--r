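#!/usr/bin/env Rscript
# Generate the synthetic two-cohort, two-depot adipocyte methylome study and
# write all study matrices plus the planted truth tables.

source("analysis/00_config.R")

study <- get_study()
sim <- study$sim
d <- res_dir("sim")
big <- scratch_dir("sim")

for (k in names(sim$meth))
  write_matrix(sim$meth[[k]], file.path(big, paste0("betas_", k, ".tsv")))
write_matrix(sim$expr, file.path(big, "expr_counts.tsv"))
write_matrix(sim$geno, file.path(big, "genotypes.tsv"))
data.table::fwrite(sim$meth$disc_subq$sample_sheet, file.path(d, "samples_disc_subq.tsv"), sep = "\t")
intervals_to_bed(study$ann$features, file.path(d, "features.bed"))
intervals_to_bed(study$ann$tads, file.path(d, "tads.bed"))
write_pairs(study$ann$interactions, file.path(d, "interactions.tsv"))
write_truth(sim$truth, d)

cat("Truth tables and annotations written to", d,
    "; full matrices to", big, "\n")
eff <- ifelse(sim$truth$sites$effect_subq != 0, sim$truth$sites$effect_subq,
              sim$truth$sites$effect_visc)
cat(sprintf("  %d CG sites, %d planted differential (%.0f%% negative shifts)\n",
            nrow(sim$sites), nrow(sim$truth$sites), 100 * mean(eff < 0)))
cat(sprintf("  %d mQTLs, %d causal chains (%d reverse), %d target links, %d mediation triples\n",
            nrow(sim$truth$mqtl), nrow(sim$truth$chains),
            sum(sim$truth$chains$direction == "reverse"),
            nrow(sim$truth$targets), nrow(sim$truth$mediation)))
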