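#!/usr/bin/env Rscript
# Sentinel definition: chain gate-passing sites into loci (<= 5 kb apart),
# take the minimum-p site per locus as sentinel, extend to DMRs, and test
# cross-depot direction concordance with the exact binomial sign test.

source("analysis/00_config.R")

study <- get_study()
sim <- study$sim
d <- res_dir("sentinels")

run_depot <- function(depot) {
  kd <- paste0("disc_", depot); kr <- paste0("repl_", depot)
  a <- site_association(sim$meth[[kd]], sim$meth[[kd]]$sample_sheet$group,
                        ewas_covars(sim, kd), cohort = "discovery")
  b <- site_association(sim$meth[[kr]], sim$meth[[kr]]$sample_sheet$group,
                        ewas_covars(sim, kr), cohort = "replication")
  meta <- ivw_meta(a, b)
  gate <- replication_gate(a, b, meta)
  sig <- merge(meta[meta$site_id %in% gate$sites, ],
               meth_sites(sim$meth[[kd]]), by = "site_id")
  loci <- clump_loci(sig)
  all_sites <- merge(meta, meth_sites(sim$meth[[kd]]), by = "site_id")
  dmrs <- lapply(seq_len(nrow(loci)), function(i)
    extend_dmr(loci[i, ], all_sites))
  list(assoc = meta, loci = loci,
       dmr = data.frame(sentinel_id = vapply(dmrs, `[[`, "", "sentinel_id"),
                        n_consistent = vapply(dmrs, `[[`, 0L, "n_consistent"),
                        is_dmr = vapply(dmrs, `[[`, TRUE, "is_dmr"),
                        width_bp = vapply(dmrs, `[[`, 0L, "width_bp")))
}

subq <- run_depot("subq")
visc <- run_depot("visc")

for (nm in c("subq", "visc")) {
  r <- get(nm)
  out <- r$loci; out$members <- vapply(out$members, paste, "", collapse = ",")
  data.table::fwrite(out, file.path(d, paste0("sentinels_", nm, ".tsv")), sep = "\t")
  data.table::fwrite(r$dmr, file.path(d, paste0("dmrs_", nm, ".tsv")), sep = "\t")
  cat(sprintf("[%s] %d loci from %d gated sites; %d flagged as DMRs (>=5 consistent flanking sites)\n",
              nm, nrow(r$loci), sum(r$loci$n_members), sum(r$dmr$is_dmr)))
}

cc <- depot_concordance(subq$loci, visc$assoc)
cat(sprintf("subq sentinels in visc: %d/%d direction-consistent (%d also Bonferroni-significant), sign test P = %.3g\n",
            cc$n_consistent, cc$n_total, cc$n_consistent_significant, cc$binom$p))
cc2 <- depot_concordance(visc$loci, subq$assoc)
cat(sprintf("visc sentinels in subq: %d/%d direction-consistent, sign test P = %.3g\n",
            cc2$n_consistent, cc2$n_total, cc2$binom$p))
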