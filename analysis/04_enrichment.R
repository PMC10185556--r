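#!/usr/bin/env Rscript
# Functional enrichment of sentinels against matched permutation backgrounds:
# 1000 methylation-matched sites per sentinel via the sliding tolerance
# ladder, then feature enrichment, GWAS/chromatin-state overlap and
# nearest-gene pathway enrichment.

source("analysis/00_config.R")

study <- get_study()
sim <- study$sim
ann <- study$ann
d <- res_dir("enrichment")

# sentinels: planted subcutaneous differential sites stand in for the
# gate-derived list so the enrichment stage is exercised at scale
sent <- sim$truth$sites$site_id[sim$truth$sites$effect_subq != 0]
pool <- site_pool_stats(sim$meth$disc_subq)
ps <- build_permutation_sets(sent, pool, seed = STUDY_SEED + 4L)
cat(sprintf("built %d permutation sets (ladder rungs %d-%d)\n", length(ps),
            min(vapply(ps, `[[`, 0L, "rung")), max(vapply(ps, `[[`, 0L, "rung"))))

fe <- feature_enrichment(sent, ps, ann$features, pool)
data.table::fwrite(fe, file.path(d, "feature_enrichment.tsv"), sep = "\t")
print(fe)

# GWAS overlap via shared chromatin-state intervals: a sentinel counts iff
# the state tile containing it also holds a genome-wide-significant SNP
gw <- simulate_gwas_from_chain(sim$truth, sim$geno, study$cfg$n_gwas,
                               seed = STUDY_SEED + 5L)
hits <- gw[gw$p < 5e-8, ]
hits <- merge(hits, data.frame(snp = rownames(sim$geno$dosages),
                               chrom = sim$geno$chrom, pos = sim$geno$pos))
go <- gwas_state_overlap(sent, ps, pool, hits, ann$states)
data.table::fwrite(go, file.path(d, "gwas_state_overlap.tsv"), sep = "\t")
cat(sprintf("GWAS-state overlap: observed %d vs expected %.2f (empirical P = %.3g)\n",
            go$observed, go$expected, go$empirical_p))

# nearest-gene pathway enrichment against a planted set
sites_tab <- meth_sites(sim$meth$disc_subq)
ng <- function(ids) vapply(ids, function(s) {
  i <- match(s, sites_tab$site_id)
  nearest_gene(sites_tab$chrom[i], sites_tab$pos[i], ann$genes)$gene_id
}, "")
sent_genes <- ng(sent)
perm_genes <- lapply(seq_len(200), function(j)
  ng(vapply(ps, function(p) p$ids[j], "")))
genesets <- list(planted_targets = unique(sim$truth$targets$gene_id),
                 random_50 = sample(ann$genes$gene$gene_id, 50))
pw <- pathway_enrichment(sent_genes, perm_genes, genesets,
                         universe = ann$genes$gene$gene_id)
data.table::fwrite(pw, file.path(d, "pathway_enrichment.tsv"), sep = "\t")
print(pw)
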