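#!/usr/bin/env Rscript
# Target-gene assignment (genic -> functional interaction -> TAD) and
# methylation-expression association with a participant random intercept on
# the combined-depot replication samples, plus DE enrichment of targets.

source("analysis/00_config.R")

study <- get_study()
sim <- study$sim
ann <- study$ann
d <- res_dir("targets")

tads <- merge_tads(ann$tads)
cat(sprintf("TADs: %d raw -> %d after hierarchy merge\n",
            length(ann$tads), length(tads)))

sent_tab <- merge(data.frame(sentinel_id = sim$truth$sites$site_id),
                  setNames(meth_sites(sim$meth$disc_subq),
                           c("sentinel_id", "chrom", "pos")))
ta <- assign_targets(sent_tab, ann$genes, ann$interactions, tads)
data.table::fwrite(ta, file.path(d, "assignments.tsv"), sep = "\t")
cat("tier counts:\n"); print(table(ta$tier))

# association on the truth-linked pairs plus the assigned pairs
pairs <- unique(rbind(ta[, c("sentinel_id", "gene_id")],
                      setNames(sim$truth$targets[, c("site_id", "gene_id")],
                               c("sentinel_id", "gene_id"))))
ma <- meth_expr_assoc(list(sim$meth$repl_subq, sim$meth$repl_visc),
                      sim$expr, pairs)
data.table::fwrite(ma, file.path(d, "meth_expr_assoc.tsv"), sep = "\t")
tr <- ma[ma$sentinel_id %in% sim$truth$targets$site_id &
           ma$gene_id %in% sim$truth$targets$gene_id, ]
cat(sprintf("meth-expr: %d pairs tested, %d significant at FDR<0.01; planted links: %d/%d within 2 SE of the true slope\n",
            nrow(ma), sum(ma$significant, na.rm = TRUE),
            sum(abs(tr$slope - study$cfg$target_slope) < 2 * tr$se, na.rm = TRUE),
            nrow(tr)))

# DE enrichment of target genes (naive log-scale DE fit as plumbing)
grp <- sim$expr$sample_sheet$group
de <- de_fit_naive(sim$expr, grp)
enr <- de_enrichment(unique(sim$truth$targets$gene_id), de, q_thresh = 0.05)
cat(sprintf("DE enrichment of targets: %d/%d DE vs background rate %.3f, binomial P = %.3g\n",
            enr$k, enr$n, enr$background_rate, enr$p))
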