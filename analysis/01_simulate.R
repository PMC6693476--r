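#!/usr/bin/env Rscript
# Step 1: draw the synthetic study cohort and write every table to disk in
# the package's standard text formats. All later steps read these files, so
# the whole workflow also exercises the I/O layer.
#
# Cohort: 31 MCTD / 255 CTRL discovery (EPIC-like, 2,000 probes of which
# 200 carry an interferon-signature-like hypomethylation), 21/103
# replication on a ~55% probe subset, four further disease groups, 200 SNPs
# with 20 wired cis-meQTLs and one mediated SNP-CpG-disease locus.

suppressMessages(library(sadewas))

seed <- as.integer(Sys.getenv("SADEWAS_SEED", "1"))
outdir <- "results/simdata"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, n_probes = 2000, n_ifn_probes = 200,
                  n_vms_only = 15)
sim <- simulate_cohort(cfg)

write_methylation(sim$discovery, file.path(outdir, "discovery_beta.tsv"),
                  file.path(outdir, "probe_annotation.tsv"))
write_methylation(sim$replication, file.path(outdir, "replication_beta.tsv"))
write_sample_sheet(sim$sheet, file.path(outdir, "sample_sheet.csv"))
write_genotypes(sim$genotypes, file.path(outdir, "dosages.tsv"))

ref <- data.frame(probe_id = rownames(sim$reference$profiles),
                  sim$reference$profiles, check.names = FALSE)
write.table(ref, file.path(outdir, "reference_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
refb <- data.frame(probe_id = rownames(sim$reference$beta),
                   sim$reference$beta, check.names = FALSE)
write.table(refb, file.path(outdir, "reference_betas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write.table(sim$truth$probes, file.path(outdir, "truth_probes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$snps, file.path(outdir, "truth_snps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$cells, file.path(outdir, "true_cell_proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

manifest <- data.frame(
  key = c("seed", "n_probes", "n_affected", "discovery_n", "replication_n",
          "genotyped_n"),
  value = c(seed, cfg$n_probes, cfg$n_ifn_probes,
            ncol(sim$discovery$beta), ncol(sim$replication$beta),
            ncol(sim$genotypes$dosage)))
write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d probes x %d discovery samples (+%d replication), %d SNPs\n",
  nrow(sim$discovery$beta), ncol(sim$discovery$beta),
  ncol(sim$replication$beta), nrow(sim$genotypes$dosage)))
cat(sprintf("truth: %d affected probes (%.0f%% hypomethylated), %d VMS, %d wired meQTLs\n",
            sum(sim$truth$probes$is_dms),
            100 * mean(sim$truth$probes$delta[sim$truth$probes$is_dms] < 0),
            sum(sim$truth$probes$vms), sum(sim$truth$probes$gamma != 0)))
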