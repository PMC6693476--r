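#!/usr/bin/env Rscript
# Step 3: the core epigenome-wide scans on the discovery cohort -- adjusted
# differential methylation (DMS) and differential variability (VMS) -- with
# replication in the independent 450K-like cohort and inflation diagnostics.

suppressMessages(library(sadewas))

indir <- "results/simdata"
disc <- read_methylation(file.path(indir, "discovery_beta.tsv"),
                         file.path(indir, "probe_annotation.tsv"))
repl <- read_methylation(file.path(indir, "replication_beta.tsv"),
                         file.path(indir, "probe_annotation.tsv"))
sheet <- read_sample_sheet(file.path(indir, "sample_sheet.csv"))
cells <- read.delim("results/cell_proportions.tsv")

scan <- run_dms_scan(disc, sheet, cells)
lam <- genomic_inflation(scan$records$p)
cat(sprintf("DMS scan: %d probes tested, threshold %s, %d DMS called\n",
            scan$m_tests, format(display_round(scan$threshold,
                                               "threshold")),
            length(scan$dms)))
cat(sprintf("genomic inflation lambda = %.3f\n", lam$lambda))
cat(sprintf("%.0f%% of DMS are hypomethylated in cases\n",
            100 * mean(scan$records$effect[scan$records$significant] < 0)))
write_records(scan$records, "results/ewas_records.tsv")
write_records(lam$qq, "results/ewas_qq.tsv")

vms <- run_vms_scan(disc, sheet, cells, dms = scan$dms)
cat(sprintf("VMS scan: %d VMS called, %d overlap the DMS set\n",
            length(vms$vms), vms$dms_overlap))
write_records(vms$records, "results/vms_records.tsv")

rep_scan <- run_dms_scan(repl, sheet, cells)
rep_out <- replicate_calls(scan$records, rep_scan$records, scan$dms)
cat(sprintf("replication: %d of %d DMS testable on the legacy platform, %d replicated (%d%%)\n",
            rep_out$n_testable, rep_out$n_calls, rep_out$n_replicated,
            rep_out$percent))
write_records(rep_out$table, "results/dms_replication.tsv")

rep_vms <- run_vms_scan(repl, sheet, cells)
rep_vms_out <- replicate_calls(vms$records, rep_vms$records, vms$vms)
cat(sprintf("VMS replication: %d of %d testable, %d replicated (%d%%)\n",
            rep_vms_out$n_testable, length(vms$vms),
            rep_vms_out$n_replicated, rep_vms_out$percent))

truth <- read.delim(file.path(indir, "truth_probes.tsv"))
rec <- truth_report(truth, scan$records, true_effect = "delta_cohort")
cat("recovery against the simulation truth (cohort-level estimand):\n")
print(rec)
write_records(rec, "results/ewas_truth_report.tsv")
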