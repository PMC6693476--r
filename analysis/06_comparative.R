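#!/usr/bin/env Rscript
# Step 6: cross-disease comparison at the MCTD DMS set, case-vs-case
# differential methylation, biomarker panel ROC/AUC evaluation, and a
# gene-set over-representation check of the called genes.

suppressMessages(library(sadewas))

indir <- "results/simdata"
disc <- read_methylation(file.path(indir, "discovery_beta.tsv"),
                         file.path(indir, "probe_annotation.tsv"))
sheet <- read_sample_sheet(file.path(indir, "sample_sheet.csv"))
cells <- read.delim("results/cell_proportions.tsv")
ewas <- read.delim("results/ewas_records.tsv")
dms <- ewas$probe_id[ewas$significant]

cd <- cross_disease_scan(disc, sheet, cells, dms)
cat("effect correlation with the MCTD signature:\n")
print(round(cd$correlations, 3))
cat(sprintf("heat-map subset (|MCTD effect| > 0.15): %d probes\n",
            length(cd$heatmap_probes)))
eff <- data.frame(probe_id = colnames(cd$effects), t(cd$effects))
write_records(eff, "results/cross_disease_effects.tsv")

for (d in c("SLE", "SjS", "RA", "SSc")) {
  cv <- case_vs_case_scan(disc, sheet, cells, dms, "MCTD", d)
  cat(sprintf("MCTD vs %s: %d differential sites at p < %s\n", d,
              length(cv$dms),
              format(display_round(cv$threshold, "threshold"))))
}

panel <- ewas$probe_id[order(ewas$p)][1:10]
cat("top-10 discriminating panel:", paste(panel[1:3], collapse = ", "),
    "...\n")
aucs <- sapply(c("CTRL", "SLE", "SjS", "RA", "SSc"), function(cmp) {
  evaluate_panel(disc, sheet, panel, cmp, cells = cells)$auc
})
cat("panel AUC by comparator:\n")
print(round(aucs, 3))
write_records(data.frame(comparator = names(aucs), auc = aucs),
              "results/panel_auc.tsv")

# over-representation of the called genes in the simulated IFN-like set
truth <- read.delim(file.path(indir, "truth_probes.tsv"))
background <- setdiff(unique(disc$probes$gene), "Intergenic")
hit_genes <- setdiff(unique(
  disc$probes$gene[disc$probes$probe_id %in% dms]), "Intergenic")
sets <- list(
  ifn_signature = setdiff(unique(truth$gene[truth$is_dms]), "Intergenic"),
  random_set = sample(background, 40))
enr <- gene_set_enrichment(hit_genes, background, sets)
print(enr[, c("set", "overlap", "set_size", "p", "q")])
write_records(enr, "results/gene_set_enrichment.tsv")
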