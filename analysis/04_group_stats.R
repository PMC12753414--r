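#!/usr/bin/env Rscript
# Step 4: group statistics on the withdrawal-delay dataset -- per-gene two-way
# ANOVA (treatment x day) with Benjamini-Hochberg correction across the panel
# (one family per analysis), Welch post-hoc contrasts by day for genes with a
# treatment or interaction signal, percent-change reporting, and the
# ALLO-over-DMSO fold-change ratio table.

suppressPackageStartupMessages({
  library(devindexr)
  library(dplyr)
})

fc <- readr::read_csv("results/tables/fold_change.csv",
                      show_col_types = FALSE)
post <- fc[fc$div > 0, ]  # DIV0 is the pre-treatment calibrator

## Per-gene two-way ANOVA; BH families across genes, one per model term.
anova_by_gene <- bind_rows(lapply(sort(unique(post$gene)), function(g) {
  res <- two_way_anova(post[post$gene == g, ], "value", "treatment", "div")
  res$gene <- g
  res[res$term != "Residuals", c("gene", "term", "df", "sum_sq", "statistic",
                                 "p")]
}))
anova_by_gene <- anova_by_gene %>%
  group_by(term) %>%
  mutate(p_adj = bh_adjust(p), family_id = paste0("panel_anova_", term)) %>%
  ungroup()

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
write_table_csv(anova_by_gene, "results/stats/anova_by_gene.csv")

inter <- anova_by_gene %>%
  filter(term == "treatment:div", p_adj < 0.05) %>%
  arrange(p_adj)
cat(sprintf("genes with a BH-adjusted treatment-by-day interaction: %d of %d\n",
            nrow(inter), length(unique(anova_by_gene$gene))))
print(as.data.frame(head(inter[, c("gene", "statistic", "p", "p_adj")], 8)),
      row.names = FALSE, digits = 3)

## Post-hoc Welch contrasts by day for the strongest interaction gene.
top_gene <- if (nrow(inter)) inter$gene[1] else "DCX"
ph <- posthoc_by_stratum(post[post$gene == top_gene, ], "value", "treatment",
                         "div", reference = "DMSO")
ph$gene <- top_gene
ph$family_id <- paste0("posthoc_", top_gene)
write_table_csv(ph, "results/stats/posthoc_top_gene.csv")
cat(sprintf("\npost-hoc (ALLO - DMSO) for %s:\n", top_gene))
print(as.data.frame(ph[, c("stratum", "estimate", "p", "p_adj")]),
      row.names = FALSE, digits = 3)

## Percent change at the days inside the delay window.
pc <- bind_rows(lapply(c(78, 95), function(d) {
  tibble::tibble(
    gene = sort(unique(post$gene)), div = d,
    percent = vapply(sort(unique(post$gene)),
                     function(g) percent_change(post, g, d), numeric(1))
  )
}))
write_table_csv(pc, "results/stats/percent_change.csv")
biggest <- pc[order(pc$percent)[1:3], ]
cat("\nlargest reductions in ALLO vs DMSO (percent change):\n")
print(as.data.frame(biggest), row.names = FALSE, digits = 3)

## Heatmap-style ratio table (mean ALLO fold change over mean DMSO).
ratios <- fold_change_ratio_table(post, arm_a = "ALLO", arm_b = "DMSO")
write_table_csv(ratios, "results/stats/fold_change_ratio.csv")
cat(sprintf("\nratio table: %d genes x %d days -> results/stats/fold_change_ratio.csv\n",
            length(unique(ratios$gene)), length(unique(ratios$div))))
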