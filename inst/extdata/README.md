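# Reference tables

Published summary tables from the YAC128 / HdhQ150 striatal expression
comparison, transcribed for worked-example checks of the package's
fold-change and table arithmetic. All values are as printed (p-values,
log2 fold changes to 3 decimals, per-model fold changes to 2 decimals);
recomputation from rounded inputs can therefore differ by one unit in the
last printed digit.

- `yac128_genotype_de_reference.tsv` — FDR-significant genotype contrast
  (all ages pooled): per-gene p, log2FC and absolute fold change
  (`abs_fc = 2^|log2fc|`), best probeset per gene.
- `model_divergence_reference.tsv` — genes with a significant
  genotype-by-model interaction and |FC difference| > 0.20: interaction p,
  per-model genotype fold changes, absolute fold-change difference.
- `tanova_pattern_reference.tsv` — trajectory pattern cross-table cells
  (MUT pattern x WT pattern) with per-cell counts of genes down-/up-
  regulated in the mutant; down + up can be below the cell count because
  direction-ambiguous genes are excluded from the tallies.
- `age_overlap_reference.tsv` — top-list overlap counts between age- or
  genotype-contrast lists with the printed overlap percentages
  (`100 * n_overlap / n_list`); one printed percentage does not match any
  printed list size and is recorded as NA.
- `genotype_fdr_counts.tsv` — direction split of the FDR-significant
  genotype probesets.
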