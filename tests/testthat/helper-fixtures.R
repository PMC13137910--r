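# Small in-code fixtures shared across test files.

toy_intensity <- function(values, design = NULL, scale_state = "linear",
                          features = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- features %||% sprintf("P%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  }
  intensity_matrix(values, design = design, scale_state = scale_state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NO contrast (iNOS KO stimulated vs WT stimulated, donor-free), used all over.
no_contrast <- contrast_spec(
  reference = list(genotype = "WT", stimulation = "stim", donor = "none"),
  contrast = list(genotype = "iNOS_KO", stimulation = "stim", donor = "none"),
  label = "iNOS_KO_stim_vs_WT_stim")

wt_stim_contrast <- contrast_spec(
  reference = list(genotype = "WT", stimulation = "unstim", donor = "none"),
  contrast = list(genotype = "WT", stimulation = "stim", donor = "none"),
  label = "WT_stim_vs_WT_unstim")

# Minimal DiffResult table builder for concordance tests.
diff_table <- function(genes, lfc, padj, label = "x") {
  data.frame(gene_symbol = genes, log2fc = lfc, p_raw = padj, p_adj = padj,
             mean_ref = 1, mean_contrast = 1, dataset_label = label,
             stringsAsFactors = FALSE)
}
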