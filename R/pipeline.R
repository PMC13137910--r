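#' Pipeline configuration
#'
#' Bundles the simulation block and all stage parameters with their
#' field-standard defaults: significance at BH-adjusted p < 0.05; robust
#' responders at |log2FC| > 0.5; NO-dependence thresholds 0.4 (stimulation
#' effects) and 0.5 (NO effect) in z units; PC contributor selection at
#' +/-2 loading SDs on PC2; a 16-valid-value filter for the DIA-like
#' proteome; a 10-read total-count filter for RNA; down-shifted imputation
#' with width 0.3 and shift 1.8.
#'
#' @param simulate a [sim_params()] block (the demo pipeline is
#'   simulation-driven; file-based inputs can be substituted by calling the
#'   stage functions directly).
#' @param alpha,lfc_cut,wt_thresh,no_thresh,k_sd,min_valid,min_total
#'   stage thresholds, see the stage functions.
#' @param impute_width,impute_downshift down-shifted imputation parameters.
#' @param component principal component used for contributor selection.
#' @param top_k quadrant label count.
#' @param gmt optional path to a GMT library for the enrichment stage; when
#'   `NULL` a synthetic demonstration library derived from the planted truth
#'   is used.
#' @param classify_significant_only restrict the NO-dependence classifier to
#'   genes significant (BH p < `alpha`) in the NO contrast or the wild-type
#'   stimulation contrast (default `TRUE`; see the methods vignette).
#' @param channel_normalize rescale each complete-matrix sample column to a
#'   total of 100 before analysis (default `FALSE`). Intended for reporter
#'   intensities, where only relative signal per channel is meaningful. With
#'   absolute-scale input and unbalanced regulation, sum normalization
#'   redistributes the regulated signal onto unregulated features (a
#'   compositional artifact), so it is off for the simulated demo data,
#'   which are generated loading-balanced; see the methods vignette.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_params(),
                            alpha = 0.05, lfc_cut = 0.5,
                            wt_thresh = 0.4, no_thresh = 0.5,
                            k_sd = 2, min_valid = 16L, min_total = 10L,
                            impute_width = 0.3, impute_downshift = 1.8,
                            component = 2L, top_k = 20L,
                            gmt = NULL,
                            classify_significant_only = TRUE,
                            channel_normalize = FALSE) {
  cfg <- as.list(environment())
  problems <- character(0)
  if (!inherits(simulate, "sim_params")) problems <- c(problems, "simulate must be a sim_params() object")
  if (alpha <= 0 || alpha >= 1) problems <- c(problems, "alpha must lie in (0, 1)")
  if (lfc_cut < 0) problems <- c(problems, "lfc_cut must be >= 0")
  if (k_sd < 0) problems <- c(problems, "k_sd must be >= 0")
  if (min_valid < 1) problems <- c(problems, "min_valid must be >= 1")
  if (!is.null(gmt) && !file.exists(gmt)) problems <- c(problems, sprintf("gmt path '%s' does not exist", gmt))
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Synthetic demonstration gene-set library
#'
#' Builds a gene-set library from a simulation truth table, for exercising
#' the enrichment stage without external annotation: one set per planted
#' regulatory class plus random draws from all simulated genes. Synthetic —
#' the set names carry a `SYNTH_` prefix to make that explicit.
#'
#' @param truth a truth table from [generate_proteomics()].
#' @param n_random number of random decoy sets.
#' @param set_size size of each decoy set.
#' @param seed integer seed.
#' @return a `gene_set_library`.
#' @export
demo_gene_set_library <- function(truth, n_random = 20, set_size = 40, seed = 1L) {
  sets <- list(
    SYNTH_PLANTED_NO_DEP_UP = toupper(truth$gene_symbol[truth$planted_class == "NO_dep_up"]),
    SYNTH_PLANTED_NO_DEP_DOWN = toupper(truth$gene_symbol[truth$planted_class == "NO_dep_down"]),
    SYNTH_PLANTED_NO_INDEPENDENT = toupper(truth$gene_symbol[truth$planted_class == "NO_independent"]))
  withr::with_seed(seed, {
    for (i in seq_len(n_random)) {
      sets[[sprintf("SYNTH_RANDOM_%02d", i)]] <-
        toupper(sample(truth$gene_symbol, min(set_size, nrow(truth))))
    }
  })
  sets <- sets[lengths(sets) > 0]
  structure(list(sets = sets,
                 description = stats::setNames(rep("synthetic demonstration set", length(sets)),
                                               names(sets))),
            class = "gene_set_library")
}

.log_stage <- function(log_path, stage, t0, ...) {
  entry <- c(list(stage = stage, elapsed_s = round(as.numeric(Sys.time()) - t0, 2)),
             list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n", file = log_path,
      append = TRUE, sep = "")
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes every stage end-to-end: simulation of a 32-sample DIA-like
#' proteome (with missingness), a 16-sample TMT-like proteome and an RNA
#' count matrix sharing one planted truth; preprocessing of each; Welch and
#' NB-Wald differential statistics for the iNOS-KO-stim vs WT-stim (NO)
#' contrast and the WT stim vs unstim contrast; PCA with contributor
#' selection; z-score NO-dependence classification (with truth scoring);
#' cross-model, cross-omic and triple concordance; and gene-set
#' over-representation. Every stage writes a TSV stamped with the config
#' hash plus a JSONL log line.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config)
  tag <- paste0("config=", hash)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  t0 <- as.numeric(Sys.time())
  params <- config$simulate

  ## --- simulate -----------------------------------------------------------
  sim_bmdm <- generate_proteomics(bmdm_design(), params)
  truth <- sim_bmdm$truth
  params_raw <- params
  params_raw$missing_rate <- 0  # TMT-like: complete reporter matrix
  params_raw$seed <- params$seed + 7L
  sim_raw <- generate_proteomics(raw_design(), params_raw, truth = truth)
  counts <- generate_counts(raw_design(replicates = 3), truth, params)
  write_matrix(sim_bmdm$matrix, file.path(out_dir, "bmdm_intensity.tsv"), provenance = tag)
  write_matrix(sim_raw$matrix, file.path(out_dir, "raw_intensity.tsv"), provenance = tag)
  write_matrix(counts, file.path(out_dir, "raw_counts.tsv"), id_col = "gene_symbol", provenance = tag)
  write_result_table(truth, file.path(out_dir, "truth.tsv"), provenance = tag)
  write_design(sim_bmdm$matrix$design, file.path(out_dir, "bmdm_design.tsv"))
  write_design(counts$design, file.path(out_dir, "rna_design.tsv"))
  .log_stage(log_path, "simulate", t0, n_features = params$n_features,
             bmdm_samples = ncol(sim_bmdm$matrix$values),
             raw_samples = ncol(sim_raw$matrix$values))

  ## --- preprocess ---------------------------------------------------------
  bmdm <- filter_complete(sim_bmdm$matrix, "min_valid", config$min_valid)
  bmdm_log2 <- impute_downshifted(log2_transform(bmdm),
                                  width = config$impute_width,
                                  downshift = config$impute_downshift,
                                  seed = params$seed + 303L)
  fmap <- data.frame(accession = truth$feature_id, gene_symbol = truth$gene_symbol,
                     stringsAsFactors = FALSE)
  bmdm_lin <- collapse_to_genes(back_transform(bmdm_log2), fmap)
  raw_pre <- if (config$channel_normalize) channel_normalize(sim_raw$matrix) else sim_raw$matrix
  raw_norm <- collapse_to_genes(raw_pre, fmap)
  raw_log2 <- log2_transform(raw_norm)
  counts_f <- filter_low_counts(counts, config$min_total)
  .log_stage(log_path, "preprocess", t0,
             bmdm_retained = nrow(bmdm$values), rna_retained = nrow(counts_f$values))

  ## --- differential -------------------------------------------------------
  no_contrast <- contrast_spec(
    reference = list(genotype = "WT", stimulation = "stim", donor = "none"),
    contrast = list(genotype = "iNOS_KO", stimulation = "stim", donor = "none"),
    label = "iNOS_KO_stim_vs_WT_stim")
  wt_contrast <- contrast_spec(
    reference = list(genotype = "WT", stimulation = "unstim", donor = "none"),
    contrast = list(genotype = "WT", stimulation = "stim", donor = "none"),
    label = "WT_stim_vs_WT_unstim")
  de_bmdm <- diff_intensity(bmdm_lin, no_contrast)
  de_bmdm$dataset_label <- "bmdm_protein"
  de_raw <- diff_intensity(raw_norm, no_contrast)
  de_raw$dataset_label <- "raw_protein"
  de_wt <- diff_intensity(raw_norm, wt_contrast)
  de_wt$dataset_label <- "raw_protein_wt_stim"
  de_rna <- nb_wald(counts_f, no_contrast)
  de_rna$dataset_label <- "raw_rna"
  for (nm in c("de_bmdm", "de_raw", "de_wt", "de_rna")) {
    write_result_table(get(nm), file.path(out_dir, paste0(nm, ".tsv")), provenance = tag)
  }
  .log_stage(log_path, "differential", t0,
             bmdm_sig = sum(de_bmdm$p_adj < config$alpha),
             raw_sig = sum(de_raw$p_adj < config$alpha),
             rna_sig = sum(de_rna$p_adj < config$alpha & abs(de_rna$log2fc) > 1))

  ## --- structure ----------------------------------------------------------
  pca <- run_pca(bmdm_log2)
  contrib <- select_contributors(pca$loadings[, config$component], config$k_sd)
  write_result_table(data.frame(sample_id = rownames(pca$scores), pca$scores[, 1:3]),
                     file.path(out_dir, "pca_scores.tsv"), provenance = tag)
  write_result_table(data.frame(component = seq_along(pca$variance_explained),
                                variance_explained = pca$variance_explained),
                     file.path(out_dir, "pca_variance.tsv"), provenance = tag)
  raw_z <- row_zscore(raw_log2)
  gate <- NULL
  if (config$classify_significant_only) {
    gate <- union(de_raw$gene_symbol[de_raw$p_adj < config$alpha],
                  de_wt$gene_symbol[de_wt$p_adj < config$alpha])
    raw_z_gated <- raw_z
    raw_z_gated$values <- raw_z$values[rownames(raw_z$values) %in% gate, , drop = FALSE]
  } else {
    raw_z_gated <- raw_z
  }
  classification <- classify_no_dependence(raw_z_gated,
                                           wt_thresh = config$wt_thresh,
                                           no_thresh = config$no_thresh)
  scores <- score_against_truth(classification, truth)
  clustering <- cluster_rows(raw_z_gated)
  write_dendrogram_newick(clustering, file.path(out_dir, "dendrogram.nwk"))
  write_result_table(classification, file.path(out_dir, "classification.tsv"), provenance = tag)
  write_result_table(scores, file.path(out_dir, "classification_scores.tsv"), provenance = tag)
  .log_stage(log_path, "structure", t0,
             pc1_pct = round(pca$variance_explained[1], 2),
             pc2_pct = round(pca$variance_explained[2], 2),
             n_pos_contrib = length(contrib$positive),
             n_neg_contrib = length(contrib$negative),
             n_classified = nrow(classification))

  ## --- concordance --------------------------------------------------------
  cross_omic <- match_genes(de_raw, de_rna)
  co_class <- classify_concordance(cross_omic, config$alpha)
  co_r <- correlation_with_test(cross_omic)
  co_strong <- strong_responders(co_class$records, config$lfc_cut, config$alpha, config$top_k)
  cross_model <- match_genes(de_bmdm, de_raw)
  cm_class <- classify_concordance(cross_model, config$alpha)
  cm_r <- correlation_with_test(cross_model)
  triple <- triple_concordance(de_bmdm, de_raw, de_rna, de_wt,
                               alpha = config$alpha, rank_by = "b")
  write_result_table(co_strong, file.path(out_dir, "cross_omic_concordance.tsv"), provenance = tag)
  write_result_table(cm_class$records, file.path(out_dir, "cross_model_concordance.tsv"), provenance = tag)
  write_result_table(triple, file.path(out_dir, "triple_concordance.tsv"), provenance = tag)
  summary_json <- list(
    cross_omic = list(counts = as.list(co_class$counts),
                      percent = as.list(round(100 * co_class$counts / sum(co_class$counts), 1)),
                      r = co_r$r, p = co_r$p, n = co_r$n),
    cross_model = list(counts = as.list(cm_class$counts),
                       percent = as.list(round(100 * cm_class$counts / sum(cm_class$counts), 1)),
                       r = cm_r$r, p = cm_r$p, n = cm_r$n),
    triple_n = nrow(triple), config_hash = hash)
  jsonlite::write_json(summary_json, file.path(out_dir, "concordance_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(log_path, "concordance", t0,
             cross_omic_r = round(co_r$r, 3), cross_model_r = round(cm_r$r, 3),
             triple_n = nrow(triple))

  ## --- enrichment ---------------------------------------------------------
  lib <- if (is.null(config$gmt)) {
    demo_gene_set_library(truth, seed = params$seed + 404L)
  } else {
    read_gmt(config$gmt)
  }
  universe <- intersect(toupper(rownames(raw_norm$values)),
                        unique(unlist(lib$sets)))
  query_up <- classification$gene_symbol[classification$category == "NO_dep_up"]
  query_up <- intersect(toupper(query_up), universe)
  enr <- enrich(query_up, lib, universe, alpha = config$alpha, filter = FALSE)
  write_result_table(enr, file.path(out_dir, "enrichment_no_dep_up.tsv"), provenance = tag)
  .log_stage(log_path, "enrichment", t0,
             n_sets = length(lib$sets), top_set = if (nrow(enr)) enr$set_name[1] else NA)

  meta <- list(package = "noremod",
               version = as.character(utils::packageVersion("noremod")),
               config_hash = hash,
               seed = params$seed,
               config = lapply(unclass(config), function(x) if (inherits(x, "sim_params")) unclass(x) else x))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(out_dir = out_dir, truth = truth,
                 bmdm_log2 = bmdm_log2, raw_norm = raw_norm, raw_z = raw_z,
                 de = list(bmdm = de_bmdm, raw = de_raw, wt = de_wt, rna = de_rna),
                 pca = pca, contributors = contrib,
                 classification = classification, classification_scores = scores,
                 concordance = list(cross_omic = co_strong, cross_omic_r = co_r,
                                    cross_model = cm_class, cross_model_r = cm_r,
                                    triple = triple),
                 enrichment = enr, config_hash = hash))
}

#' Assemble a plain-text summary report for a completed run
#'
#' Reads the stage outputs of [run_pipeline()] from `run_dir`, refuses
#' mixtures of config hashes, and writes `report.md` with: variance
#' explained and contributor counts, classification category counts and
#' truth scores, concordance category counts with correlations, the
#' strong-responder quadrant table, the top triple-concordant genes, and the
#' top enriched sets. If the RNA-dependent outputs are absent the
#' concordance section is marked cross-model only.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param top_n how many triple-concordant genes to list (default 15).
#' @return the path to `report.md`, invisibly.
#' @export
pipeline_report <- function(run_dir, top_n = 15L) {
  need <- c("pca_variance.tsv", "classification.tsv", "cross_model_concordance.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("incomplete run; missing stage output(s): ", paste(missing, collapse = ", "))
  }
  hashes <- unique(unlist(lapply(list.files(run_dir, pattern = "\\.tsv$", full.names = TRUE),
                                 function(f) {
    first <- readLines(f, n = 1)
    if (startsWith(first, "# noremod")) sub(".*config=", "", first) else NULL
  })))
  if (length(hashes) > 1) {
    stop("outputs in this directory carry different config hashes; refusing to mix runs")
  }
  rd <- function(f) utils::read.delim(file.path(run_dir, f), comment.char = "#",
                                      stringsAsFactors = FALSE)
  ve <- rd("pca_variance.tsv")
  cls <- rd("classification.tsv")
  cm <- rd("cross_model_concordance.tsv")
  has_rna <- file.exists(file.path(run_dir, "cross_omic_concordance.tsv"))
  lines <- c("# Pipeline run summary", "",
             sprintf("Config hash: %s", if (length(hashes)) hashes else "(none)"), "",
             "## PCA",
             sprintf("- PC%d: %.1f%% variance explained", ve$component[1:3],
                     ve$variance_explained[1:3]), "",
             "## NO-dependence classification",
             sprintf("- %s: %d", names(table(cls$category)), as.integer(table(cls$category))), "")
  if (file.exists(file.path(run_dir, "classification_scores.tsv"))) {
    sc <- rd("classification_scores.tsv")
    lines <- c(lines, "Recovery of planted classes:",
               sprintf("- %s: precision %.3f, recall %.3f", sc$class, sc$precision, sc$recall), "")
  }
  lines <- c(lines, "## Concordance",
             sprintf("- cross-model categories: %s",
                     paste(sprintf("%s=%d", names(table(cm$category)),
                                   as.integer(table(cm$category))), collapse = ", ")))
  if (has_rna) {
    co <- rd("cross_omic_concordance.tsv")
    lines <- c(lines,
               sprintf("- cross-omic categories: %s",
                       paste(sprintf("%s=%d", names(table(co$category)),
                                     as.integer(table(co$category))), collapse = ", ")),
               sprintf("- strong responders: both_up=%d, both_down=%d",
                       sum(co$strong_quadrant == "both_up"),
                       sum(co$strong_quadrant == "both_down")))
    if (file.exists(file.path(run_dir, "triple_concordance.tsv"))) {
      tc <- rd("triple_concordance.tsv")
      lines <- c(lines, "", sprintf("## Triple concordance (top %d of %d)",
                                    min(top_n, nrow(tc)), nrow(tc)))
      if (nrow(tc)) {
        top <- utils::head(tc, top_n)
        lines <- c(lines, sprintf("- #%d %s (ranking lfc %.2f%s)", top$rank,
                                  top$gene_symbol, top$lfc_b,
                                  ifelse(!is.na(top$no_inducible) & top$no_inducible,
                                         ", NO-inducible", "")))
      }
    }
  } else {
    lines <- c(lines, "- cross-model only (no RNA input)")
  }
  if (file.exists(file.path(run_dir, "enrichment_no_dep_up.tsv"))) {
    en <- rd("enrichment_no_dep_up.tsv")
    lines <- c(lines, "", "## Enrichment (NO-dependent up, top sets)",
               sprintf("- %s: overlap %d/%d, adj p = %.3g",
                       utils::head(en$set_name, 5), utils::head(en$overlap_count, 5),
                       utils::head(en$set_size, 5), utils::head(en$p_adj, 5)))
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}

#' Z-score heatmap of classified features
#'
#' Thin wrapper over `pheatmap` using the package's display conventions:
#' diverging palette, z-scores capped at +/-2 for display only, rows
#' clustered on Pearson correlation distance with Ward.D2 linkage.
#'
#' @param z a row-z-scored [intensity_matrix()].
#' @param cap display cap in z units (default 2; analyzed values are never
#'   capped).
#' @param filename optional output image path passed to `pheatmap`.
#' @param ... further arguments to `pheatmap::pheatmap()`.
#' @export
plot_zscore_heatmap <- function(z, cap = 2, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_zscore_heatmap requires the 'pheatmap' package")
  }
  v <- pmin(pmax(z$values, -cap), cap)
  pheatmap::pheatmap(v,
                     clustering_distance_rows = "correlation",
                     clustering_method = "ward.D2",
                     cluster_cols = FALSE,
                     color = grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101),
                     filename = filename, ...)
}
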