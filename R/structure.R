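#' Principal component analysis of samples
#'
#' PCA with samples as observations and features as variables: the log2
#' matrix is transposed, zero-variance features are removed, every feature
#' is centered and scaled to unit variance, and components are computed by
#' SVD ([stats::prcomp()]). Because the sign of a principal axis is
#' arbitrary, each component is oriented so that its largest-magnitude
#' loading is positive, making contributor labels reproducible.
#'
#' Variance explained per component is
#' `100 * sdev_i^2 / sum(sdev^2)` (percent).
#'
#' @param m a complete log2-scale [intensity_matrix()] with >= 3 samples.
#' @return a `pca_result`: list with `scores` (samples x components),
#'   `loadings` (features x components), `variance_explained` (percent per
#'   component).
#' @export
run_pca <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale_state != "log2") stop("run_pca expects log2-scale intensities")
  if (anyNA(m$values)) stop("run_pca requires a complete matrix")
  if (ncol(m$values) < 3) stop("need at least 3 samples")
  x <- t(m$values)
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = 100 * pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("pca_result: %d samples x %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), ve[1], if (length(ve) > 1) ve[2] else NA))
  invisible(x)
}

#' Select strong contributors to a principal component
#'
#' Flags features whose loading on a chosen component lies beyond
#' `k_sd` standard deviations from the mean loading of that component:
#' positive contributors above `mean + k_sd * sd`, negative below
#' `mean - k_sd * sd`.
#'
#' @param loadings_k named numeric vector of loadings for one component
#'   (>= 3 values), e.g. `pca$loadings[, 2]`.
#' @param k_sd threshold in loading-sd units (default 2).
#' @return list with character vectors `positive` and `negative`.
#' @export
select_contributors <- function(loadings_k, k_sd = 2) {
  if (length(loadings_k) < 3) stop("need at least 3 loadings")
  mu <- mean(loadings_k)
  sdv <- stats::sd(loadings_k)
  if (sdv == 0) {
    warning("constant loadings; no contributors selectable")
    return(list(positive = character(0), negative = character(0)))
  }
  list(positive = names(loadings_k)[loadings_k > mu + k_sd * sdv],
       negative = names(loadings_k)[loadings_k < mu - k_sd * sdv])
}

#' Hierarchical clustering of features on correlation distance
#'
#' Agglomerative clustering of matrix rows with pairwise distance
#' `d(a, b) = 1 - pearson_r(a, b)` and the Ward.D2 linkage update. Ward
#' linkage on a non-Euclidean distance is a widely used heuristic here, as
#' in standard heatmap software.
#'
#' @param z a row-z-scored [intensity_matrix()] (or any matrix container
#'   with >= 2 non-constant rows).
#' @return list with `hclust` (the [stats::hclust()] tree) and `order`
#'   (leaf order, feature names).
#' @export
cluster_rows <- function(z) {
  stopifnot(inherits(z, "intensity_matrix"))
  v <- z$values
  if (nrow(v) < 2) stop("need at least 2 rows to cluster")
  sdv <- apply(v, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("constant row(s) have undefined correlation; drop them in preprocessing (row_zscore)")
  }
  d <- stats::as.dist(1 - stats::cor(t(v)))
  hc <- stats::hclust(d, method = "ward.D2")
  list(hclust = hc, order = rownames(v)[hc$order])
}

#' Export a clustering as a Newick tree
#'
#' @param clustering result of [cluster_rows()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Four-way classification of NO dependence from condition-mean z-scores
#'
#' For each feature of a row-z-scored matrix over the donor-free factorial
#' cells, computes condition means of replicate z-scores and the three
#' effect statistics
#' \itemize{
#'   \item `wt_stim_effect  = mean(WT stim)   - mean(WT unstim)`
#'   \item `inos_stim_effect = mean(KO stim)  - mean(KO unstim)`
#'   \item `no_effect = wt_stim_effect - inos_stim_effect`
#' }
#' and assigns one of four mutually exclusive, exhaustive categories:
#' \itemize{
#'   \item `NO_dep_up`: `wt_stim_effect > wt_thresh` and `no_effect > no_thresh`
#'   \item `NO_dep_down`: `wt_stim_effect < -wt_thresh` and `no_effect < -no_thresh`
#'   \item `NO_independent`: `|wt_stim_effect| > wt_thresh`,
#'     `|inos_stim_effect| > wt_thresh`, and `|no_effect| < no_thresh`
#'   \item `under_threshold`: everything else.
#' }
#' The rules are checked in that order, which makes the partition exhaustive
#' for any real-valued effect triple.
#'
#' To analyse a donor-rescue comparison instead, remap the design so that
#' the donor axis plays the role of stimulation and call this function on
#' the remapped design.
#'
#' @param z a row-z-scored [intensity_matrix()].
#' @param design optional design table (defaults to the one attached to
#'   `z`); must contain all four donor-free genotype x stimulation cells.
#' @param wt_thresh threshold on the stimulation effects (z units,
#'   default 0.4).
#' @param no_thresh threshold on the NO-specific effect (z units,
#'   default 0.5).
#' @return an `EffectClassification` data.frame: `gene_symbol`,
#'   `wt_stim_effect`, `inos_stim_effect`, `no_effect`, `category`.
#' @export
classify_no_dependence <- function(z, design = NULL, wt_thresh = 0.4, no_thresh = 0.5) {
  stopifnot(inherits(z, "intensity_matrix"))
  if (z$scale_state != "zscored") stop("classification operates on row z-scores")
  if (is.null(design)) design <- z$design
  if (is.null(design)) stop("no design available")
  cells <- list(wt_un = select_samples(design, genotype = "WT", stimulation = "unstim", donor = "none"),
                wt_st = select_samples(design, genotype = "WT", stimulation = "stim", donor = "none"),
                ko_un = select_samples(design, genotype = "iNOS_KO", stimulation = "unstim", donor = "none"),
                ko_st = select_samples(design, genotype = "iNOS_KO", stimulation = "stim", donor = "none"))
  if (any(lengths(cells) == 0)) {
    stop("design must contain all four donor-free genotype x stimulation cells")
  }
  cm <- vapply(cells, function(s) rowMeans(z$values[, s, drop = FALSE]),
               numeric(nrow(z$values)))
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1, dimnames = list(NULL, names(cells)))
  wt_eff <- cm[, "wt_st"] - cm[, "wt_un"]
  ko_eff <- cm[, "ko_st"] - cm[, "ko_un"]
  no_eff <- wt_eff - ko_eff
  data.frame(gene_symbol = rownames(z$values),
             wt_stim_effect = wt_eff,
             inos_stim_effect = ko_eff,
             no_effect = no_eff,
             category = classify_effect_triple(wt_eff, ko_eff, no_eff,
                                               wt_thresh, no_thresh),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname classify_no_dependence
#' @param wt_eff,ko_eff,no_eff numeric vectors of effect statistics
#'   (recycled to common length); `no_eff` defaults to `wt_eff - ko_eff`.
#' @export
classify_effect_triple <- function(wt_eff, ko_eff, no_eff = wt_eff - ko_eff,
                                   wt_thresh = 0.4, no_thresh = 0.5) {
  cat_v <- rep("under_threshold", length(wt_eff))
  cat_v[abs(wt_eff) > wt_thresh & abs(ko_eff) > wt_thresh & abs(no_eff) < no_thresh] <- "NO_independent"
  cat_v[wt_eff > wt_thresh & no_eff > no_thresh] <- "NO_dep_up"
  cat_v[wt_eff < -wt_thresh & no_eff < -no_thresh] <- "NO_dep_down"
  cat_v
}
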