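#' Omics matrix containers
#'
#' Lightweight S3 containers modelled on the expression-list convention of
#' microarray/proteomics packages: a numeric matrix of features x samples
#' plus a sample design table and (for intensities) a scale-state flag.
#'
#' @section Scale states:
#' An `intensity_matrix` tracks its scale through the pipeline:
#' `"linear"` (positive abundances, possibly with `NA` for missing cells),
#' `"log2"` (after [log2_transform()]), and `"zscored"` (after
#' [row_zscore()]). Operations check the state they require so that, e.g.,
#' imputation can only run on log2 values and Welch testing only on linear
#' values.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimnames must be set and unique.
#' @param design `NULL` or a sample design `data.frame` (see
#'   [factorial_design()]) whose `sample_id` column matches
#'   `colnames(values)` in order.
#' @param scale_state one of `"linear"`, `"log2"`, `"zscored"`.
#' @return An object of class `intensity_matrix` or `count_matrix`: a list
#'   with elements `values`, `design`, and (intensities only) `scale_state`.
#' @examples
#' v <- matrix(2^rnorm(6, 20), 3, 2,
#'             dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' m <- intensity_matrix(v)
#' dim(m)
#' @export
intensity_matrix <- function(values, design = NULL, scale_state = "linear") {
  scale_state <- match.arg(scale_state, c("linear", "log2", "zscored"))
  values <- .check_matrix(values)
  if (scale_state == "linear" && any(values <= 0, na.rm = TRUE)) {
    stop("intensity values must be > 0 wherever observed on the linear scale")
  }
  m <- structure(list(values = values, design = NULL, scale_state = scale_state),
                 class = "intensity_matrix")
  if (!is.null(design)) m <- attach_design(m, design)
  m
}

#' @rdname intensity_matrix
#' @export
count_matrix <- function(values, design = NULL) {
  values <- .check_matrix(values)
  if (anyNA(values)) stop("count matrices may not contain missing values")
  if (any(values < 0)) stop("counts must be non-negative")
  if (any(values != round(values))) {
    bad <- which(values != round(values), arr.ind = TRUE)[1, ]
    stop(sprintf("counts must be integers; first violation at row '%s', column '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  m <- structure(list(values = values, design = NULL), class = "count_matrix")
  if (!is.null(design)) m <- attach_design(m, design)
  m
}

.check_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop(sprintf("duplicate feature id: '%s'", rownames(values)[duplicated(rownames(values))][1]))
  }
  if (anyDuplicated(colnames(values))) {
    stop(sprintf("duplicate sample id: '%s'", colnames(values)[duplicated(colnames(values))][1]))
  }
  values
}

#' Attach a sample design table to a matrix container
#'
#' @param m an `intensity_matrix` or `count_matrix`.
#' @param design a design `data.frame` with a `sample_id` column covering all
#'   columns of `m` (reordered to match).
#' @return `m` with `$design` set.
#' @export
attach_design <- function(m, design) {
  stopifnot(inherits(m, c("intensity_matrix", "count_matrix")))
  design <- validate_design(design)
  idx <- match(colnames(m$values), design$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("design is missing sample '%s'",
                 colnames(m$values)[which(is.na(idx))[1]]))
  }
  m$design <- design[idx, , drop = FALSE]
  rownames(m$design) <- NULL
  m
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)
#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale_state))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (!is.null(x$design)) cat("  design:", paste(setdiff(names(x$design), "sample_id"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (total reads %.3g)\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Factorial macrophage sample designs
#'
#' Build the sample design tables used throughout: genotype (wild-type vs
#' iNOS knockout) crossed with LPS/IFNg stimulation, optionally crossed with
#' treatment by the slow-release NO donor DETA-NONOate, with a fixed number
#' of replicates per cell.
#'
#' `bmdm_design()` is the 32-sample primary-macrophage-like layout
#' (2 genotypes x 2 stimulation x 2 donor x 4 replicates); `raw_design()` is
#' the 16-sample macrophage-cell-line-like layout (2 x 2 x 4, no donor arm).
#'
#' @param genotypes,stimulation,donors factor levels to cross.
#' @param replicates replicates per design cell (>= 2).
#' @return A `data.frame` with columns `sample_id`, `genotype`,
#'   `stimulation`, `donor`, `replicate`.
#' @examples
#' table(bmdm_design()$genotype, bmdm_design()$stimulation)
#' @export
factorial_design <- function(genotypes = c("WT", "iNOS_KO"),
                             stimulation = c("unstim", "stim"),
                             donors = "none",
                             replicates = 4) {
  if (replicates < 2) stop("each design cell needs >= 2 replicates")
  cells <- expand.grid(genotype = genotypes, stimulation = stimulation,
                       donor = donors, replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
  cells$sample_id <- sprintf("%s_%s%s_%d", cells$genotype, cells$stimulation,
                             ifelse(cells$donor == "none", "", paste0("_", cells$donor)),
                             cells$replicate)
  validate_design(cells[, c("sample_id", "genotype", "stimulation", "donor", "replicate")])
}

#' @rdname factorial_design
#' @export
bmdm_design <- function(replicates = 4) {
  factorial_design(donors = c("none", "DETA"), replicates = replicates)
}

#' @rdname factorial_design
#' @export
raw_design <- function(replicates = 4) {
  factorial_design(donors = "none", replicates = replicates)
}

#' Validate a sample design table
#'
#' Checks column presence, level membership, unique sample ids, and that
#' every occupied (genotype, stimulation, donor) cell has at least two
#' replicates.
#'
#' @param design a candidate design `data.frame`.
#' @return the validated design (invisibly unchanged).
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "genotype", "stimulation", "donor", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop("sample_ids must be unique")
  if (!all(design$genotype %in% c("WT", "iNOS_KO"))) stop("genotype must be WT or iNOS_KO")
  if (!all(design$stimulation %in% c("unstim", "stim"))) stop("stimulation must be unstim or stim")
  if (!all(design$donor %in% c("none", "DETA"))) stop("donor must be none or DETA")
  n_cell <- table(interaction(design$genotype, design$stimulation, design$donor, drop = TRUE))
  if (any(n_cell < 2)) stop("every occupied design cell needs >= 2 replicates")
  design
}

#' Select sample ids matching a condition
#'
#' @param design a design table.
#' @param ... named filters over design columns, e.g.
#'   `genotype = "WT", stimulation = "stim"`; unspecified columns are
#'   unrestricted.
#' @return character vector of matching sample ids.
#' @export
select_samples <- function(design, ...) {
  sel <- list(...)
  keep <- rep(TRUE, nrow(design))
  for (nm in names(sel)) {
    if (!nm %in% names(design)) stop(sprintf("unknown design column '%s'", nm))
    keep <- keep & design[[nm]] %in% sel[[nm]]
  }
  design$sample_id[keep]
}
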