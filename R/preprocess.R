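#' Normalize each channel (sample column) to relative percentages
#'
#' Scales every column of a complete linear-scale intensity matrix so that
#' the total signal per channel equals 100, as used for TMT reporter
#' intensities. Proportions within a column are preserved, so the operation
#' is idempotent and invariant to per-column rescaling.
#'
#' @param m a complete (no missing cells) linear-scale [intensity_matrix()].
#' @return the normalized matrix, still linear scale.
#' @export
channel_normalize <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale_state != "linear") stop("channel_normalize requires linear-scale intensities")
  if (anyNA(m$values)) {
    stop("matrix has missing cells; run filter_complete() before channel normalization")
  }
  tot <- colSums(m$values)
  if (any(tot == 0)) stop("column(s) summing to zero cannot be normalized")
  m$values <- sweep(m$values, 2, tot / 100, "/")
  m
}

#' Filter features by number of valid (observed) values
#'
#' `mode = "all_valid"` keeps only rows with no missing cells (the complete
#' TMT-style rule); `mode = "min_valid"` keeps rows with at least
#' `min_valid` observed values (e.g. 16 of 32 samples for DIA data).
#'
#' @param m an [intensity_matrix()].
#' @param mode filtering rule.
#' @param min_valid minimum observed count for `mode = "min_valid"`.
#' @return the filtered matrix; the number of removed rows is reported via
#'   `message()`.
#' @export
filter_complete <- function(m, mode = c("min_valid", "all_valid"), min_valid = 16L) {
  stopifnot(inherits(m, "intensity_matrix"))
  mode <- match.arg(mode)
  n_obs <- rowSums(!is.na(m$values))
  if (mode == "all_valid") min_valid <- ncol(m$values)
  if (min_valid > ncol(m$values)) {
    stop(sprintf("min_valid (%d) exceeds the number of samples (%d)",
                 min_valid, ncol(m$values)))
  }
  keep <- n_obs >= min_valid
  message(sprintf("filter_complete: removed %d of %d features", sum(!keep), length(keep)))
  m$values <- m$values[keep, , drop = FALSE]
  m
}

#' Log2 and inverse transforms
#'
#' Elementwise `log2` of a linear-scale matrix and its inverse
#' (`2^x`). The missingness mask is untouched; `back_transform()` after
#' [log2_transform()] restores the input to within floating-point error.
#'
#' @param m an [intensity_matrix()].
#' @return the transformed matrix with updated `scale_state`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale_state != "linear") stop("log2_transform requires linear-scale intensities")
  if (any(m$values <= 0, na.rm = TRUE)) stop("log2 of a non-positive observed value")
  m$values <- log2(m$values)
  m$scale_state <- "log2"
  m
}

#' @rdname log2_transform
#' @export
back_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale_state != "log2") stop("back_transform requires log2-scale intensities")
  m$values <- 2^m$values
  m$scale_state <- "linear"
  m
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Replaces each missing cell of a log2-scale matrix, separately for each
#' column, with a draw from
#' `Normal(mu_j - downshift * sigma_j, (width * sigma_j)^2)`, where `mu_j`
#' and `sigma_j` are the observed mean and (n-1) standard deviation of
#' column `j`. This emulates the common proteomics convention of imputing
#' left-censored missing values from a narrowed Gaussian shifted into the
#' low-abundance tail.
#'
#' @param m a log2-scale [intensity_matrix()].
#' @param width width of the imputation Gaussian relative to the column sd
#'   (default 0.3).
#' @param downshift shift below the column mean in column-sd units
#'   (default 1.8).
#' @param seed optional integer seed for reproducible imputation.
#' @return the matrix with all missing cells filled.
#' @export
impute_downshifted <- function(m, width = 0.3, downshift = 1.8, seed = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale_state != "log2") stop("impute_downshifted requires log2-scale intensities")
  n_obs <- colSums(!is.na(m$values))
  if (any(n_obs < 3)) {
    stop(sprintf("column '%s' has fewer than 3 observed values; sd is unstable",
                 colnames(m$values)[which(n_obs < 3)[1]]))
  }
  draw <- function() {
    for (j in seq_len(ncol(m$values))) {
      miss <- is.na(m$values[, j])
      if (!any(miss)) next
      mu <- mean(m$values[, j], na.rm = TRUE)
      sdj <- stats::sd(m$values[, j], na.rm = TRUE)
      m$values[miss, j] <<- stats::rnorm(sum(miss), mu - downshift * sdj, width * sdj)
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  m
}

#' Row-wise z-scoring
#'
#' Centers and scales each row of a complete log2-scale matrix to mean 0 and
#' (n-1) standard deviation 1. Constant rows, whose z-score is undefined,
#' are dropped with a `message()`.
#'
#' @param m a complete log2-scale [intensity_matrix()].
#' @return the z-scored matrix (`scale_state = "zscored"`).
#' @export
row_zscore <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale_state != "log2") stop("row_zscore requires log2-scale intensities")
  if (anyNA(m$values)) stop("row_zscore requires a complete matrix; impute or filter first")
  mu <- rowMeans(m$values)
  sdv <- apply(m$values, 1, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    message(sprintf("row_zscore: dropped %d constant row(s)", sum(const)))
  }
  m$values <- (m$values[!const, , drop = FALSE] - mu[!const]) / sdv[!const]
  m$scale_state <- "zscored"
  m
}
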