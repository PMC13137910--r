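#' Read a features x samples matrix from TSV
#'
#' Reads a tab-delimited matrix with feature ids in the first column and
#' sample ids in the header. Leading `#` comment lines (provenance headers
#' written by this package) are skipped. `"NA"`, `"NaN"` and empty cells
#' parse as missing.
#'
#' @param path file path.
#' @param kind `"intensity"` (positive reals or missing) or `"counts"`
#'   (non-negative integers, no missing).
#' @param design optional design table to attach.
#' @return an [intensity_matrix()] or [count_matrix()].
#' @export
read_matrix <- function(path, kind = c("intensity", "counts"), design = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop("matrix file must have a header and at least one row")
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1) {
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 which(nfield != nfield[1])[1], nfield[nfield != nfield[1]][1], nfield[1]))
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""))
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   vals[[j]][bad], ids[bad], names(vals)[j]))
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- ids
  message(sprintf("read %s matrix: %d features x %d samples", kind,
                  nrow(values), ncol(values)))
  if (kind == "counts") {
    if (anyNA(values)) stop("count matrix contains missing cells")
    bad <- which(values != round(values) | values < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("counts must be non-negative integers; violation at row '%s', column '%s'",
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
    }
    count_matrix(values, design = design)
  } else {
    if (any(values <= 0, na.rm = TRUE)) {
      bad <- which(values <= 0, arr.ind = TRUE)
      stop(sprintf("intensities must be > 0 where observed; violation at row '%s', column '%s'",
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
    }
    intensity_matrix(values, design = design, scale_state = "linear")
  }
}

#' Write a matrix container to TSV
#'
#' Missing cells are written as `"NA"`. An optional `# `-prefixed provenance
#' header (package version plus a caller-supplied tag such as a config hash)
#' is prepended; [read_matrix()] skips it.
#'
#' @param m an `intensity_matrix` or `count_matrix`.
#' @param path output path.
#' @param id_col name for the feature-id column.
#' @param provenance optional character tag recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature_id", provenance = NULL) {
  stopifnot(inherits(m, c("intensity_matrix", "count_matrix")))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# noremod %s %s",
                       as.character(utils::packageVersion("noremod")), provenance), con)
  }
  df <- data.frame(rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a sample design table
#'
#' @param path TSV path with columns `sample_id`, `genotype`, `stimulation`,
#'   `donor`, `replicate`.
#' @return validated design `data.frame`.
#' @export
read_design <- function(path) {
  validate_design(utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"))
}

#' @rdname read_design
#' @param design a design table.
#' @export
write_design <- function(design, path) {
  utils::write.table(validate_design(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set library in GMT format
#'
#' Each line is `set_name TAB description TAB member TAB member ...`.
#' Members are uppercased for case-insensitive matching downstream and
#' deduplicated within a set.
#'
#' @param path GMT file path.
#' @return a `gene_set_library`: list with `sets` (named list of uppercase
#'   member vectors) and `description` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("GMT line %d has %d field(s); need name, description, and >= 1 member",
                 short[1], lengths(fields)[short[1]]))
  }
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene-set name '%s'", nm[duplicated(nm)][1]))
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nm
  desc <- vapply(fields, `[[`, "", 2)
  names(desc) <- nm
  structure(list(sets = sets, description = desc), class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library: %d sets, %d distinct members\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Read a protein-accession to gene-symbol mapping table
#'
#' @param path TSV with header `accession<TAB>gene_symbol`.
#' @return data.frame with unique accessions and non-empty gene symbols.
#' @export
read_feature_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("accession", "gene_symbol") %in% names(map))) {
    stop("feature map must have columns 'accession' and 'gene_symbol'")
  }
  if (anyDuplicated(map$accession)) stop("accessions must be unique")
  if (any(is.na(map$gene_symbol) | !nzchar(map$gene_symbol))) {
    stop("gene_symbol must be non-empty for every accession")
  }
  map
}

#' Collapse protein isoforms to gene-level rows
#'
#' Maps feature accessions to gene symbols and collapses multiple rows per
#' gene by averaging quantified linear-scale intensities across isoforms.
#' The mean is taken over observed values only; a collapsed cell is missing
#' only when all contributing isoform cells are missing. Unmapped features
#' are dropped (count reported via `message()`). Matching of gene symbols is
#' case-insensitive; the first-seen spelling is kept for output.
#'
#' @param m a linear-scale [intensity_matrix()].
#' @param map a feature map (see [read_feature_map()]).
#' @return an [intensity_matrix()] with one row per distinct mapped gene.
#' @examples
#' v <- matrix(c(10, 20, 30, NA, 5, 6), 3, 2,
#'             dimnames = list(c("A1", "A2", "B1"), c("s1", "s2")))
#' map <- data.frame(accession = c("A1", "A2", "B1"),
#'                   gene_symbol = c("GeneA", "GeneA", "GeneB"))
#' collapse_to_genes(intensity_matrix(v), map)$values
#' @export
collapse_to_genes <- function(m, map) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale_state != "linear") stop("collapse_to_genes requires linear-scale intensities")
  if (nrow(map) == 0) stop("feature map is empty")
  idx <- match(rownames(m$values), map$accession)
  unmapped <- sum(is.na(idx))
  if (unmapped) message(sprintf("dropping %d unmapped feature(s)", unmapped))
  keep <- !is.na(idx)
  if (!any(keep)) stop("no features could be mapped to gene symbols")
  vals <- m$values[keep, , drop = FALSE]
  sym <- map$gene_symbol[idx[keep]]
  key <- toupper(sym)
  display <- sym[!duplicated(key)]
  names(display) <- key[!duplicated(key)]
  grp <- factor(key, levels = unique(key))
  obs <- !is.na(vals)
  sums <- rowsum(ifelse(obs, vals, 0), grp)
  ns <- rowsum(obs + 0, grp)
  out <- sums / ns
  out[ns == 0] <- NA_real_
  rownames(out) <- unname(display[rownames(out)])
  intensity_matrix(out, design = m$design, scale_state = "linear")
}

#' Write a differential-result or other result table to TSV
#'
#' @param df a data.frame.
#' @param path output path.
#' @param provenance optional tag for the `# ` header comment.
#' @export
write_result_table <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# noremod %s %s",
                       as.character(utils::packageVersion("noremod")), provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
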