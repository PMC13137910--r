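#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the overlap `X` between a gene set of size `K` and a
#' query of size `n` drawn without replacement from a universe of size `N`.
#' Computed exactly via [stats::phyper()]; stable for universes up to at
#' least 1e6 genes.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K gene-set size within the universe.
#' @param n query size within the universe.
#' @param N universe size (`K, n <= N`).
#' @return the upper-tail probability.
#' @examples
#' hypergeom_upper(3, 5, 5, 20)  # 1126/15504
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (K > N || n > N) stop("set and query sizes cannot exceed the universe")
  if (k < 0 || k > min(K, n)) stop("overlap k must lie in [0, min(K, n)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' Local replacement for web-service enrichment: every set in the library
#' is trimmed to the universe, its overlap with the query is scored with
#' the upper-tail hypergeometric test, and p-values are BH-adjusted across
#' all sets in the library. All matching is case-insensitive and query
#' duplicates are ignored.
#'
#' @param query character vector of gene symbols (subset of the universe;
#'   genes outside it are dropped with a warning).
#' @param library a `gene_set_library` from [read_gmt()].
#' @param universe character vector of background gene symbols (e.g. all
#'   quantified genes).
#' @param alpha BH-adjusted significance cutoff for the filtered report
#'   (default 0.05).
#' @param top_k truncate the filtered report to the `top_k` most significant
#'   sets (default `Inf`).
#' @param filter if `FALSE`, return all sets unfiltered (still ranked).
#' @return an `EnrichmentResult` data.frame: `set_name`, `overlap_count`,
#'   `set_size`, `query_size`, `universe_size`, `p_raw`, `p_adj`,
#'   `overlap_members` (semicolon-joined), ranked by `p_adj` then `p_raw`.
#' @export
enrich <- function(query, library, universe, alpha = 0.05, top_k = Inf,
                   filter = TRUE) {
  stopifnot(inherits(library, "gene_set_library"))
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("universe is empty")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe were dropped", length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(library$sets), function(nm) {
    members <- intersect(library$sets[[nm]], universe)
    overlap <- intersect(members, query)
    data.frame(set_name = nm,
               overlap_count = length(overlap),
               set_size = length(members),
               query_size = n,
               universe_size = N,
               p_raw = hypergeom_upper(length(overlap), length(members), n, N),
               overlap_members = paste(sort(overlap), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_raw)
  res <- res[order(res$p_adj, res$p_raw, res$set_name), , drop = FALSE]
  if (filter) {
    res <- res[res$p_adj < alpha, , drop = FALSE]
    if (nrow(res) > top_k) res <- res[seq_len(top_k), , drop = FALSE]
  }
  rownames(res) <- NULL
  res[, c("set_name", "overlap_count", "set_size", "query_size",
          "universe_size", "p_raw", "p_adj", "overlap_members")]
}
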