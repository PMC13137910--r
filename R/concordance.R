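#' Match two differential-result tables by gene symbol
#'
#' Case-insensitive inner join of two `DiffResult` tables; unmatched counts
#' on either side are reported via `message()`.
#'
#' @param a,b `DiffResult` data.frames (unique gene symbols each).
#' @return a paired data.frame with columns `gene_symbol` (spelling from
#'   `a`), `lfc_a`, `padj_a`, `lfc_b`, `padj_b`.
#' @export
match_genes <- function(a, b) {
  ka <- toupper(a$gene_symbol); kb <- toupper(b$gene_symbol)
  if (anyDuplicated(ka)) stop("duplicate gene symbols in table a; collapse isoforms first")
  if (anyDuplicated(kb)) stop("duplicate gene symbols in table b; collapse isoforms first")
  idx <- match(ka, kb)
  keep <- !is.na(idx)
  message(sprintf("match_genes: paired %d genes (%d only in a, %d only in b)",
                  sum(keep), sum(!keep), nrow(b) - sum(keep)))
  if (!any(keep)) warning("no genes in common between the two tables")
  data.frame(gene_symbol = a$gene_symbol[keep],
             lfc_a = a$log2fc[keep], padj_a = a$p_adj[keep],
             lfc_b = b$log2fc[idx[keep]], padj_b = b$p_adj[idx[keep]],
             stringsAsFactors = FALSE)
}

#' Five-category significance concordance
#'
#' Labels each paired gene by agreement of significance and fold-change
#' direction between the two datasets:
#' `both_concordant` (significant in both, same direction), `both_opposite`
#' (significant in both, opposite directions), `only_a` / `only_b`
#' (dataset-specific significance), `neither`. A fold change of exactly 0
#' in one significant dataset is treated as concordant with the other
#' dataset's sign.
#'
#' @param paired output of [match_genes()].
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return list with `records` (the paired table plus `category` and
#'   `strong_quadrant` placeholder) and `counts` (named category counts).
#' @export
classify_concordance <- function(paired, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nrow(paired) == 0) stop("paired table is empty")
  sig_a <- paired$padj_a < alpha
  sig_b <- paired$padj_b < alpha
  same_dir <- sign(paired$lfc_a) == sign(paired$lfc_b) |
    paired$lfc_a == 0 | paired$lfc_b == 0
  category <- ifelse(sig_a & sig_b, ifelse(same_dir, "both_concordant", "both_opposite"),
              ifelse(sig_a, "only_a", ifelse(sig_b, "only_b", "neither")))
  records <- cbind(paired,
                   data.frame(category = category, strong_quadrant = "none",
                              stringsAsFactors = FALSE))
  lv <- c("both_concordant", "both_opposite", "only_a", "only_b", "neither")
  counts <- table(factor(category, levels = lv))
  list(records = records, counts = c(counts))
}

#' Pearson correlation of fold changes with significance test
#'
#' @param paired output of [match_genes()] with >= 3 rows.
#' @return list with `r`, `p` (two-sided, from the t transform with n-2
#'   df), and `n`.
#' @export
correlation_with_test <- function(paired) {
  if (nrow(paired) < 3) stop("need at least 3 paired genes")
  if (stats::sd(paired$lfc_a) == 0 || stats::sd(paired$lfc_b) == 0) {
    stop("zero variance in fold changes; correlation undefined")
  }
  ct <- stats::cor.test(paired$lfc_a, paired$lfc_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(paired))
}

#' Strong-responder quadrants
#'
#' Among concordant genes, flags robust responders meeting
#' `|log2FC| > lfc_cut` and adjusted p < `alpha` in both datasets as
#' `both_up` or `both_down`. Within each quadrant, genes are ranked by the
#' sum of absolute fold changes (descending) and the top `top_k` are
#' labelled.
#'
#' @param records the `records` table from [classify_concordance()].
#' @param lfc_cut fold-change magnitude cutoff (default 0.5).
#' @param alpha significance threshold (default 0.05).
#' @param top_k how many genes per quadrant to label (default 20).
#' @return the records with `strong_quadrant` filled, plus columns
#'   `quadrant_rank` (within-quadrant rank, NA outside quadrants) and
#'   `top_labelled` (logical).
#' @export
strong_responders <- function(records, lfc_cut = 0.5, alpha = 0.05, top_k = 20L) {
  strong <- records$category == "both_concordant" &
    abs(records$lfc_a) > lfc_cut & abs(records$lfc_b) > lfc_cut &
    records$padj_a < alpha & records$padj_b < alpha
  records$strong_quadrant <- ifelse(strong & records$lfc_a > 0, "both_up",
                             ifelse(strong & records$lfc_a < 0, "both_down", "none"))
  records$quadrant_rank <- NA_integer_
  records$top_labelled <- FALSE
  for (q in c("both_up", "both_down")) {
    idx <- which(records$strong_quadrant == q)
    if (!length(idx)) next
    score <- abs(records$lfc_a[idx]) + abs(records$lfc_b[idx])
    ord <- idx[order(-score, records$gene_symbol[idx])]
    records$quadrant_rank[ord] <- seq_along(ord)
    records$top_labelled[ord[seq_len(min(top_k, length(ord)))]] <- TRUE
  }
  records
}

#' Triple-concordant downregulated genes
#'
#' Keeps genes significantly downregulated (`p_adj < alpha` and
#' `log2fc < 0`) in all three datasets (typically two proteomes and one
#' transcriptome) — the highest-confidence targets of NO-dependent
#' induction — and rank-orders them from most to least downregulated by the
#' designated ranking dataset's fold change (ties broken by gene symbol).
#' Each gene is annotated with `no_inducible`: whether it is significantly
#' upregulated by stimulation in wild-type cells (`wt_stim` table,
#' `p_adj < alpha` and `log2fc > 0`); genes absent from `wt_stim` get `NA`
#' with a `message()`.
#'
#' @param a,b,c `DiffResult` data.frames.
#' @param wt_stim `DiffResult` for the wild-type stimulated vs unstimulated
#'   contrast used for the inducibility flag.
#' @param alpha significance threshold (default 0.05).
#' @param rank_by which dataset's fold change orders the result
#'   (`"a"`, `"b"`, or `"c"`; default `"b"`).
#' @return data.frame with `gene_symbol`, `lfc_a`, `lfc_b`, `lfc_c`,
#'   `rank`, `no_inducible`.
#' @export
triple_concordance <- function(a, b, c, wt_stim, alpha = 0.05,
                               rank_by = c("b", "a", "c")) {
  rank_by <- match.arg(rank_by)
  tabs <- list(a = a, b = b, c = c)
  for (nm in names(tabs)) {
    if (anyDuplicated(toupper(tabs[[nm]]$gene_symbol))) {
      stop(sprintf("duplicate gene symbols in table %s", nm))
    }
  }
  keys <- lapply(tabs, function(t) toupper(t$gene_symbol))
  common <- Reduce(intersect, keys)
  pick <- function(nm) {
    t <- tabs[[nm]]
    i <- match(common, keys[[nm]])
    data.frame(lfc = t$log2fc[i], padj = t$p_adj[i])
  }
  pa <- pick("a"); pb <- pick("b"); pc_ <- pick("c")
  down <- pa$padj < alpha & pa$lfc < 0 &
          pb$padj < alpha & pb$lfc < 0 &
          pc_$padj < alpha & pc_$lfc < 0
  sym <- tabs$a$gene_symbol[match(common, keys$a)]
  out <- data.frame(gene_symbol = sym[down],
                    lfc_a = pa$lfc[down], lfc_b = pb$lfc[down], lfc_c = pc_$lfc[down],
                    stringsAsFactors = FALSE)
  rank_col <- c(a = "lfc_a", b = "lfc_b", c = "lfc_c")[[rank_by]]
  ord <- order(out[[rank_col]], out$gene_symbol)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))

  wkey <- toupper(wt_stim$gene_symbol)
  wi <- match(toupper(out$gene_symbol), wkey)
  if (anyNA(wi) && nrow(out)) {
    message(sprintf("triple_concordance: %d gene(s) absent from the wt_stim table; flag set to NA",
                    sum(is.na(wi))))
  }
  out$no_inducible <- wt_stim$p_adj[wi] < alpha & wt_stim$log2fc[wi] > 0
  rownames(out) <- NULL
  out
}
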