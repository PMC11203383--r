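#' Fisher's-exact over-representation analysis
#'
#' Tests each gene set for over-representation of the query list within the
#' universe via the one-sided hypergeometric tail (equivalent to Fisher's
#' exact test with alternative "greater" on the 2x2 table). Query genes
#' absent from the universe are dropped with a message; set members are
#' intersected with the universe before testing. P-values are adjusted by
#' Benjamini–Hochberg across all tested sets and a set is flagged
#' significant when its adjusted p is below `fdr_threshold`.
#'
#' @param query Character vector of genes of interest (e.g. called DEGs).
#' @param universe Character vector of all assayed genes.
#' @param sets A gene-set collection from [read_gmt()], or a named list of
#'   character vectors.
#' @param categories Optional named character vector of category labels per
#'   set (e.g. BP/CC/MF); defaults to the collection's description attribute.
#' @param fdr_threshold Significance cutoff on the adjusted p (default 0.05).
#' @return A data.frame with one row per set: `set`, `category`, `overlap`,
#'   `query_size`, `set_size`, `universe_size`, `odds_ratio`, `p_value`,
#'   `p_adj`, `significant`.
#' @export
fisher_ora <- function(query, universe, sets, categories = NULL,
                       fdr_threshold = 0.05) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(length(dropped), " query gene(s) absent from the universe, dropped")
    query <- intersect(query, universe)
  }
  if (is.null(categories)) {
    descr <- attr(sets, "description")
    categories <- if (is.null(descr)) setNames(rep("", length(sets)),
                                               names(sets)) else descr
  }
  empty <- data.frame(set = character(0), category = character(0),
                      overlap = integer(0), query_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("empty query after universe filtering; returning no results")
    return(empty)
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    m <- length(members)
    if (m == 0L) return(NULL)
    x <- length(intersect(members, query))
    # one-sided enrichment tail: P(overlap >= x)
    p <- stats::phyper(x - 1, m, N - m, q, lower.tail = FALSE)
    a <- x; b <- q - x; cc <- m - x; d <- N - m - q + x
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(set = nm, category = unname(categories[nm]),
               overlap = x, query_size = q, set_size = m, universe_size = N,
               odds_ratio = or, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  res$p_adj <- bh_adjust(res$p_value)
  res$significant <- res$p_adj < fdr_threshold
  res[order(res$p_adj, res$p_value, res$set), , drop = FALSE]
}

#' Top enriched terms per category
#'
#' Within each category, significant terms are ordered by adjusted p
#' (ascending), ties broken by larger overlap then by set name, and
#' truncated to `per_category` entries.
#'
#' @param results A [fisher_ora()] result table.
#' @param per_category Maximum terms returned per category (default 10).
#' @return The truncated table.
#' @export
top_terms <- function(results, per_category = 10L) {
  stopifnot(is.data.frame(results), "category" %in% colnames(results))
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  keep <- unlist(lapply(split(seq_len(nrow(sig)), sig$category), function(idx) {
    ord <- idx[order(sig$p_adj[idx], -sig$overlap[idx], sig$set[idx])]
    utils::head(ord, per_category)
  }), use.names = FALSE)
  out <- sig[keep, , drop = FALSE]
  out[order(out$category, out$p_adj, -out$overlap, out$set), , drop = FALSE]
}
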