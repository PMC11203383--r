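#' Configuration for a CASh analysis
#'
#' @param prescreen_alpha Raw-p cutoff used to preselect genes before the
#'   game stage; the published analyses use 0.01 (restrictive) or 0.05.
#' @param prescreen_test Test providing the raw prescreen p-values,
#'   `"welch"` (default) or `"ebayes"`.
#' @param n_boot Bootstrap iterations for the resampling null (default 1000,
#'   minimum 100).
#' @param p_threshold Final significance cutoff on the (possibly adjusted)
#'   bootstrap p-value; defaults to `prescreen_alpha`.
#' @param apply_fdr Apply Benjamini–Hochberg adjustment (within direction,
#'   over the prescreened family) before thresholding.
#' @param fc_threshold Linear fold-change gate; a gene is only called when
#'   `|signed FC| > fc_threshold` (default 2).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `cash_config`.
#' @export
cash_config <- function(prescreen_alpha = 0.05,
                        prescreen_test = c("welch", "ebayes"),
                        n_boot = 1000L,
                        p_threshold = prescreen_alpha,
                        apply_fdr = FALSE,
                        fc_threshold = 2,
                        seed = 1L) {
  prescreen_test <- match.arg(prescreen_test)
  if (n_boot < 100L) stop("n_boot must be at least 100")
  stopifnot(prescreen_alpha > 0, prescreen_alpha <= 1,
            p_threshold > 0, p_threshold <= 1, fc_threshold > 0)
  structure(list(prescreen_alpha = prescreen_alpha,
                 prescreen_test = prescreen_test,
                 n_boot = as.integer(n_boot),
                 p_threshold = p_threshold,
                 apply_fdr = isTRUE(apply_fdr),
                 fc_threshold = fc_threshold,
                 seed = as.integer(seed)),
            class = "cash_config")
}

#' Raw-p prescreen of an expression matrix
#'
#' Keeps the genes whose raw p-value from the configured classical test
#' falls below `prescreen_alpha`, preserving input gene order. An empty
#' survivor set is returned as a 0-row matrix (the caller reports an empty
#' result rather than failing).
#'
#' @param expr Log2 expression matrix.
#' @param design Design data.frame.
#' @param config A [cash_config()].
#' @return The reduced matrix, with attributes `prescreen_p` (raw p-values of
#'   the retained genes) and `n_input`.
#' @export
prescreen <- function(expr, design, config) {
  stopifnot(inherits(config, "cash_config"))
  de <- switch(config$prescreen_test,
               welch = welch_t(expr, design),
               ebayes = moderated_t(expr, design))
  keep <- de$p_value < config$prescreen_alpha
  structure(expr[keep, , drop = FALSE],
            prescreen_p = de$p_value[keep],
            n_input = nrow(expr))
}

#' @keywords internal
#' Shapley values of a column subset of a boolean matrix (closed form).
phi_columns <- function(B, idx) {
  sub <- B[, idx, drop = FALSE]
  s <- colSums(sub)
  nz <- s > 0
  if (!any(nz)) return(numeric(nrow(B)))
  as.vector(sub[, nz, drop = FALSE] %*% (1 / s[nz])) / length(idx)
}

#' Case-versus-control Shapley contrast
#'
#' Booleanizes the matrix in the given direction (thresholds from controls),
#' splits the boolean columns by group, computes the Shapley value of each
#' group's microarray game, and returns the per-gene difference.
#'
#' @param expr Expression matrix (typically the prescreened one).
#' @param design Design data.frame.
#' @param direction `"over"` or `"under"`.
#' @return A data.frame with columns `gene_id`, `phi_case`, `phi_control`,
#'   `delta_phi`.
#' @export
cash_contrast <- function(expr, design, direction = c("over", "under")) {
  direction <- match.arg(direction)
  design <- validate_design(design, expr)
  B <- booleanize_all(expr, design, direction)
  case_idx <- match(design$sample_id[design$group == "case"], colnames(B))
  ctrl_idx <- match(design$sample_id[design$group == "control"], colnames(B))
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L) {
    stop("each group needs at least 2 arrays for the Shapley contrast")
  }
  phi_case <- phi_columns(B, case_idx)
  phi_control <- phi_columns(B, ctrl_idx)
  data.frame(gene_id = rownames(expr),
             phi_case = phi_case, phi_control = phi_control,
             delta_phi = phi_case - phi_control,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bootstrap p-values for the Shapley contrast
#'
#' Null of sample exchangeability: the booleanized columns of both groups are
#' pooled, and each iteration redraws `k_case` "case" and `k_control`
#' "control" columns with replacement from the pool and recomputes the
#' contrast. The one-sided p-value per gene is
#' `(1 + #\{b : delta*_b >= delta_obs\}) / (n_boot + 1)`, testing
#' case enrichment in the given direction; it is bounded below by
#' `1 / (n_boot + 1)`.
#'
#' @param expr Expression matrix (typically prescreened).
#' @param design Design data.frame.
#' @param direction `"over"` or `"under"`.
#' @param config A [cash_config()]; `seed` and `n_boot` are used.
#' @return A data.frame with `gene_id`, `delta_phi` (observed), `p_boot`.
#' @export
bootstrap_p <- function(expr, design, direction = c("over", "under"),
                        config = cash_config()) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "cash_config"))
  design <- validate_design(design, expr)
  obs <- cash_contrast(expr, design, direction)
  B <- booleanize_all(expr, design, direction)
  k1 <- sum(design$group == "case")
  k2 <- sum(design$group == "control")
  k <- ncol(B)
  set.seed(config$seed)
  count_ge <- integer(nrow(B))
  for (b in seq_len(config$n_boot)) {
    idx1 <- sample.int(k, k1, replace = TRUE)
    idx2 <- sample.int(k, k2, replace = TRUE)
    delta_star <- phi_columns(B, idx1) - phi_columns(B, idx2)
    count_ge <- count_ge + (delta_star >= obs$delta_phi)
  }
  obs$p_boot <- (1 + count_ge) / (config$n_boot + 1)
  obs
}

#' @keywords internal
#' Per-record significance under the configured p and fold-change gates.
flag_significant <- function(records, config) {
  p_used <- if (config$apply_fdr) records$p_adj else records$p_boot
  p_used < config$p_threshold & abs(records$signed_fc) > config$fc_threshold
}

#' Call differentially expressed genes from CASh records
#'
#' A record is significant when its (adjusted, if `apply_fdr`) bootstrap
#' p-value is below `p_threshold` and `|signed FC| > fc_threshold`. A gene
#' significant in both directions keeps the direction with the larger
#' `delta_phi`; ties go to the larger `|log2 FC|`, then to `over`. Calls are
#' `up` from the over-direction analysis and `down` from the under-direction.
#'
#' @param records CASh record table (both directions stacked), as produced
#'   by [run_cash()].
#' @param config A [cash_config()].
#' @return A data.frame of called genes with a `call` column, ordered by
#'   ascending bootstrap p.
#' @export
call_degs <- function(records, config) {
  stopifnot(inherits(config, "cash_config"))
  records$significant <- flag_significant(records, config)
  sig <- records[records$significant, , drop = FALSE]
  if (nrow(sig) > 1L && anyDuplicated(sig$gene_id)) {
    pick <- vapply(split(seq_len(nrow(sig)), sig$gene_id), function(idx) {
      if (length(idx) == 1L) return(idx)
      d <- sig$delta_phi[idx]
      best <- idx[d == max(d)]
      if (length(best) > 1L) {
        fc <- abs(sig$log2_fc[best])
        best <- best[fc == max(fc)]
      }
      if (length(best) > 1L) {
        best <- best[sig$direction[best] == "over"][1L]
        if (is.na(best)) best <- idx[1L]
      }
      best[1L]
    }, integer(1))
    sig <- sig[sort(pick), , drop = FALSE]
  }
  sig$call <- ifelse(sig$direction == "over", "up", "down")
  sig[order(sig$p_boot, sig$gene_id), , drop = FALSE]
}

#' Run the full CASh analysis
#'
#' Pipeline: raw-p prescreen, booleanization in both directions against
#' control thresholds, per-group microarray games and Shapley contrast,
#' bootstrap resampling null, Benjamini–Hochberg adjustment within each
#' direction, and fold-change-gated DEG calling.
#'
#' @param expr Log2 expression matrix.
#' @param design Design data.frame.
#' @param config A [cash_config()].
#' @return An object of class `cash_result`: list with `records` (per gene
#'   and direction: Shapley values, contrast, bootstrap and adjusted p,
#'   fold changes, significance), `degs` (called genes), and `summary`
#'   (gene counts through the stages and total/up/down DEG counts).
#' @export
run_cash <- function(expr, design, config = cash_config()) {
  stopifnot(inherits(config, "cash_config"))
  design <- validate_design(design, expr)
  reduced <- prescreen(expr, design, config)
  n_input <- attr(reduced, "n_input")
  empty_records <- data.frame(gene_id = character(0), direction = character(0),
                              phi_case = numeric(0), phi_control = numeric(0),
                              delta_phi = numeric(0), p_boot = numeric(0),
                              p_adj = numeric(0), log2_fc = numeric(0),
                              signed_fc = numeric(0), significant = logical(0),
                              stringsAsFactors = FALSE)
  if (nrow(reduced) == 0L) {
    degs <- empty_records
    degs$call <- character(0)
    return(structure(list(records = empty_records, degs = degs,
                          summary = list(n_genes = n_input, n_prescreen = 0L,
                                         n_boot = config$n_boot,
                                         total = 0L, up = 0L, down = 0L),
                          config = config),
                     class = "cash_result"))
  }
  fc <- fold_change(reduced, design)
  records <- do.call(rbind, lapply(c("over", "under"), function(dir) {
    boot <- bootstrap_p(reduced, design, dir, config)
    data.frame(gene_id = boot$gene_id, direction = dir,
               phi_case = boot$phi_case, phi_control = boot$phi_control,
               delta_phi = boot$delta_phi, p_boot = boot$p_boot,
               p_adj = bh_adjust(boot$p_boot),
               log2_fc = fc$log2_fc, signed_fc = fc$signed_fc,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  records$significant <- flag_significant(records, config)
  degs <- call_degs(records, config)
  structure(list(records = records, degs = degs,
                 summary = list(n_genes = n_input,
                                n_prescreen = nrow(reduced),
                                n_boot = config$n_boot,
                                total = nrow(degs),
                                up = sum(degs$call == "up"),
                                down = sum(degs$call == "down")),
                 config = config),
            class = "cash_result")
}

#' @export
print.cash_result <- function(x, ...) {
  s <- x$summary
  cat("CASh analysis\n")
  cat(sprintf("  genes: %d input, %d past prescreen (alpha = %g, %s)\n",
              s$n_genes, s$n_prescreen, x$config$prescreen_alpha,
              x$config$prescreen_test))
  cat(sprintf("  bootstrap: %d iterations, seed %d\n",
              s$n_boot, x$config$seed))
  cat(sprintf("  DEGs: %d (%d up, %d down) at p < %g%s, |FC| > %g\n",
              s$total, s$up, s$down, x$config$p_threshold,
              if (x$config$apply_fdr) " (BH)" else "",
              x$config$fc_threshold))
  invisible(x)
}
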