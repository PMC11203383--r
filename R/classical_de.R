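#' @keywords internal
split_groups <- function(expr, design) {
  design <- validate_design(design, expr)
  list(case = expr[, design$sample_id[design$group == "case"], drop = FALSE],
       control = expr[, design$sample_id[design$group == "control"], drop = FALSE])
}

#' @keywords internal
row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

# p-values are floored at the smallest positive double so downstream -log10
# transforms and the (0, 1] contract stay well defined
.p_floor <- function(p) pmax(p, .Machine$double.xmin)

#' Gene-wise Welch t-test
#'
#' Two-sample unequal-variance t-test per gene (case minus control), with
#' Welch–Satterthwaite degrees of freedom, Benjamini–Hochberg adjusted
#' p-values and fold changes. Genes where both group variances are zero are
#' flagged degenerate rather than dropped: with equal means they get
#' `t = 0, p = 1`; with different means the p-value is set to the smallest
#' representable positive double.
#'
#' @param expr Log2 expression matrix (genes x samples).
#' @param design Design data.frame (`sample_id`, `group`).
#' @return A data.frame with columns `gene_id`, `t`, `df`, `p_value`,
#'   `p_adj`, `log2_fc`, `signed_fc`, `degenerate`.
#' @export
welch_t <- function(expr, design) {
  g <- split_groups(expr, design)
  k1 <- ncol(g$case); k2 <- ncol(g$control)
  m1 <- rowMeans(g$case); m2 <- rowMeans(g$control)
  v1 <- row_vars(g$case); v2 <- row_vars(g$control)
  se2 <- v1 / k1 + v2 / k2
  diff <- m1 - m2
  degenerate <- se2 == 0
  t_stat <- ifelse(degenerate, ifelse(diff == 0, 0, sign(diff) * Inf),
                   diff / sqrt(se2))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((v1 / k1)^2 / (k1 - 1L) + (v2 / k2)^2 / (k2 - 1L)))
  p <- ifelse(degenerate, ifelse(diff == 0, 1, .Machine$double.xmin),
              .p_floor(2 * stats::pt(-abs(t_stat), df)))
  fc <- fold_change(expr, design)
  data.frame(gene_id = rownames(expr), t = t_stat, df = df,
             p_value = p, p_adj = bh_adjust(p),
             log2_fc = fc$log2_fc, signed_fc = fc$signed_fc,
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-F hierarchical model for gene-wise sample variances by
#' moment matching on the log scale (the standard digamma/trigamma fit),
#' yielding prior degrees of freedom `d0` and prior variance `s0_sq`. With
#' zero dispersion in the log variances the moment equation has no positive
#' solution and `d0 = Inf` is returned (full moderation towards `s0_sq`).
#'
#' @param s2 Per-gene residual variances.
#' @param df Per-gene residual degrees of freedom (scalar or vector).
#' @return A list with `d0`, `s0_sq`, and the inputs `s2`, `df`.
#' @export
estimate_variance_prior <- function(s2, df) {
  stopifnot(length(s2) >= 10, all(is.finite(s2)), all(s2 >= 0))
  df <- rep_len(df, length(s2))
  stopifnot(all(df >= 1))
  pos <- s2 > 0
  if (sum(pos) < 10) stop("need at least 10 genes with positive variance")
  if (stats::var(log(s2[pos])) == 0) {
    return(list(d0 = Inf, s0_sq = s2[pos][1L], s2 = s2, df = df))
  }
  fit <- limma::fitFDist(s2, df1 = df)
  list(d0 = fit$df2, s0_sq = fit$scale, s2 = s2, df = df)
}

#' Posterior (moderated) gene variances
#'
#' Shrinks each gene's pooled variance towards the prior:
#' `s_tilde^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, with the `d0 = 0`
#' (no moderation) and `d0 = Inf` (all moderation) limits handled exactly.
#'
#' @param s2 Per-gene variances.
#' @param df Per-gene residual degrees of freedom.
#' @param d0,s0_sq Prior degrees of freedom and prior variance.
#' @return Numeric vector of posterior variances.
#' @export
posterior_var <- function(s2, df, d0, s0_sq) {
  if (is.infinite(d0)) return(rep_len(s0_sq, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s0_sq + df * s2) / (d0 + df)
}

#' Empirical-Bayes moderated t-test
#'
#' Two-group moderated t-statistic with pooled within-group variance
#' (`d_g = k_case + k_control - 2`) shrunk towards an estimated (or supplied)
#' prior, referred to a Student t distribution on `d0 + d_g` degrees of
#' freedom (`d0 = Inf` gives the normal reference).
#'
#' @param expr Log2 expression matrix.
#' @param design Design data.frame.
#' @param d0,s0_sq Optional prior overrides; when `NULL` the prior is
#'   estimated from the data via [estimate_variance_prior()].
#' @return A data.frame like [welch_t()]'s, with additional columns `s2`
#'   (pooled variance) and `s2_post` (posterior variance), plus attributes
#'   `d0` and `s0_sq`.
#' @export
moderated_t <- function(expr, design, d0 = NULL, s0_sq = NULL) {
  g <- split_groups(expr, design)
  k1 <- ncol(g$case); k2 <- ncol(g$control)
  dg <- k1 + k2 - 2L
  v1 <- row_vars(g$case); v2 <- row_vars(g$control)
  s2 <- ((k1 - 1L) * v1 + (k2 - 1L) * v2) / dg
  if (is.null(d0) || is.null(s0_sq)) {
    if (sum(s2 > 0) < 10) {
      # too few genes to fit the scaled-F moments: no moderation
      message("fewer than 10 genes with positive variance; ",
              "moderated t falls back to the ordinary pooled t")
      prior <- list(d0 = 0, s0_sq = mean(s2))
    } else {
      prior <- estimate_variance_prior(s2, dg)
    }
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }
  s2_post <- posterior_var(s2, dg, d0, s0_sq)
  diff <- rowMeans(g$case) - rowMeans(g$control)
  se <- sqrt(s2_post * (1 / k1 + 1 / k2))
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, ifelse(diff == 0, 0, sign(diff) * Inf),
                   diff / se)
  df_total <- d0 + dg
  p <- ifelse(degenerate, ifelse(diff == 0, 1, .Machine$double.xmin),
              .p_floor(2 * stats::pt(-abs(t_stat), df_total)))
  fc <- fold_change(expr, design)
  res <- data.frame(gene_id = rownames(expr), t = t_stat,
                    df = rep_len(df_total, nrow(expr)),
                    p_value = p, p_adj = bh_adjust(p),
                    log2_fc = fc$log2_fc, signed_fc = fc$signed_fc,
                    s2 = s2, s2_post = s2_post, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  res
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric within [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene fold change between case and control
#'
#' On log2 input, `log2_fc` is the case-minus-control mean difference; the
#' linear fold change is `2^log2_fc` and the signed fold change reports
#' down-regulation as a negative reciprocal (`FC >= 1` kept as is, otherwise
#' `-1/FC`), so the conventional `|FC| > 2` gate equals `|log2_fc| > 1`.
#'
#' @param expr Log2 expression matrix.
#' @param design Design data.frame.
#' @return A data.frame with columns `gene_id`, `log2_fc`, `signed_fc`.
#' @export
fold_change <- function(expr, design) {
  g <- split_groups(expr, design)
  log2_fc <- rowMeans(g$case) - rowMeans(g$control)
  fc <- 2^log2_fc
  data.frame(gene_id = rownames(expr), log2_fc = log2_fc,
             signed_fc = ifelse(fc >= 1, fc, -1 / fc),
             stringsAsFactors = FALSE, row.names = NULL)
}
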