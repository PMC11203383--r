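#' Configuration for the two-group microarray simulator
#'
#' Defines a synthetic log2 expression experiment: `n_genes` genes measured
#' on `k_case` case and `k_control` control arrays. Gene-wise variances are
#' drawn from a scaled inverse-chi-square prior
#' (sigma_g^2 ~ prior_var * prior_df / chisq(prior_df)), the hierarchical
#' model underlying empirical-Bayes variance moderation, so the prior is a
#' recoverable ground truth. A fraction `deg_fraction` of genes receive an
#' additive log2 shift of `effect_log2` in the case group with random sign.
#' Optionally, a fraction `outlier_rate` of matrix cells (sampled without
#' replacement) are contaminated with an added shift of
#' `outlier_sd_multiple * sigma_g` and random sign — the heavy-tailed
#' failure mode that Shapley-based calling is designed to tolerate.
#'
#' The default variance prior (`prior_df = 4`, `prior_var = 0.5`, i.e. a
#' typical per-gene log2 SD around 0.7) emulates small cohorts of human
#' tissue biopsies, where inter-individual biological variability dominates
#' and classical gene-wise tests are underpowered; technical-replicate
#' designs would correspond to a much smaller `prior_var`.
#'
#' @param n_genes Number of genes (rows).
#' @param k_case,k_control Samples per group; both must be >= 2.
#' @param deg_fraction Fraction of genes that are true DEGs, in `[0, 1)`.
#' @param effect_log2 Additive log2 shift for true DEGs (positive); the
#'   default 1.5 is a roughly three-fold linear change.
#' @param baseline_mean Location of the gene baselines (log2 scale).
#' @param prior_df,prior_var Parameters (d0, s0^2) of the variance prior.
#' @param outlier_rate Fraction of cells contaminated, in `[0, 1)`.
#' @param outlier_sd_multiple Outlier magnitude in units of the gene SD.
#' @param seed Integer seed; one generator stream drives the whole draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes, k_case, k_control,
                       deg_fraction = 0, effect_log2 = 1.5,
                       baseline_mean = 8, prior_df = 4, prior_var = 0.5,
                       outlier_rate = 0, outlier_sd_multiple = 4,
                       seed = 1L) {
  stopifnot(n_genes >= 1, k_case >= 1, k_control >= 1,
            deg_fraction >= 0, deg_fraction < 1,
            effect_log2 > 0, prior_df > 0, prior_var > 0,
            outlier_rate >= 0, outlier_rate < 1, outlier_sd_multiple > 0)
  structure(list(n_genes = as.integer(n_genes),
                 k_case = as.integer(k_case),
                 k_control = as.integer(k_control),
                 deg_fraction = deg_fraction,
                 effect_log2 = effect_log2,
                 baseline_mean = baseline_mean,
                 prior_df = prior_df, prior_var = prior_var,
                 outlier_rate = outlier_rate,
                 outlier_sd_multiple = outlier_sd_multiple,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-group expression experiment with known truth
#'
#' Values follow `mu_g + delta * sign_g * [case & DEG] + N(0, sigma_g^2)`,
#' with optional outlier cells receiving a further `+/- m * sigma_g` shift.
#' The generator consumes one seeded stream in a fixed order (gene
#' parameters, DEG assignment, noise, outliers), so results are bit-identical
#' for identical configurations.
#'
#' @param config A [sim_config()].
#' @return A list with components `expr` (log2 matrix, genes x samples),
#'   `design` (data.frame `sample_id`, `group`), and `truth` (list with
#'   per-gene data.frame `genes` — columns `gene_id`, `is_deg`, `direction`,
#'   `sigma_sq` — and data.frame `outliers` with cell coordinates).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$k_case < 2L || config$k_control < 2L) {
    stop("simulate_expression needs at least 2 samples per group")
  }
  n <- config$n_genes
  k1 <- config$k_case
  k2 <- config$k_control
  k <- k1 + k2
  set.seed(config$seed)

  gene_ids <- sprintf("gene_%0*d", nchar(n), seq_len(n))
  sample_ids <- c(sprintf("case_%02d", seq_len(k1)),
                  sprintf("ctrl_%02d", seq_len(k2)))
  group <- factor(rep(c("case", "control"), c(k1, k2)),
                  levels = c("case", "control"))

  # 1. gene-level parameters
  sigma_sq <- config$prior_var * config$prior_df / stats::rchisq(n, config$prior_df)
  mu <- stats::rnorm(n, config$baseline_mean, 1)

  # 2. DEG assignment
  n_deg <- round(config$deg_fraction * n)
  deg_idx <- if (n_deg > 0) sort(sample.int(n, n_deg)) else integer(0)
  is_deg <- seq_len(n) %in% deg_idx
  sign_g <- integer(n)
  if (n_deg > 0) sign_g[deg_idx] <- ifelse(stats::runif(n_deg) < 0.5, 1L, -1L)
  direction <- rep("none", n)
  direction[sign_g == 1L] <- "up"
  direction[sign_g == -1L] <- "down"

  # 3. signal + noise
  vals <- matrix(stats::rnorm(n * k, sd = rep(sqrt(sigma_sq), k)),
                 nrow = n, ncol = k,
                 dimnames = list(gene_ids, sample_ids))
  vals <- vals + mu
  if (n_deg > 0) {
    shift <- config$effect_log2 * sign_g
    vals[, group == "case"] <- vals[, group == "case"] +
      matrix(shift, n, k1)
  }

  # 4. outliers (cells without replacement)
  n_out <- round(config$outlier_rate * n * k)
  outliers <- data.frame(gene_id = character(0), sample_id = character(0),
                         sign = integer(0), stringsAsFactors = FALSE)
  if (n_out > 0) {
    cells <- sample.int(n * k, n_out)
    rows <- ((cells - 1L) %% n) + 1L
    cols <- ((cells - 1L) %/% n) + 1L
    osign <- ifelse(stats::runif(n_out) < 0.5, 1L, -1L)
    vals[cbind(rows, cols)] <- vals[cbind(rows, cols)] +
      osign * config$outlier_sd_multiple * sqrt(sigma_sq[rows])
    outliers <- data.frame(gene_id = gene_ids[rows],
                           sample_id = sample_ids[cols],
                           sign = osign, stringsAsFactors = FALSE)
  }

  list(expr = vals,
       design = data.frame(sample_id = sample_ids, group = group,
                           stringsAsFactors = FALSE),
       truth = list(genes = data.frame(gene_id = gene_ids,
                                       is_deg = is_deg,
                                       direction = direction,
                                       sigma_sq = sigma_sq,
                                       stringsAsFactors = FALSE),
                    outliers = outliers))
}

#' Simulate a random boolean matrix
#'
#' Independent Bernoulli(`density`) entries; used as fixtures for microarray
#' game computations.
#'
#' @param n Gene (row) count, >= 1.
#' @param k Array (column) count, >= 1.
#' @param density Bernoulli rate in `[0, 1]`.
#' @param seed Integer seed.
#' @return An integer 0/1 matrix with gene rownames and array colnames.
#' @export
simulate_boolean_matrix <- function(n, k, density, seed = 1L) {
  stopifnot(n >= 1, k >= 1, density >= 0, density <= 1)
  set.seed(seed)
  matrix(as.integer(stats::runif(n * k) < density), nrow = n, ncol = k,
         dimnames = list(sprintf("g%d", seq_len(n)),
                         sprintf("a%d", seq_len(k))))
}
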