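#' Principal-component scores of the samples
#'
#' Singular-value decomposition of the gene-centered expression matrix;
#' returns per-sample coordinates and the explained-variance fractions
#' (non-increasing, summing to at most 1). A constant matrix has zero
#' variance: all scores are 0 and the result is flagged via the
#' `"zero_variance"` attribute.
#'
#' @param expr Log2 expression matrix (genes x samples).
#' @param n_components Number of components, at most
#'   `min(n_genes, k_total - 1)`.
#' @return A list with `scores` (data.frame: `sample_id`, `PC1`, ...) and
#'   `explained_variance` (numeric fractions).
#' @export
pca_scores <- function(expr, n_components = 2L) {
  n <- nrow(expr); k <- ncol(expr)
  if (n_components > min(n, k - 1L)) {
    stop("n_components must be at most min(n_genes, k_total - 1) = ",
         min(n, k - 1L))
  }
  centered <- expr - rowMeans(expr)
  sv <- svd(centered, nu = 0, nv = n_components)
  d <- sv$d
  total <- sum(d^2)
  zero_var <- total == 0
  scores <- if (zero_var) {
    matrix(0, k, n_components)
  } else {
    sv$v * rep(d[seq_len(n_components)], each = k)
  }
  ev <- if (zero_var) rep(0, n_components) else (d^2 / total)[seq_len(n_components)]
  out <- data.frame(sample_id = colnames(expr), scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[-1L] <- paste0("PC", seq_len(n_components))
  structure(list(scores = out, explained_variance = ev),
            zero_variance = zero_var)
}

#' Volcano-plot table comparing classical and CASh p-values
#'
#' Joins a classical result table with CASh records on `gene_id`. Every
#' classical gene appears exactly once; for genes analyzed by CASh the
#' smaller of the two directional bootstrap p-values is used, and genes that
#' did not pass the CASh prescreen carry `NA` in the CASh columns.
#'
#' @param classical A [welch_t()] or [moderated_t()] result table.
#' @param cash_records The `records` table of a [run_cash()] result.
#' @return A data.frame with `gene_id`, `log2_fc`, `neg_log10_p_classical`,
#'   `neg_log10_p_cash`.
#' @export
volcano_table <- function(classical, cash_records) {
  p_cash <- if (nrow(cash_records)) {
    tapply(cash_records$p_boot, cash_records$gene_id, min)
  } else {
    numeric(0)
  }
  idx <- match(classical$gene_id, names(p_cash))
  data.frame(gene_id = classical$gene_id,
             log2_fc = classical$log2_fc,
             neg_log10_p_classical = -log10(classical$p_value),
             neg_log10_p_cash = -log10(as.numeric(p_cash)[idx]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse a flat key = value pipeline configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Recognized keys:
#' `expr`, `design`, `dialect`, `gmt`, `outdir`, `classical_fdr`,
#' `enrich_top`, `sim.*` (any [sim_config()] argument) and `cash.*` (any
#' [cash_config()] argument). Exactly one of `expr`/`design` paths or a
#' `sim.*` block must be present.
#'
#' @param path Path to the config file.
#' @return A config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  cfg <- list()
  num_or_char <- function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  }
  for (i in seq_along(keys)) {
    k <- keys[i]
    v <- num_or_char(vals[i])
    if (startsWith(k, "sim.")) {
      cfg$sim_args[[sub("^sim\\.", "", k)]] <- v
    } else if (startsWith(k, "cash.")) {
      key <- sub("^cash\\.", "", k)
      if (key == "apply_fdr") v <- as.logical(v) | v %in% c(1, "true", "yes")
      cfg$cash_args[[key]] <- v
    } else {
      cfg[[k]] <- v
    }
  }
  cfg
}

#' @keywords internal
pipeline_log <- function(state, msg) {
  line <- paste0("[", state$stage, "] ", msg)
  message(line)
  cat(line, "\n", file = state$log, append = TRUE, sep = "")
}

#' @keywords internal
pipeline_write <- function(state, df, name) {
  path <- file.path(state$outdir, name)
  write_table(df, path)
  cat(name, "\n", file = state$manifest, append = TRUE, sep = "")
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, classical differential expression (Welch and
#' moderated t), CASh, optional enrichment of the called DEGs, and the
#' exploratory report tables (PCA scores, volcano table). All tables are
#' written as TSV under `outdir` together with `summary.json`, a `run.log`,
#' and a `MANIFEST` listing completed outputs (so an aborted run is
#' recognizable by its incomplete manifest). Given a fixed seed the run is
#' deterministic: repeated runs produce byte-identical `summary.json`.
#'
#' @param config A config list (see [read_pipeline_config()]) or a path to a
#'   config file. Programmatic configs may carry `sim` (a [sim_config()]) or
#'   `sim_args` (arguments for one), alternatively `expr`/`design` paths;
#'   `cash` (a [cash_config()]) or `cash_args`; optional `gmt`,
#'   `classical_fdr` (default 0.05), `enrich_top` (default 10), `dialect`;
#'   and `outdir`.
#' @return A `RunSummary`-style list (also serialized as `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config[["outdir"]])) stop("config must name an output directory")
  outdir <- config[["outdir"]]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env()
  state$outdir <- outdir
  state$log <- file.path(outdir, "run.log")
  state$manifest <- file.path(outdir, "MANIFEST")
  cat("", file = state$log)
  cat("INCOMPLETE\n", file = state$manifest)
  state$stage <- "setup"

  run_stage <- function(stage, fn) {
    state$stage <- stage
    tryCatch(fn(), error = function(e) {
      pipeline_log(state, paste("FAILED:", conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  has_sim <- !is.null(config[["sim"]]) || !is.null(config[["sim_args"]])
  has_paths <- !is.null(config[["expr"]]) || !is.null(config[["design"]])
  if (has_sim == has_paths) {
    stop("config must provide exactly one of a simulation block or ",
         "expression/design paths")
  }

  truth <- NULL
  inputs <- run_stage("input", function() {
    if (has_sim) {
      sc <- config[["sim"]]
      if (is.null(sc)) sc <- do.call(sim_config, config[["sim_args"]])
      sim <- simulate_expression(sc)
      truth <<- sim$truth
      pipeline_log(state, sprintf("simulated %d genes x %d samples (seed %d)",
                                  nrow(sim$expr), ncol(sim$expr), sc$seed))
      pipeline_write(state, as.data.frame(cbind(gene_id = rownames(sim$expr),
                                                as.data.frame(sim$expr))),
                     "expression.tsv")
      pipeline_write(state, sim$design, "design.tsv")
      pipeline_write(state, sim$truth$genes, "truth_genes.tsv")
      list(expr = sim$expr, design = sim$design, sim = sc)
    } else {
      expr <- read_expression_matrix(config[["expr"]],
                                     dialect = config[["dialect"]] %||% "plain_tsv")
      design <- read_design(config[["design"]], expr)
      pipeline_log(state, sprintf("loaded %d genes x %d samples",
                                  nrow(expr), ncol(expr)))
      list(expr = expr, design = design, sim = NULL)
    }
  })
  expr <- inputs$expr
  design <- validate_design(inputs$design, expr)

  classical_fdr <- config[["classical_fdr"]] %||% 0.05
  cash_cfg <- config[["cash"]]
  if (is.null(cash_cfg)) {
    cash_cfg <- do.call(cash_config, config[["cash_args"]] %||% list())
  }

  classical <- run_stage("classical_de", function() {
    welch <- welch_t(expr, design)
    ebayes <- moderated_t(expr, design)
    pipeline_write(state, welch, "welch.tsv")
    pipeline_write(state, ebayes, "ebayes.tsv")
    pipeline_log(state, sprintf("welch: %d/%d genes at BH < %g",
                                sum(welch$p_adj < classical_fdr), nrow(welch),
                                classical_fdr))
    list(welch = welch, ebayes = ebayes)
  })

  cash_res <- run_stage("cash", function() {
    res <- run_cash(expr, design, cash_cfg)
    pipeline_write(state, res$records, "cash_records.tsv")
    pipeline_write(state, res$degs, "degs.tsv")
    pipeline_log(state, sprintf("prescreen kept %d/%d genes; %d DEGs called",
                                res$summary$n_prescreen, res$summary$n_genes,
                                res$summary$total))
    res
  })

  enrich <- NULL
  if (!is.null(config[["gmt"]])) {
    enrich <- run_stage("enrichment", function() {
      sets <- read_gmt(config[["gmt"]])
      res <- fisher_ora(cash_res$degs$gene_id, rownames(expr), sets)
      top <- top_terms(res, config[["enrich_top"]] %||% 10L)
      pipeline_write(state, res, "enrichment.tsv")
      pipeline_write(state, top, "enrichment_top.tsv")
      pipeline_log(state, sprintf("%d/%d sets significant at FDR < 0.05",
                                  sum(res$significant), nrow(res)))
      res
    })
  }

  run_stage("report", function() {
    ncomp <- min(2L, nrow(expr), ncol(expr) - 1L)
    pca <- pca_scores(expr, ncomp)
    pipeline_write(state, pca$scores, "pca_scores.tsv")
    pipeline_write(state,
                   data.frame(component = paste0("PC", seq_len(ncomp)),
                              explained_variance = pca$explained_variance),
                   "pca_variance.tsv")
    pipeline_write(state, volcano_table(classical$ebayes, cash_res$records),
                   "volcano.tsv")
  })

  method_counts <- function(de) {
    sig <- de$p_adj < classical_fdr & abs(de$signed_fc) > cash_cfg$fc_threshold
    list(total = sum(sig),
         up = sum(sig & de$signed_fc > 0),
         down = sum(sig & de$signed_fc < 0))
  }
  summary <- run_stage("summary", function() {
    s <- list(
      n_genes = nrow(expr),
      n_samples = ncol(expr),
      n_case = sum(design$group == "case"),
      n_control = sum(design$group == "control"),
      n_prescreen = cash_res$summary$n_prescreen,
      seed = cash_cfg$seed,
      sim_seed = if (!is.null(inputs$sim)) inputs$sim$seed else NULL,
      parameters = list(
        prescreen_alpha = cash_cfg$prescreen_alpha,
        prescreen_test = cash_cfg$prescreen_test,
        n_boot = cash_cfg$n_boot,
        p_threshold = cash_cfg$p_threshold,
        apply_fdr = cash_cfg$apply_fdr,
        fc_threshold = cash_cfg$fc_threshold,
        classical_fdr = classical_fdr),
      degs = list(
        welch = method_counts(classical$welch),
        ebayes = method_counts(classical$ebayes),
        cash = cash_res$summary[c("total", "up", "down")]),
      n_enriched = if (!is.null(enrich)) sum(enrich$significant) else NULL)
    if (!is.null(truth)) {
      truth_ids <- truth$genes$gene_id[truth$genes$is_deg]
      if (length(truth_ids)) {
        s$recall <- list(
          cash = mean(truth_ids %in% cash_res$degs$gene_id),
          welch = mean(truth_ids %in%
                         classical$welch$gene_id[classical$welch$p_adj < classical_fdr]))
      }
    }
    jsonlite::write_json(s, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    cat("summary.json\n", file = state$manifest, append = TRUE)
    s
  })

  # rewrite manifest without the INCOMPLETE marker
  done <- readLines(state$manifest)
  writeLines(done[done != "INCOMPLETE"], state$manifest)
  pipeline_log(state, "complete")
  invisible(summary)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
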