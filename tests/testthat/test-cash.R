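test_that("prescreen keeps the expected genes and preserves order", {
  sim <- simulate_expression(sim_config(1000, 5, 5, deg_fraction = 0,
                                        seed = 6))
  cfg <- cash_config(prescreen_alpha = 1, n_boot = 100, seed = 1)
  expect_identical(nrow(prescreen(sim$expr, sim$design, cfg)), 1000L)

  cfg2 <- cash_config(prescreen_alpha = 0.05, n_boot = 100, seed = 1)
  red <- prescreen(sim$expr, sim$design, cfg2)
  # null raw p-values are uniform: roughly 5% retained
  expect_gt(nrow(red), 20)
  expect_lt(nrow(red), 90)
  expect_identical(rownames(red),
                   intersect(rownames(sim$expr), rownames(red)))

  # a strong effect survives the restrictive cutoff
  sim3 <- simulate_expression(sim_config(50, 10, 10, deg_fraction = 0.02,
                                         effect_log2 = 3, seed = 9))
  strong <- sim3$truth$genes$gene_id[sim3$truth$genes$is_deg]
  cfg3 <- cash_config(prescreen_alpha = 0.01, n_boot = 100, seed = 1)
  expect_true(strong %in% rownames(prescreen(sim3$expr, sim3$design, cfg3)))
})

test_that("identical case and control profiles give a zero contrast", {
  vals <- matrix(rnorm(40), 10, 4)
  expr <- cbind(vals, vals)  # case columns duplicate control columns
  dimnames(expr) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:8))
  design <- data.frame(sample_id = sprintf("s%d", 1:8),
                       group = rep(c("case", "control"), each = 4))
  for (dir in c("over", "under")) {
    ct <- cash_contrast(expr, design, dir)
    expect_equal(ct$delta_phi, rep(0, 10))
  }
})

test_that("a fully case-specific gene earns the maximal contrast", {
  # g1 over-expressed in every case column; all other genes silent.
  # Control values (-1, 0, 0.5): mean -1/6, sd ~0.76, so no control value
  # reaches the over threshold and g2 never does anywhere.
  expr <- rbind(g1 = c(10, 10, 10, -1, 0, 0.5),
                g2 = c(0, 0, 0, -1, 0, 0.5))
  colnames(expr) <- sprintf("s%d", 1:6)
  design <- data.frame(sample_id = sprintf("s%d", 1:6),
                       group = rep(c("case", "control"), each = 3))
  ct <- cash_contrast(expr, design, "over")
  expect_equal(ct$phi_case[1], 1)   # sole member of all 3 case supports
  expect_equal(ct$phi_control[1], 0)
  expect_equal(ct$delta_phi[1], 1)
})

test_that("relabelling groups negates the contrast when thresholds agree", {
  # case values are a permutation of control values per gene, so the
  # per-gene mean/sd thresholds are identical under either labelling
  set.seed(2)
  ctrl <- matrix(rnorm(60), 10, 6)
  case <- t(apply(ctrl, 1, sample))
  expr <- cbind(case, ctrl)
  dimnames(expr) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:12))
  design <- data.frame(sample_id = sprintf("s%d", 1:12),
                       group = rep(c("case", "control"), each = 6))
  swapped <- design
  swapped$group <- ifelse(design$group == "case", "control", "case")
  a <- cash_contrast(expr, design, "over")
  b <- cash_contrast(expr, swapped, "over")
  expect_equal(a$delta_phi, -b$delta_phi, tolerance = 1e-12)
})

test_that("bootstrap p-values are deterministic, bounded and tie-consistent", {
  sim <- simulate_expression(sim_config(80, 4, 4, deg_fraction = 0.1,
                                        seed = 15))
  cfg <- cash_config(prescreen_alpha = 1, n_boot = 200, seed = 5)
  a <- bootstrap_p(sim$expr, sim$design, "over", cfg)
  b <- bootstrap_p(sim$expr, sim$design, "over", cfg)
  expect_identical(a$p_boot, b$p_boot)
  expect_true(all(a$p_boot >= 1 / 201 & a$p_boot <= 1))

  # genes with identical boolean rows share delta and p exactly
  B <- booleanize(sim$expr, sim$design, "over", "case")
  Ball <- cbind(B, booleanize(sim$expr, sim$design, "over", "control"))
  key <- apply(Ball, 1, paste, collapse = "")
  expect_true(all(tapply(a$p_boot, key,
                         function(x) length(unique(x))) == 1))

  # an all-zero boolean row sits at the null centre: p = 1
  # case values inside the control band, controls below their own threshold
  flat <- sim$expr
  flat["gene_01", ] <- c(rep(0.5, 4), 0, 1, 1, 1)
  p_flat <- bootstrap_p(flat, sim$design, "over", cfg)
  zero_row <- rowSums(cbind(
    booleanize(flat, sim$design, "over", "case"),
    booleanize(flat, sim$design, "over", "control"))) == 0
  expect_true(all(p_flat$p_boot[zero_row] == 1))

  expect_error(cash_config(n_boot = 50), "at least 100")
})

test_that("DEG calling applies the p and fold-change gates with tie rules", {
  cfg <- cash_config(p_threshold = 0.01, n_boot = 1000, fc_threshold = 2,
                     seed = 1)
  rec <- data.frame(
    gene_id = c("a", "b", "c", "c", "d", "d"),
    direction = c("over", "over", "over", "under", "over", "under"),
    phi_case = 0.5, phi_control = 0.1,
    delta_phi = c(0.4, 0.4, 0.5, 0.3, 0.2, 0.2),
    p_boot = c(0.003, 0.003, 0.004, 0.002, 0.005, 0.004),
    p_adj = c(0.01, 0.01, 0.02, 0.01, 0.02, 0.02),
    log2_fc = c(1.3, 0.58, 1.5, 1.5, 1.2, 1.4),
    signed_fc = c(2.5, 1.5, 2.8, 2.8, 2.3, 2.6),
    stringsAsFactors = FALSE)
  degs <- call_degs(rec, cfg)
  expect_true("a" %in% degs$gene_id)           # passes both gates -> up
  expect_false("b" %in% degs$gene_id)          # FC gate fails
  expect_identical(degs$call[degs$gene_id == "a"], "up")
  # c significant both ways: larger delta_phi wins (over)
  expect_identical(degs$direction[degs$gene_id == "c"], "over")
  # d tied on delta_phi: larger |log2_fc| wins (under)
  expect_identical(degs$direction[degs$gene_id == "d"], "under")
  expect_identical(sum(degs$gene_id == "c"), 1L)
})

test_that("run_cash produces a consistent accounting summary", {
  sim <- simulate_expression(sim_config(300, 5, 5, deg_fraction = 0.1,
                                        effect_log2 = 2, seed = 27))
  cfg <- cash_config(prescreen_alpha = 0.05, n_boot = 300, seed = 27)
  res <- run_cash(sim$expr, sim$design, cfg)
  expect_s3_class(res, "cash_result")
  expect_identical(res$summary$total, res$summary$up + res$summary$down)
  expect_identical(res$summary$total, nrow(res$degs))
  expect_identical(res$summary$n_genes, 300L)
  expect_true(all(res$degs$call %in% c("up", "down")))
  expect_true(all(res$degs$significant))
  # records carry both directions for every prescreened gene
  expect_identical(nrow(res$records), 2L * res$summary$n_prescreen)

  # doubling n_boot changes p granularity, not the observed statistic
  cfg2 <- cash_config(prescreen_alpha = 0.05, n_boot = 600, seed = 27)
  res2 <- run_cash(sim$expr, sim$design, cfg2)
  expect_identical(res$records$delta_phi, res2$records$delta_phi)
})

test_that("an empty prescreen yields a clean empty result", {
  sim <- simulate_expression(sim_config(50, 3, 3, deg_fraction = 0,
                                        seed = 33))
  cfg <- cash_config(prescreen_alpha = 1e-9, n_boot = 100, seed = 1)
  res <- run_cash(sim$expr, sim$design, cfg)
  expect_identical(res$summary$total, 0L)
  expect_identical(nrow(res$records), 0L)
  expect_identical(nrow(res$degs), 0L)
})
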