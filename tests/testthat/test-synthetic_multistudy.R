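small_cfg <- function(...) {
  sim_config(n_genes = 400L, n_per_group = 4L, f_de = 0.25,
             rho = c(REF = 1, A = 0.8, B = 0.2), seed = 5L, ...)
}

test_that("sim_config validates bounds and identifies the reference", {
  cfg <- small_cfg()
  expect_equal(cfg$reference, "REF")
  expect_error(sim_config(n_genes = 5))
  expect_error(sim_config(f_de = 0))
  expect_error(sim_config(rho = c(A = 1.2)))
  expect_error(sim_config(rho = c(A = 0.5, B = 0.3), reference = "A"),
               "rho = 1")
})

test_that("simulate_truth plants effects per the concordance model", {
  cfg <- small_cfg()
  tr <- simulate_truth(cfg)
  expect_equal(sum(tr$is_de), round(400 * 0.25))
  # non-DE genes carry zero effect everywhere
  expect_true(all(tr$beta_ref[!tr$is_de] == 0))
  expect_true(all(tr$beta_study[!tr$is_de, ] == 0))
  # rho = 1 reproduces the reference exactly
  expect_equal(tr$beta_study[, "REF"], setNames(tr$beta_ref, tr$genes))
  # determinism
  expect_identical(simulate_truth(cfg), tr)

  # rho = 0: correlation with the reference vanishes within sampling error
  cfg0 <- sim_config(n_genes = 4000L, f_de = 0.5,
                     rho = c(REF = 1, Z = 0), seed = 9L)
  tr0 <- simulate_truth(cfg0)
  r <- cor(tr0$beta_ref[tr0$is_de], tr0$beta_study[tr0$is_de, "Z"])
  expect_lt(abs(r), 3 / sqrt(sum(tr0$is_de)))
})

test_that("simulate_counts follows the NB mean model and is deterministic", {
  cfg <- sim_config(n_genes = 50L, n_per_group = 200L, f_de = 0.2,
                    rho = c(REF = 1, A = 0.5), phi = 1e-4,
                    baseline_log_mean = 5, baseline_log_sd = 0.5, seed = 17L)
  tr <- simulate_truth(cfg)
  sim <- simulate_counts(tr, cfg, "REF")
  ctrl <- sim$counts$counts[, sim$design$group == "control"]
  # with near-Poisson dispersion, per-gene control means track mu_baseline
  rel_err <- abs(rowMeans(ctrl) - tr$mu_baseline) /
    (tr$mu_baseline + 1)
  expect_lt(stats::median(rel_err), 0.05)
  # treated/control mean ratio near 1 for non-DE genes
  trt <- sim$counts$counts[, sim$design$group == "treated"]
  ratio <- rowMeans(trt)[!tr$is_de] / rowMeans(ctrl)[!tr$is_de]
  expect_lt(abs(mean(ratio) - 1), 0.05)

  expect_identical(simulate_counts(tr, cfg, "REF")$counts$counts,
                   sim$counts$counts)
  expect_error(simulate_counts(tr, cfg, "nope"), "unknown study")
})

test_that("mean absolute effect difference matches its closed form", {
  cfg <- sim_config(n_genes = 2000L, f_de = 0.5, sigma_beta = 1,
                    rho = c(REF = 1, S = 0.5), seed = 23L)
  tr <- simulate_truth(cfg)
  d <- abs(tr$beta_study[tr$is_de, "S"] - tr$beta_ref[tr$is_de])
  expected <- 2 * cfg$sigma_beta * sqrt((1 - 0.5) / pi)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("expected true-effect distance to the reference decreases in rho", {
  cfg <- sim_config(n_genes = 3000L, f_de = 0.5,
                    rho = c(REF = 1, R2 = 0.2, R5 = 0.5, R8 = 0.8, R10 = 1),
                    seed = 29L)
  tr <- simulate_truth(cfg)
  s <- vapply(c("R2", "R5", "R8", "R10"), function(lab)
    sum(abs(tr$beta_study[, lab] - tr$beta_ref)), numeric(1))
  expect_true(all(diff(s) < 0))
  expect_equal(unname(s[["R10"]]), 0)
})

test_that("simulate_panel bundles studies reproducibly and separates rho on true betas", {
  cfg <- small_cfg()
  panel <- simulate_panel(cfg)
  expect_named(panel$studies, c("REF", "A", "B"))
  tr <- panel$truth
  s_a <- sum(abs(tr$beta_study[, "A"] - tr$beta_ref))
  s_b <- sum(abs(tr$beta_study[, "B"] - tr$beta_ref))
  expect_lt(s_a, s_b)

  panel2 <- simulate_panel(cfg)
  expect_identical(panel2$studies$A$counts$counts,
                   panel$studies$A$counts$counts)

  expect_error(simulate_panel(sim_config(rho = c(A = 1, B = 0.5))),
               "at least two comparison")
  expect_error(simulate_panel(sim_config(rho = c(A = 0.9, B = 0.5, C = 0.1))),
               "reference")
})

test_that("adding a study never perturbs existing substreams", {
  cfg3 <- small_cfg()
  cfg4 <- sim_config(n_genes = 400L, n_per_group = 4L, f_de = 0.25,
                     rho = c(REF = 1, A = 0.8, B = 0.2, C = 0.5), seed = 5L)
  p3 <- simulate_panel(cfg3)
  p4 <- simulate_panel(cfg4)
  expect_identical(p3$studies$A$counts$counts, p4$studies$A$counts$counts)
  expect_identical(p3$studies$REF$counts$counts,
                   p4$studies$REF$counts$counts)
})

test_that("the full pipeline recovers the planted similarity ordering", {
  cfg <- sim_config(n_genes = 1500L, n_per_group = 6L, f_de = 0.1,
                    rho = c(REF = 1, A = 0.8, B = 0.2), seed = 37L)
  res <- run_panel_pipeline(simulate_panel(cfg))
  expect_equal(res$ranking$label[1], "A")
  expect_equal(res$dm$n_genes, 1500L)
})
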