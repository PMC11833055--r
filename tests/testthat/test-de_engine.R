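toy_cm <- function(counts, genes, samples) {
  dimnames(counts) <- list(genes, samples)
  count_matrix(counts)
}

test_that("cpm_normalize scales every sample to one million", {
  cm <- toy_cm(matrix(c(10, 20), 1, 2), "g1", c("s1", "s2"))
  expect_equal(unname(cpm_normalize(cm)), matrix(1e6, 1, 2))

  cm2 <- toy_cm(matrix(5, 2, 3), paste0("g", 1:2), paste0("s", 1:3))
  expect_true(all(cpm_normalize(cm2) == 5e5))

  set.seed(101)
  cm3 <- toy_cm(matrix(rpois(200, 50), 20, 10), paste0("g", 1:20),
                paste0("s", 1:10))
  expect_equal(unname(colSums(cpm_normalize(cm3))), rep(1e6, 10),
               tolerance = 1e-6)

  cm4 <- toy_cm(matrix(c(1, 0), 1, 2), "g1", c("ok", "empty"))
  expect_error(cpm_normalize(cm4), "zero total count.*empty")
})

test_that("estimate_log2fc matches its closed form and is antisymmetric", {
  # columns already sum to 1e6, so CPM equals the raw counts
  counts <- rbind(g1 = c(1000, 1000, 2000, 2000),
                  g2 = c(999000, 999000, 998000, 998000))
  cm <- toy_cm(counts, c("g1", "g2"), paste0("s", 1:4))
  des <- group_design(paste0("s", 1:4),
                      c("control", "control", "treated", "treated"))
  fc <- estimate_log2fc(cm, des)
  expect_equal(unname(fc["g1"]), log2(2000.5 / 1000.5), tolerance = 1e-12)
  expect_equal(unname(fc["g1"]), 0.99964, tolerance = 1e-4)

  # identical group means give zero
  des_same <- group_design(paste0("s", 1:4),
                           c("control", "treated", "control", "treated"))
  expect_equal(unname(estimate_log2fc(cm, des_same)), c(0, 0))

  # swapping labels negates every log2fc
  des_swap <- group_design(paste0("s", 1:4),
                           c("treated", "treated", "control", "control"))
  expect_equal(estimate_log2fc(cm, des_swap), -fc)
})

test_that("log2fc is invariant under common per-sample count scaling", {
  set.seed(111)
  counts <- matrix(rpois(120, 100), 12, 10,
                   dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  des <- group_design(paste0("s", 1:10),
                      rep(c("control", "treated"), each = 5))
  fc1 <- estimate_log2fc(count_matrix(counts), des)
  fc2 <- estimate_log2fc(count_matrix(counts * 7L), des)
  expect_equal(fc1, fc2, tolerance = 1e-12)
})

test_that("welch_de agrees with stats::t.test per gene", {
  set.seed(121)
  counts <- matrix(rnbinom(50 * 12, mu = 200, size = 5), 50, 12,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:12)))
  cm <- count_matrix(counts)
  des <- group_design(paste0("s", 1:12),
                      rep(c("control", "treated"), each = 6))
  p <- welch_de(cm, des)
  logc <- log2(cpm_normalize(cm) + 0.5)
  for (i in c(1, 7, 25, 50)) {
    ref <- stats::t.test(logc[i, 7:12], logc[i, 1:6])$p.value
    expect_equal(unname(p[i]), ref, tolerance = 1e-12)
  }
})

test_that("welch_de handles degenerate genes and rejects tiny groups", {
  counts <- rbind(flat = c(100, 100, 100, 100),
                  other = c(50, 60, 70, 80))
  cm <- toy_cm(counts, c("flat", "other"), paste0("s", 1:4))
  des <- group_design(paste0("s", 1:4),
                      rep(c("control", "treated"), each = 2))
  # CPM makes 'flat' non-constant here, so build a truly constant case
  const <- matrix(100, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  p <- welch_de(count_matrix(const), des)
  expect_equal(unname(p), c(1, 1))

  des3 <- group_design(paste0("s", 1:4),
                       c("control", "treated", "treated", "treated"))
  expect_error(welch_de(cm, des3), "at least two samples")
})

test_that("a planted strong shift is detected at small n", {
  set.seed(131)
  mu <- rep(500, 30)
  ctrl <- matrix(rnbinom(30 * 6, mu = mu, size = 50), 30, 6)
  trt <- matrix(rnbinom(30 * 6, mu = mu, size = 50), 30, 6)
  trt[1, ] <- rnbinom(6, mu = 8 * 500, size = 50)
  counts <- cbind(ctrl, trt)
  dimnames(counts) <- list(sprintf("g%02d", 1:30), paste0("s", 1:12))
  des <- group_design(paste0("s", 1:12),
                      rep(c("control", "treated"), each = 6))
  p <- welch_de(count_matrix(counts), des)
  expect_lt(p[["g01"]], 0.05)
})

test_that("build_profile composes the two engines, genes sorted", {
  set.seed(141)
  counts <- matrix(rpois(3 * 8, 100), 3, 8,
                   dimnames = list(c("b_gene", "a_gene", "c_gene"),
                                   paste0("s", 1:8)))
  cm <- count_matrix(counts)
  des <- group_design(paste0("s", 1:8),
                      rep(c("control", "treated"), each = 4))
  prof <- build_profile(cm, des, "SIM")
  expect_equal(prof$effects$gene_id, c("a_gene", "b_gene", "c_gene"))
  fc <- estimate_log2fc(cm, des)
  p <- welch_de(cm, des)
  expect_equal(prof$effects$log2fc,
               unname(fc[prof$effects$gene_id]))
  expect_equal(prof$effects$pvalue, unname(p[prof$effects$gene_id]))
})

test_that("count and sample-sheet TSVs round-trip into the engine", {
  set.seed(151)
  counts <- matrix(rpois(20, 30), 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  bundle <- list(counts = count_matrix(counts),
                 design = group_design(paste0("s", 1:4),
                                       rep(c("control", "treated"), 2)))
  write_study_tsv(bundle, f1, f2)
  back <- read_counts_tsv(f1, f2)
  expect_equal(back$counts$counts, counts)
  expect_equal(back$design$group, bundle$design$group)
})
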