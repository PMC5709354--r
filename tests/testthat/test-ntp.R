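test_that("cosine similarity matches hand values and rejects degenerate input", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(1, 1), "length")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("template matrix restricts to matrix genes and enforces coverage", {
  emat <- matrix(rnorm(12), 6, dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  tpl <- template_set(list(A = c("g1", "g2", "g3", "g4"), B = c("g5", "g6")))
  tm <- build_template_matrix(tpl, emat)
  expect_identical(tm$genes, paste0("g", 1:6))
  expect_equal(unname(rowSums(tm$indicators)), rep(1, 6))
  expect_equal(unname(colSums(tm$indicators)), c(4, 2))

  # 3/4 genes present at min_fraction 0.5: built with a message
  sub <- emat[c("g1", "g2", "g3", "g5", "g6"), ]
  expect_message(tm2 <- build_template_matrix(tpl, sub), "A: 3/4")
  expect_equal(unname(colSums(tm2$indicators)), c(3, 2))

  # 1/4 genes present: below coverage
  sub2 <- emat[c("g4", "g5", "g6"), ]
  expect_error(build_template_matrix(tpl, sub2), "A \\(1/4\\)")
})

test_that("a perfect template match gets similarity 1 and the minimum p", {
  set.seed(99)
  n_genes <- 100
  genes <- sprintf("g%03d", 1:n_genes)
  x <- rnorm(n_genes, 0, 0.5) + 2   # nonzero background
  names(x) <- genes
  x[c("g001", "g002")] <- 1
  x[c("g003", "g004")] <- 0
  emat <- matrix(x, ncol = 1, dimnames = list(genes, "s1"))
  tpl <- template_set(list(A = c("g001", "g002"), B = c("g003", "g004")))
  fit <- ntp(emat, tpl, n_resample = 1000, seed = 7, do_row_scale = FALSE)
  expect_equal(unname(fit$similarity[1, "A"]), 1)
  expect_identical(fit$best_class, "A")
  expect_equal(fit$predictions$p_value, 1 / 1001)
})

test_that("Monte-Carlo resampling p matches the exhaustive enumeration oracle", {
  # 6 genes, 2 classes x 2 template genes, 1 sample: all C(6,2)*C(4,2) = 90
  # null gene-set partitions are enumerable
  genes <- paste0("g", 1:6)
  x <- c(2.0, 1.5, -1.0, 0.5, -0.5, 1.0)
  names(x) <- genes
  emat <- matrix(x, ncol = 1, dimnames = list(genes, "s1"))
  tpl <- template_set(list(A = c("g1", "g2"), B = c("g3", "g4")))

  fit0 <- ntp(emat, tpl, n_resample = 10, seed = 1, do_row_scale = FALSE)
  obs_max <- max(fit0$similarity)
  oracle <- enumerate_null_p(x, c(A = 2L, B = 2L), obs_max)
  expect_identical(unname(oracle["total"]), 90)

  n_mc <- 10000
  fit <- ntp(emat, tpl, n_resample = n_mc, seed = 123, do_row_scale = FALSE)
  p_mc <- fit$predictions$p_value
  p_exact <- unname(oracle["p"])
  se <- sqrt(p_exact * (1 - p_exact) / n_mc)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / (n_mc + 1))
})

test_that("classification is deterministic under a fixed seed", {
  case <- small_labeled_case(seed = 5)
  fit1 <- suppressWarnings(ntp(case$sim$emat, case$tpl, n_resample = 100, seed = 11))
  fit2 <- suppressWarnings(ntp(case$sim$emat, case$tpl, n_resample = 100, seed = 11))
  expect_identical(fit1$predictions, fit2$predictions)
  expect_identical(fit1$similarity, fit2$similarity)
})

test_that("sample permutation permutes predictions; gene order is irrelevant", {
  case <- small_labeled_case(seed = 2)
  emat <- case$sim$emat
  fit <- suppressWarnings(ntp(emat, case$tpl, n_resample = 200, seed = 3))

  perm_s <- sample(ncol(emat))
  fit_s <- suppressWarnings(ntp(emat[, perm_s], case$tpl, n_resample = 200, seed = 3))
  expect_identical(fit_s$best_class, fit$best_class[perm_s])
  expect_equal(unname(fit_s$similarity), unname(fit$similarity[perm_s, ]))

  perm_g <- sample(nrow(emat))
  fit_g <- suppressWarnings(ntp(emat[perm_g, ], case$tpl, n_resample = 200, seed = 3))
  expect_identical(fit_g$best_class, fit$best_class)
  expect_equal(fit_g$similarity[, case$tpl$classes],
               fit$similarity[, case$tpl$classes], tolerance = 1e-12)
})

test_that("p-values stay within [1/(n+1), 1] and fdr >= p always", {
  case <- small_labeled_case(seed = 4, n = 20)
  fit <- suppressWarnings(ntp(case$sim$emat, case$tpl, n_resample = 50, seed = 1))
  p <- fit$predictions$p_value
  expect_true(all(p >= 1 / 51 - 1e-15))
  expect_true(all(p <= 1))
  expect_true(all(fit$predictions$fdr >= p - 1e-15))
})

test_that("lowering alpha never converts a not-assigned sample to assigned", {
  set.seed(12)
  emat <- matrix(rnorm(400 * 30), 400,
                 dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:30)))
  tpl <- template_set(list(A = sprintf("g%03d", 1:10), B = sprintf("g%03d", 11:20)))
  strict <- suppressWarnings(ntp(emat, tpl, n_resample = 200, alpha = 0.01, seed = 2))
  loose <- suppressWarnings(ntp(emat, tpl, n_resample = 200, alpha = 0.10, seed = 2))
  na_loose <- is.na(loose$predictions$prediction)
  na_strict <- is.na(strict$predictions$prediction)
  expect_true(all(na_strict[na_loose]))  # unassigned at 0.10 stays unassigned at 0.01
})

test_that("strong planted subtypes are recovered for nearly all assigned samples", {
  sim <- simulate_cohort(n_samples = 60, n_genes = 1000, k_classes = 4,
                         markers_per_class = 25, marker_lfc = 2, noise_sd = 1,
                         stromal_genes = 0, stromal_present = FALSE, seed = 21)
  tpl <- template_set(sim$truth$marker_map)
  fit <- ntp(sim$emat, tpl, n_resample = 500, seed = 21)
  acc <- overall_accuracy(fit, sim$truth$labels)
  expect_gte(acc$accuracy, 0.95)
})

test_that("exact similarity ties set the tie flag and pick the earliest class", {
  genes <- paste0("g", 1:8)
  x <- c(1, 1, 1, 1, rep(0.5, 4))
  emat <- matrix(c(x, x + rnorm(8, 0, 1e-9)), ncol = 2,
                 dimnames = list(genes, c("s1", "s2")))
  tpl <- template_set(list(B1 = c("g1", "g2"), B2 = c("g3", "g4")))
  fit <- suppressWarnings(ntp(emat, tpl, n_resample = 20, seed = 1,
                              do_row_scale = FALSE))
  expect_true(fit$predictions$tie_flag[1L])
  expect_identical(fit$best_class[1L], "B1")
})

test_that("benjamini_hochberg reproduces hand-computed step-up values", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  # order-insensitivity and the output >= input guarantee
  p <- c(0.04, 0.005, 0.03, 0.01)
  expect_equal(benjamini_hochberg(p), c(0.04, 0.02, 0.04, 0.02))
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_error(benjamini_hochberg(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(benjamini_hochberg(numeric(0)), "empty")
})
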