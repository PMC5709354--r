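test_that("with homogeneous variances the moderated t equals the pooled t", {
  # same residual pattern for every gene => identical gene-wise variances
  set.seed(8)
  n_a <- 5; n_b <- 5
  resid <- rnorm(n_a + n_b)
  resid <- resid - mean(resid[1:n_a]) * rep(c(1, 0), c(n_a, n_b)) -
    mean(resid[(n_a + 1):(n_a + n_b)]) * rep(c(0, 1), c(n_a, n_b))
  means <- seq(0, 3, length.out = 50)
  emat <- t(vapply(means, function(mu) {
    resid + rep(c(mu, 0), c(n_a, n_b))
  }, numeric(n_a + n_b)))
  dimnames(emat) <- list(sprintf("g%02d", 1:50),
                         c(paste0("a", 1:n_a), paste0("b", 1:n_b)))
  de <- moderated_t_test(emat, paste0("a", 1:n_a), paste0("b", 1:n_b))

  # independent oracle: ordinary pooled two-sample t computed from scratch
  t_ord <- apply(emat, 1, function(y) {
    ya <- y[1:n_a]; yb <- y[(n_a + 1):(n_a + n_b)]
    sp2 <- ((n_a - 1) * var(ya) + (n_b - 1) * var(yb)) / (n_a + n_b - 2)
    (mean(ya) - mean(yb)) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  })
  expect_lt(max(abs(de$t_stat - t_ord)), 1e-8)
  expect_equal(de$lfc, unname(means), tolerance = 1e-12)
})

test_that("a gene with identical values in both groups gets lfc 0, t 0, p 1", {
  set.seed(9)
  emat <- matrix(rnorm(40 * 8), 40,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 c(paste0("a", 1:4), paste0("b", 1:4))))
  emat["g01", ] <- rep(c(1, 2, 3, 4), 2)  # same values in both groups
  de <- moderated_t_test(emat, paste0("a", 1:4), paste0("b", 1:4))
  row <- de[de$gene == "g01", ]
  expect_equal(row$lfc, 0)
  expect_equal(row$t_stat, 0)
  expect_equal(row$p, 1)
})

test_that("moderated t validates groups", {
  emat <- matrix(rnorm(20), 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_error(moderated_t_test(emat, "s1", c("s2", "s3")), ">= 2")
  expect_error(moderated_t_test(emat, c("s1", "s2"), c("s2", "s3")), "disjoint")
  expect_error(moderated_t_test(emat, c("s1", "s2"), c("s3", "sX")), "sX")
})

test_that("planted fold changes are recovered to within 0.15", {
  set.seed(31)
  n_genes <- 2000; n_a <- 10; n_b <- 10
  planted <- sprintf("g%04d", 1:100)
  genes <- sprintf("g%04d", 1:n_genes)
  emat <- matrix(rnorm(n_genes * (n_a + n_b), 0, 0.5), n_genes,
                 dimnames = list(genes, c(paste0("a", 1:n_a), paste0("b", 1:n_b))))
  emat[planted, 1:n_a] <- emat[planted, 1:n_a] + 2
  de <- moderated_t_test(emat, paste0("a", 1:n_a), paste0("b", 1:n_b))
  expect_lt(abs(mean(de$lfc[de$gene %in% planted]) - 2), 0.15)
})

test_that("candidate markers recover planted one-vs-rest blocks", {
  sim <- simulate_cohort(n_samples = 60, n_genes = 1000, k_classes = 4,
                         markers_per_class = 20, marker_lfc = 3, noise_sd = 1,
                         stromal_genes = 0, stromal_present = FALSE, seed = 17)
  cand <- candidate_markers(sim$emat, sim$truth$labels)
  truth <- sim$truth$marker_map
  recall <- mean(unlist(mapply(function(cl, genes) genes %in% cand[[cl]],
                               names(truth), truth)))
  precision <- mean(unlist(mapply(function(cl, genes) genes %in% truth[[cl]],
                                  names(cand), cand)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.9)
})

test_that("pure noise yields (essentially) no candidates; infinite lfc_min none", {
  set.seed(23)
  emat <- matrix(rnorm(800 * 40), 800,
                 dimnames = list(sprintf("g%03d", 1:800), paste0("s", 1:40)))
  labels <- rep(c("A", "B"), each = 20)
  cand <- candidate_markers(emat, labels)
  expect_lte(sum(lengths(cand)), 0.1 * 800)  # BH bound; typically zero
  cand_inf <- candidate_markers(emat, labels, lfc_min = Inf)
  expect_identical(sum(lengths(cand_inf)), 0L)
  expect_error(candidate_markers(emat, c("A", rep("B", 39))), "A")
})

test_that("multi-class qualifiers go to the class with the larger fold change", {
  set.seed(41)
  n <- 30
  emat <- matrix(rnorm(200 * n, 5, 0.3), 200,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:n)))
  labels <- rep(c("A", "B", "C"), each = 10)
  # g001 is up in both A and B, more strongly in B
  emat["g001", labels == "A"] <- emat["g001", labels == "A"] + 2
  emat["g001", labels == "B"] <- emat["g001", labels == "B"] + 5
  cand <- candidate_markers(emat, labels)
  expect_false("g001" %in% cand$A)
  expect_true("g001" %in% cand$B)
})

test_that("IPR and within-sample expression criteria match hand computation", {
  emat <- matrix(5, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  emat["g1", ] <- c(0, 0, 10, 10)
  # only g1 has nonzero 10-90 IPR; top-25% cut of (10,0,0,0) is 2.5
  keep <- robust_intrinsic_filter(emat, min_samples = 2)
  expect_identical(keep, "g1")

  # within-sample criterion: top-quartile in >= min_samples samples
  set.seed(6)
  emat2 <- matrix(rnorm(8 * 4, 5, 1), 8,
                  dimnames = list(paste0("g", 1:8), paste0("s", 1:4)))
  emat2["g1", ] <- c(20, 20, 20, 0)   # top in 3 of 4 samples
  emat2["g2", ] <- c(0, 0, 30, 30)    # top in only 2 samples, huge IPR
  keep2 <- robust_intrinsic_filter(emat2, min_samples = 3)
  expect_true("g1" %in% keep2)
  expect_false("g2" %in% keep2)

  const <- matrix(1, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_warning(none <- robust_intrinsic_filter(const), "no genes")
  expect_length(none, 0)
  expect_error(robust_intrinsic_filter(emat[, 1:2]), ">= 3")
})

test_that("intrinsic filter drops stroma-inflated genes and keeps the rest", {
  # stromal_lfc 4.6 times the mean stromal fraction 0.65 plants a realized
  # tumor-minus-xenograft stromal fold change of about 3
  pair <- simulate_model_pair(n_samples = 40, n_genes = 1000, k_classes = 4,
                              markers_per_class = 20, marker_lfc = 2,
                              noise_sd = 1, stromal_genes = 50,
                              stromal_lfc = 4.6, seed = 13)
  keep <- intrinsic_filter(pair$tumor, pair$xenograft)
  stromal <- pair$truth$stromal_genes
  non_stromal <- setdiff(rownames(pair$tumor), stromal)
  expect_gte(mean(!stromal %in% keep), 48 / 50)          # >= 48/50 excluded
  expect_lte(mean(!non_stromal %in% keep), 0.05)         # <= 5% false exclusion
  expect_true(all(unlist(pair$truth$marker_map) %in% keep) ||
                mean(unlist(pair$truth$marker_map) %in% keep) >= 0.95)

  # lfc 0 gene retained; strongly stromal gene excluded (hand-planted)
  a <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("t", 1:6)))
  b <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("x", 1:6)))
  a <- a + matrix(rnorm(24, 0, 0.1), 4)
  b <- b + matrix(rnorm(24, 0, 0.1), 4)
  a["g1", ] <- a["g1", ] + 4
  keep2 <- intrinsic_filter(a, b)
  expect_false("g1" %in% keep2)
  expect_true("g2" %in% keep2)
  expect_error(intrinsic_filter(a, matrix(1, 2, 2,
    dimnames = list(c("z1", "z2"), c("x1", "x2")))), "intersection")
})

test_that("derive_template intersects the three filters and reports removals", {
  cand <- list(A = c("g1", "g2"), B = "g3")
  deriv <- derive_template(cand, robust = c("g1", "g3"),
                           intrinsic = c("g1", "g2", "g3"))
  expect_identical(deriv$template$members, list(A = "g1", B = "g3"))
  expect_identical(
    deriv$report$removal_reason[deriv$report$gene == "g2"], "not_robust")

  all_g <- c("g1", "g2", "g3")
  ident <- derive_template(cand, all_g, all_g)
  expect_identical(ident$template$members, lapply(cand, identity))

  expect_error(derive_template(cand, robust = "g3", intrinsic = all_g),
               "A")
})

test_that("relaxing thresholds never shrinks the template", {
  study <- simulate_study(n_samples = 60, n_celllines = 60, n_pair = 24,
                          n_test = 10, n_genes = 800, markers_per_class = 20,
                          stromal_genes = 50, seed = 29)
  strict <- suppressMessages(build_intrinsic_template(
    study$tumor$emat, study$tumor$truth$labels, study$celllines$emat,
    study$pair$tumor, study$pair$xenograft,
    lfc_min = 1.5, adjp_max = 0.05, ipr_top_fraction = 0.2,
    expr_top_fraction = 0.2, lfc_max = 1.5))
  loose <- suppressMessages(build_intrinsic_template(
    study$tumor$emat, study$tumor$truth$labels, study$celllines$emat,
    study$pair$tumor, study$pair$xenograft,
    lfc_min = 1, adjp_max = 0.1, ipr_top_fraction = 0.3,
    expr_top_fraction = 0.3, lfc_max = 2))
  for (cl in strict$template$classes) {
    expect_true(all(strict$template$members[[cl]] %in%
                      loose$template$members[[cl]]))
  }
})
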