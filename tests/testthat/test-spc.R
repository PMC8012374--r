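test_that("the embedded d2 table matches the expected normal range", {
  expect_identical(hartley_d2(2), 1.128)
  # independent oracle: numerical integration of E[range of n std normals]
  for (n in 2:10) {
    expect_equal(hartley_d2(n), expected_range_normal(n), tolerance = 5e-4)
  }
  expect_error(hartley_d2(1), class = "mranet_domain_error")
  expect_error(hartley_d2(11), class = "mranet_domain_error")
})

test_that("the worked range fixture gives mean range over d2", {
  est <- spc_intra_sd(rbind(c(1, 2), c(5, 7), c(10, 13)))
  expect_equal(est$ranges, c(1, 2, 3))
  expect_equal(est$s_intra, 6 / (3 * 1.128))
  # list input is equivalent
  est2 <- spc_intra_sd(list(c(1, 2), c(5, 7), c(10, 13)))
  expect_equal(est2$s_intra, est$s_intra)
  # constant subgroups have zero spread
  expect_identical(spc_intra_sd(rbind(c(4, 4), c(9, 9)))$s_intra, 0)
  expect_error(spc_intra_sd(list(c(1, 2), c(3, 4, 5))),
               class = "mranet_validation_error")
})

test_that("the range estimator is scale-equivariant and translation-invariant", {
  set.seed(13)
  for (rep in 1:10) {
    x <- matrix(rnorm(12, sd = runif(1, 0.1, 5)), nrow = 4)
    lambda <- runif(1, 0.1, 10)
    shift <- rnorm(1, sd = 100)
    base <- spc_intra_sd(x)$s_intra
    expect_equal(spc_intra_sd(lambda * x)$s_intra, lambda * base)
    expect_equal(spc_intra_sd(x + shift)$s_intra, base)
  }
})

test_that("the estimator is nearly unbiased on normal subgroups", {
  set.seed(17)
  x <- matrix(rnorm(2 * 10000, mean = 0, sd = 2), ncol = 2)
  est <- spc_intra_sd(x)
  expect_lt(abs(est$s_intra - 2) / 2, 0.02)
})

test_that("disabling exclusion reproduces the plain pooled estimator", {
  set.seed(19)
  m <- matrix(rnorm(400 * 2, mean = rnorm(400, sd = 3), sd = 0.7), ncol = 2)
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  fit <- spc_population_sd(m, rule = "none")
  expect_identical(fit$n_iterations, 1L)
  expect_identical(nrow(fit$excluded_genes), 0L)
  expect_equal(fit$sigma, spc_intra_sd(m)$s_intra)
  expect_equal(fit$sigma, 0.7, tolerance = 0.05)
})

test_that("an extreme-range gene is excluded and sigma recomputed without it", {
  set.seed(29)
  m <- matrix(rnorm(60 * 2, sd = 0.5), ncol = 2)
  rownames(m) <- sprintf("g%02d", 1:60)
  base_range <- mean(apply(m, 1, function(x) max(x) - min(x)))
  m["g01", ] <- c(0, 100 * base_range)   # wildly out of control
  fit <- spc_population_sd(m, rule = "range")
  expect_true("g01" %in% fit$excluded_genes$gene)
  expect_identical(fit$excluded_genes$iteration[
    fit$excluded_genes$gene == "g01"], 1L)
  clean <- spc_population_sd(m[rownames(m) != "g01", ], rule = "none")
  expect_lt(fit$sigma, spc_population_sd(m, rule = "none")$sigma)
  expect_equal(fit$sigma, clean$sigma, tolerance = 0.15)
  # bookkeeping: retained and excluded partition the input
  expect_setequal(c(fit$retained_genes, fit$excluded_genes$gene), rownames(m))
})

test_that("the individuals rule flags genes by mean deviation", {
  set.seed(37)
  m <- matrix(rnorm(40 * 3, sd = 0.4), ncol = 3)
  rownames(m) <- sprintf("g%02d", 1:40)
  m["g05", ] <- m["g05", ] + 50   # huge location shift, normal spread
  fit_rng <- spc_population_sd(m, rule = "range")
  fit_ind <- spc_population_sd(m, rule = "individuals")
  expect_false("g05" %in% fit_rng$excluded_genes$gene)
  expect_true("g05" %in% fit_ind$excluded_genes$gene)
})

test_that("exclusion loops terminate at a fixed point within the gene count", {
  set.seed(41)
  for (rep in 1:5) {
    m <- matrix(rnorm(50 * 2, sd = sample(c(0.2, 1, 5), 50, TRUE)), ncol = 2)
    rownames(m) <- sprintf("g%02d", 1:50)
    fit <- tryCatch(spc_population_sd(m), mranet_degenerate = function(e) NULL)
    if (is.null(fit)) next
    expect_lte(fit$n_iterations, 50)
    # fixed point: re-running on the retained genes excludes nothing
    refit <- spc_population_sd(m[fit$retained_genes, ], rule = "range")
    expect_identical(nrow(refit$excluded_genes), 0L)
    expect_equal(refit$sigma, fit$sigma)
  }
})

test_that("over-pruned populations raise a degeneracy error", {
  set.seed(43)
  m <- matrix(rnorm(12 * 2, sd = 0.1), ncol = 2)
  rownames(m) <- sprintf("g%02d", 1:12)
  m["g01", 2] <- 1e3
  expect_error(spc_population_sd(m, min_genes = 12),
               class = "mranet_degenerate")
  expect_error(spc_population_sd(m[1:5, ]), class = "mranet_validation_error")
  expect_error(spc_population_sd(m[, 1, drop = FALSE]),
               class = "mranet_validation_error")
})

test_that("per-column wrapper pools each perturbation independently", {
  set.seed(47)
  long <- tidyr::expand_grid(gene = sprintf("g%02d", 1:30),
                             perturbation = c("pA", "pB"),
                             replicate = 1:2)
  long$response <- rnorm(nrow(long),
                         sd = ifelse(long$perturbation == "pA", 0.2, 1))
  out <- spc_population_sd_by_column(long, rule = "none")
  expect_identical(nrow(out), 2L)
  expect_lt(out$sigma[out$perturbation == "pA"],
            out$sigma[out$perturbation == "pB"])
})
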