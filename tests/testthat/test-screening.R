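make_net <- function(offdiag, P = NULL, modules = c("A", "B", "C")) {
  # offdiag in row-major order: r12, r13, r21, r23, r31, r32
  r <- diag(-1, 3)
  r[1, 2] <- offdiag[1]; r[1, 3] <- offdiag[2]
  r[2, 1] <- offdiag[3]; r[2, 3] <- offdiag[4]
  r[3, 1] <- offdiag[5]; r[3, 2] <- offdiag[6]
  mra_network(r, P %||% c(-1, -1, -1), modules = modules)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("network distances match hand-computed values", {
  a <- make_net(c(1, 0, 0, -1, 0.5, 0.5))
  b <- make_net(c(0, 0, 0, -1, 0.5, 0.5))
  expect_equal(network_distance(a, b, "euclidean"), 1)
  expect_equal(network_distance(a, a, "euclidean"), 0)
  expect_equal(network_distance(a, a, "one_minus_correlation"), 0)
  # doubling all off-diagonals is invisible to the correlation metric
  d <- make_net(2 * c(1, 0, 0, -1, 0.5, 0.5))
  expect_equal(network_distance(a, d, "one_minus_correlation"), 0)
  expect_gt(network_distance(a, d, "euclidean"), 0)
})

test_that("distance metrics are symmetric and euclidean obeys the triangle inequality", {
  set.seed(61)
  nets <- replicate(6, make_net(runif(6, -1, 1)), simplify = FALSE)
  for (i in 1:5) {
    a <- nets[[i]]; b <- nets[[i + 1]]
    expect_equal(network_distance(a, b, "euclidean"),
                 network_distance(b, a, "euclidean"))
    expect_equal(network_distance(a, b, "one_minus_correlation"),
                 network_distance(b, a, "one_minus_correlation"))
  }
  for (i in 1:4) {
    dab <- network_distance(nets[[i]], nets[[i + 1]], "euclidean")
    dbc <- network_distance(nets[[i + 1]], nets[[i + 2]], "euclidean")
    dac <- network_distance(nets[[i]], nets[[i + 2]], "euclidean")
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("degenerate correlation and mismatched orders raise errors", {
  a <- make_net(rep(0.3, 6))   # constant off-diagonals: zero variance
  b <- make_net(runif(6))
  expect_error(network_distance(a, b, "one_minus_correlation"),
               class = "mranet_degenerate")
  c2 <- make_net(runif(6), modules = c("X", "Y", "Z"))
  expect_error(network_distance(b, c2), class = "mranet_validation_error")
})

screen_fixture <- function() {
  tr <- truth_corepressor3()
  reference <- infer_network(tr$R)
  shared <- tr$R[c("coR1", "coR2"), , drop = FALSE]
  list(truth = tr, reference = reference, shared = shared,
       ref_row = tr$R["TF", ])
}

test_that("the reference reporter itself screens first with zero distance", {
  fx <- screen_fixture()
  direction <- c(0.21, -0.34, 0.11)   # fixed detuning direction
  eps <- c(0, 0.05, 0.25, 0.9)
  resp <- t(vapply(eps, function(e) fx$ref_row + e * direction, numeric(3)))
  colnames(resp) <- fx$reference$modules
  panel <- dplyr::bind_cols(
    tibble::tibble(gene = c("self", "near", "mid", "far")),
    tibble::as_tibble(resp))
  res <- rank_candidates(fx$reference, panel, fx$shared, replace = "TF")
  self <- res[res$gene == "self", ]
  expect_equal(self$euclidean, 0)
  expect_equal(self$one_minus_correlation, 0, tolerance = 1e-12)
  expect_identical(self$rank_euclid, 1L)
  expect_identical(self$rank_corr, 1L)
  # distances grow with the detuning magnitude
  expect_identical(res$rank_euclid, 1:4)
})

test_that("zero-response candidates are flagged un-screenable, not fatal", {
  fx <- screen_fixture()
  panel <- tibble::tibble(
    gene = c("dead", "self"),
    TF = c(0, fx$ref_row[["TF"]]),
    coR1 = c(0, fx$ref_row[["coR1"]]),
    coR2 = c(0, fx$ref_row[["coR2"]]))
  res <- rank_candidates(fx$reference, panel, fx$shared, replace = "TF")
  expect_false(res$screenable[res$gene == "dead"])
  expect_true(is.na(res$euclidean[res$gene == "dead"]))
  expect_identical(res$rank_euclid[res$gene == "self"], 1L)
  # an all-dead panel is an error
  dead <- panel[1, ]
  expect_error(rank_candidates(fx$reference, dead, fx$shared, replace = "TF"),
               class = "mranet_degenerate")
})

test_that("tied candidates rank by panel order and ranking ignores input order otherwise", {
  fx <- screen_fixture()
  panel <- tibble::tibble(
    gene = c("twinB", "twinA"),
    TF = rep(fx$ref_row[["TF"]] + 0.1, 2),
    coR1 = rep(fx$ref_row[["coR1"]], 2),
    coR2 = rep(fx$ref_row[["coR2"]], 2))
  res <- rank_candidates(fx$reference, panel, fx$shared, replace = "TF")
  expect_identical(res$euclidean[1], res$euclidean[2])
  expect_identical(res$rank_euclid, c(1L, 2L))   # first-come tie break
})

test_that("candidate networks degrade continuously with detuning size", {
  fx <- screen_fixture()
  direction <- c(-0.12, 0.3, 0.07)
  d_small <- network_distance(
    infer_candidate_network(fx$ref_row + 0.02 * direction, fx$shared,
                            "TF", fx$reference$modules),
    fx$reference)
  d_large <- network_distance(
    infer_candidate_network(fx$ref_row + 0.4 * direction, fx$shared,
                            "TF", fx$reference$modules),
    fx$reference)
  expect_lt(d_small, 0.2)
  expect_lt(d_small, d_large)
})
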