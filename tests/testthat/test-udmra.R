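test_that("incoming coefficients solve the row system exactly", {
  set.seed(51)
  tr <- truth_corepressor3()
  R <- tr$R
  # a gene tracking module 2 exactly gets the unit row
  coef <- fit_udmra_row(R, R[2, ])
  expect_equal(unname(coef), c(0, 1, 0), tolerance = 1e-12)
  # a flat gene gets the zero row
  expect_equal(unname(fit_udmra_row(R, c(0, 0, 0))), c(0, 0, 0))
  # forward-composed rows are recovered to near machine precision
  for (rep in 1:10) {
    w <- runif(3, -0.8, 0.8)
    resp <- drop(w %*% R)
    expect_lt(max(abs(fit_udmra_row(R, resp) - w)), 1e-10)
  }
  expect_error(fit_udmra_row(R, c(0, 0, 2.5)), class = "mranet_domain_error")
})

test_that("the panel fitter agrees with the single-row solver", {
  set.seed(53)
  tr <- truth_crosstalk4()
  coefs <- matrix(runif(12, -0.6, 0.6), 3, 4)
  panel <- tibble::tibble(gene = c("g1", "g2", "g3"))
  resp <- coefs %*% tr$R
  colnames(resp) <- tr$modules
  panel <- dplyr::bind_cols(panel, tibble::as_tibble(resp))
  fit <- fit_udmra(tr$R, panel)
  for (i in 1:3) {
    expect_equal(unlist(fit[i, tr$modules]),
                 fit_udmra_row(tr$R, resp[i, ]), tolerance = 1e-12)
    expect_lt(max(abs(unlist(fit[i, tr$modules]) - coefs[i, ])), 1e-10)
  }
})

test_that("gene predictions are consistent with training responses", {
  tr <- truth_corepressor3()
  net <- infer_network(tr$R)
  set.seed(59)
  w_row <- runif(3, -0.5, 0.5)
  resp <- drop(w_row %*% tr$R)
  coef <- fit_udmra_row(tr$R, resp)
  # elementary perturbation k reproduces the observed response to q_k
  for (k in 1:3) {
    e <- numeric(3); e[k] <- 1
    expect_equal(predict_gene(coef, net, e, 10)$relative_change, resp[[k]],
                 tolerance = 1e-10)
  }
  # zero-coefficient genes stay at basal under any perturbation
  flat <- predict_gene(c(TF = 0, coR1 = 0, coR2 = 0), net, c(1, 1, 0), 7.5)
  expect_equal(flat$abundance, 7.5)
  # double perturbation matches the generator's ground truth
  u_true <- sum(w_row * (tr$R[, 2] + tr$R[, 3]))
  x_true <- 10 * (2 + u_true) / (2 - u_true)
  got <- predict_gene(coef, net, c(0, 1, 1), 10)
  expect_equal(got$relative_change, u_true, tolerance = 1e-10)
  expect_lt(abs(got$abundance - x_true) / x_true, 1e-9)
})

test_that("weight optimization recovers generating weights from clean data", {
  tr <- truth_corepressor3()
  net <- infer_network(tr$R)
  observed <- predict_response(net, c(0, 1, 0.4))
  fit <- optimize_weights(net, observed, free = c("coR1", "coR2"))
  expect_equal(unname(fit$weights), c(0, 1, 0.4), tolerance = 1e-6)
  expect_lt(fit$objective_value, 1e-10)
  # all-ones observation has its optimum at all-ones
  obs1 <- predict_response(net, c(0, 1, 1))
  fit1 <- optimize_weights(net, obs1, free = c("coR1", "coR2"))
  expect_equal(unname(fit1$weights[c("coR1", "coR2")]), c(1, 1),
               tolerance = 1e-6)
  # the returned optimum is the minimum of the evaluated trace
  expect_equal(fit$objective_value, min(fit$trace$objective))
})

test_that("weight optimization rejects all-zero observations in relative mode", {
  net <- infer_network(truth_corepressor3()$R)
  expect_error(optimize_weights(net, c(0, 0, 0), free = "coR1"),
               class = "mranet_degenerate")
  # absolute mode handles the same input
  fit <- optimize_weights(net, c(0, 0, 0), free = "coR1",
                          objective = "absolute")
  # the all-zero weight vector itself is not an admissible perturbation, so
  # the optimum approaches 0 from above within the refinement tolerance
  expect_lt(abs(unname(fit$weights["coR1"])), 1e-3)
})

test_that("the optimization objective is scale-invariant in relative mode", {
  tr <- truth_corepressor3()
  net <- infer_network(tr$R)
  observed <- predict_response(net, c(0, 1, 0.7)) * 1.0
  f1 <- optimize_weights(net, observed, free = "coR2",
                         fixed_weights = c(coR1 = 1))
  # scaling predictions and observations jointly leaves relative errors
  # unchanged; here we simply check the recovered weight is stable
  expect_equal(unname(f1$weights["coR2"]), 0.7, tolerance = 1e-6)
})

test_that("naive predictors are elementary summaries of the observations", {
  out <- naive_predictors(c(4, 9))
  expect_equal(out$prediction[out$method == "mean"], 6.5)
  expect_equal(out$prediction[out$method == "gmean"], 6)
  expect_equal(out$prediction[out$method == "max"], 9)
  same <- naive_predictors(c(5, 5))
  expect_equal(same$prediction, rep(5, 3))
  single <- naive_predictors(7)
  expect_equal(single$prediction, rep(7, 3))
  expect_error(naive_predictors(numeric(0)), class = "mranet_validation_error")
  expect_error(naive_predictors(c(1, -1)), class = "mranet_domain_error")
  # fold-change space agrees for these on a shared basal up to scaling
  fc <- naive_predictors(c(4, 9), basal = 2, space = "response")
  expect_equal(fc$prediction[fc$method == "gmean"], 6)
})

test_that("an exact method dominates the benchmark and ties give p = 1", {
  obs <- tibble::tibble(gene = sprintf("g%d", 1:10),
                        observed = seq(2, 20, by = 2))
  pred <- dplyr::bind_rows(
    tibble::tibble(gene = obs$gene, method = "exact", predicted = obs$observed),
    tibble::tibble(gene = obs$gene, method = "off",
                   predicted = obs$observed * 1.3),
    tibble::tibble(gene = obs$gene, method = "off2",
                   predicted = obs$observed * 1.3))
  bench <- benchmark_predictions(pred, obs)
  expect_equal(
    bench$summary$median_rel_error[bench$summary$method == "exact"], 0)
  p_exact <- bench$tests$p_value[bench$tests$method_a == "exact" &
                                   bench$tests$method_b == "off"]
  expect_lt(p_exact, 0.01)
  p_tie <- bench$tests$p_value[bench$tests$method_a == "off" &
                                 bench$tests$method_b == "off2"]
  expect_identical(p_tie, 1)
  # zero observed abundances are skipped with a warning
  obs0 <- obs; obs0$observed[1] <- 0
  expect_warning(b2 <- benchmark_predictions(pred, obs0), "zero observed")
  expect_false("g1" %in% b2$errors$gene)
})
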