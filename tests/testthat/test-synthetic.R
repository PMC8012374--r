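test_that("inadmissible ground truths are rejected at construction", {
  # diagonal must be exactly -1
  r_bad <- diag(-1, 3); r_bad[1, 1] <- -0.99
  expect_error(mra_truth(r_bad, c(-1, -1, -1), c(10, 10, 10)),
               class = "mranet_validation_error")
  # implied responses must stay inside (-2, 2)
  r <- diag(-1, 2)
  expect_error(mra_truth(r, P = c(-3, -0.5), basal = c(10, 10)),
               class = "mranet_domain_error")
  expect_error(mra_truth(diag(-1, 2), c(-1, -1), c(10, -1)),
               class = "mranet_domain_error")
})

test_that("random truths respect their admissibility bounds", {
  set.seed(73)
  for (rep in 1:20) {
    tr <- random_mra_truth(sample(2:5, 1))
    expect_true(all(abs(tr$R) < 2))
    expect_lt(kappa(tr$R, exact = TRUE), 1e3)
    expect_identical(unname(diag(tr$r)), rep(-1, length(tr$modules)))
  }
})

test_that("the generator and the inference core are exact inverses without noise", {
  tr <- noiseless_truth3()
  d <- truth_design(tr)
  data <- simulate_dataset(tr, d)
  # basal rows carry the basal abundances exactly
  basal_rows <- data[data$condition == "basal" & data$bio_rep == 1 &
                       data$tech_rep == 1, ]
  expect_equal(setNames(basal_rows$value, basal_rows$reporter)[tr$modules],
               tr$basal)
  R <- global_response(data, d)
  expect_lt(max(abs(R - tr$R)), 1e-12)
  net <- infer_network(R)
  rec <- recovery_report(tr, net)
  expect_lt(max(rec$errors$max_abs_error), 1e-9)
})

test_that("equal seeds give byte-identical datasets, unequal seeds do not", {
  tr <- truth_corepressor3()
  a <- simulate_dataset(tr, seed = 123)
  b <- simulate_dataset(tr, seed = 123)
  c <- simulate_dataset(tr, seed = 124)
  expect_identical(a, b)
  expect_false(identical(a$value, c$value))
})

test_that("technical noise drives the SPC estimate monotonically", {
  d <- truth_design(truth_corepressor3())
  est <- vapply(c(0.02, 0.06, 0.18), function(s) {
    tr <- truth_corepressor3(sigma_bio = 0, sigma_tech = s,
                             noise_space = "response")
    pr <- global_response(simulate_dataset(tr, d, seed = 500 + round(100 * s)),
                          d, mode = "per_replicate")
    mean(replicate_sd_matrix(pr, d))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("response-space noise yields normally distributed response replicates", {
  tr <- truth_corepressor3(sigma_bio = 0, sigma_tech = 0.05,
                           noise_space = "response")
  d <- truth_design(tr)
  set.seed(79)
  vals <- unlist(lapply(1:170, function(i) {
    pr <- global_response(simulate_dataset(tr, d), d, mode = "per_replicate")
    vapply(pr, function(m) m[1, 1], numeric(1))
  }))
  expect_gt(stats::shapiro.test(sample(vals, 1000))$p.value, 0.01)
  expect_equal(sd(vals), 0.05, tolerance = 0.1)
})

test_that("log-abundance noise perturbs every condition including basal", {
  tr <- truth_corepressor3(sigma_bio = 0.1, sigma_tech = 0.05)
  data <- simulate_dataset(tr, seed = 81)
  basal_vals <- data$value[data$condition == "basal" & data$reporter == "TF"]
  expect_gt(sd(basal_vals), 0)
})

test_that("gene panels follow the linear generative model", {
  tr <- truth_corepressor3()
  # a gene tracking module 2 reproduces module 2's responses
  rows <- tibble::tibble(gene = c("track2", "flat"),
                         basal_abundance = c(10, 4),
                         TF = c(0, 0), coR1 = c(1, 0), coR2 = c(0, 0))
  panel <- simulate_gene_panel(tr, gene_rows = rows)
  expect_equal(unlist(panel[panel$gene == "track2", tr$modules]),
               setNames(tr$R["coR1", ], tr$modules))
  expect_true(all(panel[panel$gene == "flat", tr$modules] == 0))
  expect_true(all(fit_udmra_row(tr$R, as.double(
    panel[panel$gene == "flat", tr$modules])) == 0))
  # random noiseless rows are recovered by the row solver
  rnd <- simulate_gene_panel(tr, n_genes = 15, seed = 83)
  fit <- fit_udmra(tr$R, rnd)
  err <- abs(as.matrix(fit[, tr$modules]) -
               as.matrix(rnd[, paste0("coef_", tr$modules)]))
  expect_lt(max(err), 1e-10)
})

test_that("gene rows implying saturated responses are rejected by name", {
  tr <- truth_corepressor3()
  rows <- tibble::tibble(gene = "wild", basal_abundance = 5,
                         TF = 40, coR1 = 0, coR2 = 0)
  err <- tryCatch(simulate_gene_panel(tr, gene_rows = rows), error = identity)
  expect_s3_class(err, "mranet_domain_error")
  expect_match(conditionMessage(err), "wild")
})

test_that("recovery reports flag perfect inference and CI coverage", {
  tr <- truth_corepressor3()
  net <- mra_network(tr$r, tr$P, modules = tr$modules)
  ci <- bootstrap_network(tr$R, matrix(0.02, 3, 3), n_samples = 500, seed = 6)
  rec <- recovery_report(tr, net, ci = ci)
  expect_true(all(rec$errors$max_abs_error == 0))
  expect_true(all(rec$coverage$covered))
})
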