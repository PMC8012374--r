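# Shared fixtures and independent oracles for the test-suite.

# Zero-noise variant of the 3-module fixture truth.
noiseless_truth3 <- function() {
  truth_corepressor3(sigma_bio = 0, sigma_tech = 0)
}

# Simulate a dataset and derive the inputs of the CI pipeline.
derive_inputs <- function(truth, design = truth_design(truth), seed = NULL) {
  dat <- simulate_dataset(truth, design, seed = seed)
  pr <- global_response(dat, design, mode = "per_replicate")
  list(
    data = dat, design = design, per_rep = pr,
    mean_R = Reduce(`+`, pr) / length(pr),
    sd_mean = replicate_sd_matrix(pr, design, scale = "mean")
  )
}

# Independent 2x2 inverse by the adjugate formula (oracle for infer_network).
inverse_2x2 <- function(m) {
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  matrix(c(m[2, 2], -m[2, 1], -m[1, 2], m[1, 1]), 2, 2) / det
}

# Expected range of n i.i.d. standard normals by numerical integration
# (independent oracle for the embedded d2 table):
# E[range] = integral of 1 - F(x)^n - (1 - F(x))^n over the real line.
expected_range_normal <- function(n) {
  integrate(function(x) 1 - pnorm(x)^n - (1 - pnorm(x))^n,
            lower = -12, upper = 12, rel.tol = 1e-10)$value
}

# Off-diagonal entries in row-major order (mirrors the screening metric).
offdiag_rowmajor <- function(r) {
  t(r)[row(r) != col(r)]
}
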