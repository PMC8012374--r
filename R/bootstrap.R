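#' Per-cell standard deviations of replicate global response matrices
#'
#' Applies the SPC range estimator [spc_intra_sd()] cell-wise to a list of
#' per-replicate global response matrices, grouping the `k_bio * n_tech`
#' values of each cell into `k_bio` subgroups of `n_tech` technical
#' replicates. Different cells typically display very different variances,
#' which is why the bootstrap uses an element-specific normal distribution
#' per cell.
#'
#' With `scale = "replicate"` (the raw SPC estimate) the returned values are
#' the intra-replicate standard deviations `s_intra`. With `scale = "mean"`
#' they are divided by `sqrt(k_bio * n_tech)`, giving the standard deviation
#' of the pooled mean matrix — the scale at which [bootstrap_network()]
#' brackets the point estimate with calibrated coverage, since the point
#' estimate is inferred from the mean of the replicate matrices.
#'
#' @param per_replicate_Rs List of matrices from
#'   `global_response(..., mode = "per_replicate")`, named `bio<i>.tech<r>`.
#' @param design The [mra_design()] describing the replicate structure.
#' @param scale `"replicate"` for the raw intra-replicate sd, `"mean"` for
#'   the sd of the replicate-averaged matrix.
#' @return A numeric matrix of standard deviations with module dimnames.
#' @export
replicate_sd_matrix <- function(per_replicate_Rs, design,
                                scale = c("replicate", "mean")) {
  scale <- match.arg(scale)
  k_t <- design$k_bio
  n_r <- design$n_tech
  if (length(per_replicate_Rs) != k_t * n_r) {
    mra_abort(
      paste0("expected ", k_t * n_r, " replicate matrices (",
             k_t, " biological x ", n_r, " technical), got ",
             length(per_replicate_Rs)),
      "mranet_validation_error")
  }
  want <- paste0("bio", rep(seq_len(k_t), each = n_r),
                 ".tech", rep(seq_len(n_r), k_t))
  if (!is.null(names(per_replicate_Rs)) &&
      !setequal(names(per_replicate_Rs), want)) {
    mra_abort("replicate matrices do not match the design's replicate labels",
              "mranet_validation_error")
  }
  if (!is.null(names(per_replicate_Rs))) {
    per_replicate_Rs <- per_replicate_Rs[want]
  }
  tmpl <- per_replicate_Rs[[1]]
  sd_R <- tmpl * 0
  arr <- simplify2array(per_replicate_Rs)  # n x n x (k_t * n_r)
  for (j in seq_len(nrow(tmpl))) {
    for (k in seq_len(ncol(tmpl))) {
      subgroups <- matrix(arr[j, k, ], nrow = k_t, ncol = n_r, byrow = TRUE)
      sd_R[j, k] <- spc_intra_sd(subgroups)$s_intra
    }
  }
  if (scale == "mean") sd_R <- sd_R / sqrt(k_t * n_r)
  sd_R
}

# Core parametric bootstrap: draw B matrices with independent
# Normal(mean_R[j,k], sd_R[j,k]) entries, infer (r, P) for each invertible
# draw, and return the raw draws of the parameters. Invalid draws (singular
# matrix, non-finite result, zero diagonal of R^-1) are NA columns.
bootstrap_draws <- function(mean_R, sd_R, n_samples) {
  n <- nrow(mean_R)
  n_par <- n * n            # n*(n-1) off-diagonal r's + n P's
  draws <- array(rnorm(n * n * n_samples, mean = mean_R, sd = sd_R),
                 dim = c(n, n, n_samples))
  off <- which(row(mean_R) != col(mean_R))
  res <- matrix(NA_real_, n_par, n_samples)
  for (b in seq_len(n_samples)) {
    m <- draws[, , b]
    inv <- tryCatch(solve.default(m), error = function(e) NULL)
    if (is.null(inv)) next
    d <- diag(inv)
    if (any(d == 0) || any(!is.finite(inv))) next
    r <- -inv / d
    res[, b] <- c(r[off], 1 / d)
  }
  list(draws = res, off = off)
}

ci_quantiles <- function(x, level) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
}

#' Parametric bootstrap confidence intervals for network parameters
#'
#' Draws `n_samples` global response matrices with independent normal entries
#' (`mean_R[j,k]`, `sd_R[j,k]`), infers the connection coefficients and
#' perturbation magnitudes for every invertible draw, and reports empirical
#' percentile confidence intervals (for the default level 0.95, the 2.5th
#' and 97.5th percentiles). Point estimates come from `mean_R` itself, not
#' from the draws. A parameter is flagged significant when its interval
#' excludes 0, i.e. its sign is known at the corresponding significance
#' level.
#'
#' Draws whose response matrix is singular (or yields non-finite parameters)
#' are discarded and counted; if the fraction of valid draws falls below
#' `min_valid_fraction` the network is too noisy for percentile intervals
#' and an instability error reports the fraction.
#'
#' @param mean_R Point-estimate global response matrix (the element-wise mean
#'   of the per-replicate matrices).
#' @param sd_R Matrix of per-cell standard deviations, e.g. from
#'   [replicate_sd_matrix()] or a pooled population estimate.
#' @param n_samples Number of bootstrap draws (default one million; scaled-
#'   down seeded runs of 10,000 are used for routine checks).
#' @param level Confidence level in (0, 1).
#' @param seed Optional integer; when given, results are bit-reproducible.
#' @param min_valid_fraction Minimum tolerated fraction of invertible draws.
#' @return An object of class `mra_ci`; `tidy()` returns the table with
#'   columns `parameter`, `type` (`"connection"` or `"magnitude"`), `from`,
#'   `to`, `estimate`, `lower`, `upper`, `significant`, `n_valid`.
#' @export
bootstrap_network <- function(mean_R, sd_R, n_samples = 1e6, level = 0.95,
                              seed = NULL, min_valid_fraction = 0.5) {
  check_bootstrap_args(mean_R, sd_R, n_samples, level)
  if (!is.null(seed)) set.seed(seed)
  net <- infer_network(mean_R)
  n <- nrow(mean_R)
  mods <- net$modules
  bs <- bootstrap_draws(mean_R, sd_R, n_samples)
  valid <- colSums(is.na(bs$draws)) == 0
  n_valid <- sum(valid)
  if (n_valid / n_samples < min_valid_fraction) {
    mra_abort(
      paste0("only ", format(n_valid / n_samples, digits = 3),
             " of bootstrap draws were invertible (minimum ",
             min_valid_fraction, "); the network is too noisy for ",
             "percentile confidence intervals"),
      "mranet_instability", valid_fraction = n_valid / n_samples)
  }
  off <- bs$off
  q <- t(apply(bs$draws, 1, ci_quantiles, level = level))
  tab <- dplyr::bind_rows(
    tibble::tibble(
      parameter = paste0("r[", mods[row(mean_R)[off]], ",",
                         mods[col(mean_R)[off]], "]"),
      type = "connection",
      from = mods[col(mean_R)[off]],
      to = mods[row(mean_R)[off]],
      estimate = net$r[off],
      lower = q[seq_along(off), 1],
      upper = q[seq_along(off), 2]),
    tibble::tibble(
      parameter = paste0("P[", mods, "]"),
      type = "magnitude",
      from = mods,
      to = mods,
      estimate = unname(net$P),
      lower = q[length(off) + seq_len(n), 1],
      upper = q[length(off) + seq_len(n), 2]))
  tab$significant <- tab$lower > 0 | tab$upper < 0
  tab$n_valid <- n_valid
  new_mra_ci(tab, n_samples = n_samples, level = level, seed = seed,
             valid_fraction = n_valid / n_samples, kind = "network")
}

check_bootstrap_args <- function(mean_R, sd_R, n_samples, level) {
  if (!all(dim(mean_R) == dim(sd_R))) {
    mra_abort("`mean_R` and `sd_R` must have identical dimensions",
              "mranet_validation_error")
  }
  if (any(!is.finite(sd_R)) || any(sd_R < 0)) {
    mra_abort("`sd_R` entries must be finite and >= 0", "mranet_domain_error")
  }
  if (n_samples < 100) {
    mra_abort("at least 100 bootstrap samples are required",
              "mranet_validation_error")
  }
  if (level <= 0 || level >= 1) {
    mra_abort("`level` must lie strictly between 0 and 1",
              "mranet_validation_error")
  }
  invisible(TRUE)
}

#' Bootstrap confidence intervals for predicted abundances
#'
#' Propagates every bootstrap draw of the global response matrix through
#' network inference and [predict_abundance()] under the combined
#' perturbation `weights`, and reports percentile intervals of the predicted
#' abundances. Any requested level is supported (95/96/98/99% variants are
#' common when checking whether a measured validation value falls inside).
#' Draws whose predicted relative change reaches magnitude 2 cannot be mapped
#' back to an abundance and are counted as invalid, like singular draws.
#'
#' @inheritParams bootstrap_network
#' @param weights Combined-perturbation weight vector (see
#'   [predict_response()]).
#' @param basal Positive basal abundances per module.
#' @return An `mra_ci` whose rows are predicted module abundances (`type`
#'   `"abundance"`; no significance flag).
#' @export
bootstrap_prediction <- function(mean_R, sd_R, weights, basal,
                                 n_samples = 1e6, level = 0.95, seed = NULL,
                                 min_valid_fraction = 0.5) {
  check_bootstrap_args(mean_R, sd_R, n_samples, level)
  if (!is.null(seed)) set.seed(seed)
  net <- infer_network(mean_R)
  w <- check_weights(net, weights)
  n <- nrow(mean_R)
  mods <- net$modules
  if (length(basal) != n || any(basal <= 0) || any(!is.finite(basal))) {
    mra_abort("`basal` must be positive, one value per module",
              "mranet_domain_error")
  }
  point <- predict_abundance(net, w, basal)
  draws <- array(rnorm(n * n * n_samples, mean = mean_R, sd = sd_R),
                 dim = c(n, n, n_samples))
  pred <- matrix(NA_real_, n, n_samples)
  for (b in seq_len(n_samples)) {
    m <- draws[, , b]
    inv <- tryCatch(solve.default(m), error = function(e) NULL)
    if (is.null(inv)) next
    d <- diag(inv)
    if (any(d == 0) || any(!is.finite(inv))) next
    r <- -inv / d
    diag(r) <- -1
    v <- tryCatch(solve.default(r, -(1 / d) * w), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v)) || any(abs(v) >= 2)) next
    pred[, b] <- invert_relative_change(v, basal)
  }
  valid <- colSums(is.na(pred)) == 0
  n_valid <- sum(valid)
  if (n_valid / n_samples < min_valid_fraction) {
    mra_abort(
      paste0("only ", format(n_valid / n_samples, digits = 3),
             " of bootstrap draws gave representable predictions (minimum ",
             min_valid_fraction, ")"),
      "mranet_instability", valid_fraction = n_valid / n_samples)
  }
  q <- t(apply(pred, 1, ci_quantiles, level = level))
  tab <- tibble::tibble(
    parameter = paste0("x[", mods, "]"),
    type = "abundance",
    from = mods,
    to = mods,
    estimate = unname(point),
    lower = q[, 1],
    upper = q[, 2],
    significant = NA,
    n_valid = n_valid)
  new_mra_ci(tab, n_samples = n_samples, level = level, seed = seed,
             valid_fraction = n_valid / n_samples, kind = "prediction")
}

new_mra_ci <- function(tab, n_samples, level, seed, valid_fraction, kind) {
  structure(
    list(table = tab, n_samples = n_samples, level = level,
         seed = seed, valid_fraction = valid_fraction, kind = kind),
    class = "mra_ci")
}

#' @export
print.mra_ci <- function(x, ...) {
  cat("<mra_ci> ", round(100 * x$level, 1), "% percentile intervals from ",
      format(x$n_samples, big.mark = ","), " draws (",
      format(100 * x$valid_fraction, digits = 4), "% valid)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @method tidy mra_ci
#' @export
tidy.mra_ci <- function(x, ...) {
  x$table
}

#' @method glance mra_ci
#' @export
glance.mra_ci <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    level = x$level,
    valid_fraction = x$valid_fraction,
    n_significant = sum(x$table$significant, na.rm = TRUE))
}

#' Interval plot for bootstrap results
#'
#' @param object An `mra_ci`.
#' @param ... Unused.
#' @return A ggplot object showing each parameter's point estimate and
#'   interval; significant parameters (interval excluding 0) are marked.
#' @method autoplot mra_ci
#' @export
autoplot.mra_ci <- function(object, ...) {
  df <- object$table
  df$label <- ifelse(!is.na(df$significant) & df$significant,
                     paste0(df$parameter, " *"), df$parameter)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free") +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = paste0(round(100 * object$level, 1),
                                 "% bootstrap confidence intervals"),
                  subtitle = "* interval excludes 0") +
    ggplot2::theme_minimal()
}

#' Write a CI table as TSV
#'
#' @param ci An `mra_ci`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ci <- function(ci, path) {
  stopifnot(inherits(ci, "mra_ci"))
  out <- dplyr::mutate(ci$table,
                       dplyr::across(c("estimate", "lower", "upper"),
                                     ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path)
  invisible(path)
}
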