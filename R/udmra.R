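#' Fit incoming coefficients of a non-perturbed gene (unidirectional MRA)
#'
#' A gene that was never perturbed can be appended to an inferred network as
#' an extra module with outgoing coefficients fixed at zero. Its incoming
#' connection coefficients solve the linear system
#' `response_k = sum_j coef_j * R[j, k]` over the elementary perturbations
#' `k`, i.e. `coef = response %*% R^-1` (a row-vector solve, exact for
#' consistent systems).
#'
#' @param R Invertible global response matrix of the core network.
#' @param responses Numeric vector (length = module count) of the gene's
#'   symmetric relative changes under each elementary perturbation, in module
#'   order; entries must lie in (-2, 2).
#' @return Named numeric vector of incoming coefficients `r[gene, j]`.
#' @export
fit_udmra_row <- function(R, responses) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (length(responses) != n) {
    mra_abort(paste0("`responses` must have one entry per module (", n, ")"),
              "mranet_validation_error")
  }
  if (any(!is.finite(responses)) || any(abs(responses) >= 2)) {
    mra_abort("gene responses must be finite relative changes in (-2, 2)",
              "mranet_domain_error")
  }
  coef <- tryCatch(drop(solve(t(R), as.double(responses))),
                   error = function(e) {
                     mra_abort("global response matrix is singular",
                               "mranet_singular")
                   })
  setNames(coef, rownames(R))
}

#' Fit incoming coefficients for a panel of genes
#'
#' @param R Invertible global response matrix.
#' @param gene_responses Tibble with a `gene` column and one response column
#'   per module (named by module, in any order).
#' @return A tibble with `gene` and one coefficient column per module.
#' @export
fit_udmra <- function(R, gene_responses) {
  mods <- rownames(R)
  miss <- setdiff(c("gene", mods), names(gene_responses))
  if (length(miss)) {
    mra_abort(paste0("`gene_responses` lacks column(s): ",
                     paste(miss, collapse = ", ")),
              "mranet_validation_error")
  }
  resp <- as.matrix(gene_responses[, mods, drop = FALSE])
  if (any(!is.finite(resp)) || any(abs(resp) >= 2)) {
    mra_abort("gene responses must be finite relative changes in (-2, 2)",
              "mranet_domain_error")
  }
  coef <- resp %*% solve(R)   # row-wise solve for all genes at once
  out <- tibble::as_tibble(as.data.frame(coef))
  names(out) <- mods
  dplyr::bind_cols(tibble::tibble(gene = gene_responses$gene), out)
}

#' Predict a non-perturbed gene under a combined perturbation
#'
#' The core modules' relative changes under the combined perturbation are
#' `v = -r^-1 diag(P) c`; the gene's relative change is the fitted linear
#' combination `u = sum_j coef_j v_j`, and its abundance is
#' `basal * (2 + u) / (2 - u)`.
#'
#' @param coefficients Named incoming coefficients from [fit_udmra_row()].
#' @param net The core `mra_network`.
#' @param weights Combined-perturbation weights (see [predict_response()]).
#' @param basal_abundance The gene's positive basal abundance.
#' @return A list with `abundance` and `relative_change`.
#' @export
predict_gene <- function(coefficients, net, weights, basal_abundance) {
  stopifnot(inherits(net, "mra_network"))
  if (length(coefficients) != length(net$modules)) {
    mra_abort("`coefficients` must have one entry per core module",
              "mranet_validation_error")
  }
  if (!is.null(names(coefficients))) {
    coefficients <- coefficients[net$modules]
  }
  if (length(basal_abundance) != 1L || !is.finite(basal_abundance) ||
      basal_abundance <= 0) {
    mra_abort("`basal_abundance` must be a single positive value",
              "mranet_domain_error")
  }
  v <- predict_response(net, weights)
  u <- sum(coefficients * v)
  if (!is.finite(u) || abs(u) >= 2) {
    mra_abort(
      paste0("predicted gene relative change outside (-2, 2): ", u),
      "mranet_saturation")
  }
  list(abundance = invert_relative_change(u, basal_abundance),
       relative_change = u)
}

#' Optimize perturbation weights against observed responses
#'
#' When elementary perturbations are combined experimentally, their
#' effective magnitudes need not equal the single-perturbation magnitudes;
#' the weight vector `c` lets each elementary perturbation enter with its
#' own relative weight. This fits the free weights by minimizing the summed
#' squared relative error between the network's predicted relative changes
#' and the observed ones on the core modules, using a dense grid search
#' (default step 0.05 over [0, 2] per free weight) followed by
#' derivative-free local refinement. The search is deterministic and the
#' evaluated trace is returned.
#'
#' @param net An `mra_network`.
#' @param observed Named (or module-ordered) vector of observed relative
#'   changes of the core modules under the combined perturbation, entries in
#'   (-2, 2).
#' @param free Modules whose weights are optimized (character or index).
#' @param fixed_weights Weights for the remaining modules (default: 1 for
#'   perturbed-at-full-strength modules would be supplied by the caller;
#'   modules absent from the combination get 0).
#' @param grid Grid of candidate values per free weight.
#' @param objective `"relative"` (default) or `"absolute"` squared error;
#'   relative error is undefined when all observed entries are ~0, in which
#'   case an error advises absolute mode.
#' @return An object of class `udmra_weights`: `weights` (full vector),
#'   `objective_value`, `trace` (tibble of evaluated weight vectors and
#'   objectives, refinement included).
#' @export
optimize_weights <- function(net, observed, free,
                             fixed_weights = NULL,
                             grid = seq(0, 2, by = 0.05),
                             objective = c("relative", "absolute")) {
  stopifnot(inherits(net, "mra_network"))
  objective <- match.arg(objective)
  mods <- net$modules
  n <- length(mods)
  if (is.character(free)) {
    bad <- setdiff(free, mods)
    if (length(bad)) {
      mra_abort(paste0("unknown module(s) in `free`: ",
                       paste(bad, collapse = ", ")),
                "mranet_validation_error")
    }
    free_idx <- match(free, mods)
  } else {
    free_idx <- as.integer(free)
  }
  if (length(free_idx) == 0L) {
    mra_abort("`free` must name at least one module", "mranet_validation_error")
  }
  if (!is.null(names(observed))) observed <- observed[mods]
  observed <- as.double(observed)
  if (length(observed) != n || any(!is.finite(observed)) ||
      any(abs(observed) >= 2)) {
    mra_abort("`observed` must be relative changes in (-2, 2), one per module",
              "mranet_domain_error")
  }
  if (objective == "relative" && all(abs(observed) < 1e-12)) {
    mra_abort(
      "all observed responses are ~0: relative error is undefined; use objective = 'absolute'",
      "mranet_degenerate")
  }
  w0 <- setNames(numeric(n), mods)
  if (!is.null(fixed_weights)) {
    w0[names(fixed_weights)] <- fixed_weights
  }
  obj_fun <- function(wfree) {
    w <- w0
    w[free_idx] <- wfree
    if (all(w == 0)) return(Inf)
    v <- solve(net$r, -(net$P * w))
    if (objective == "relative") {
      keep <- abs(observed) >= 1e-12
      sum(((v[keep] - observed[keep]) / observed[keep])^2)
    } else {
      sum((v - observed)^2)
    }
  }
  grid_pts <- do.call(expand.grid, rep(list(grid), length(free_idx)))
  vals <- apply(grid_pts, 1, function(w) obj_fun(as.double(w)))
  trace <- tibble::as_tibble(grid_pts)
  names(trace) <- mods[free_idx]
  trace$objective <- vals
  best <- as.double(grid_pts[which.min(vals), ])
  # local derivative-free refinement around the best grid point
  if (length(free_idx) == 1L) {
    step <- diff(range(grid)) / (length(grid) - 1)
    opt <- optimize(obj_fun, interval = c(best - step, best + step))
    refined <- opt$minimum; refined_val <- opt$objective
  } else {
    opt <- optim(best, obj_fun, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    refined <- opt$par; refined_val <- opt$value
  }
  if (refined_val <= min(vals)) {
    ref_row <- as.list(setNames(refined, mods[free_idx]))
    ref_row$objective <- refined_val
    trace <- dplyr::bind_rows(trace, tibble::as_tibble(ref_row))
    best <- refined
  }
  w <- w0
  w[free_idx] <- best
  structure(
    list(weights = w, objective_value = min(trace$objective),
         trace = trace, objective = objective, free = mods[free_idx]),
    class = "udmra_weights")
}

#' @export
print.udmra_weights <- function(x, ...) {
  cat("<udmra_weights> objective (", x$objective, ") = ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Naive predictors of a double-perturbation abundance
#'
#' Baseline predictors that combine the abundances observed under each
#' single perturbation: their mean, geometric mean and maximum. Used as the
#' comparison for unidirectional MRA predictions. With `space = "response"`
#' the combination is done on fold changes relative to `basal` and mapped
#' back to abundances.
#'
#' @param observed Positive abundances of the gene under each single
#'   perturbation.
#' @param basal Positive basal abundance (only used in fold-change space).
#' @param space `"abundance"` (default) or `"response"` (fold-change).
#' @return A tibble with columns `method` (`"mean"`, `"gmean"`, `"max"`) and
#'   `prediction`.
#' @examples
#' naive_predictors(c(4, 9)) # mean 6.5, gmean 6, max 9
#' @export
naive_predictors <- function(observed, basal = NULL,
                             space = c("abundance", "response")) {
  space <- match.arg(space)
  if (length(observed) == 0L) {
    mra_abort("at least one single-perturbation observation is required",
              "mranet_validation_error")
  }
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    mra_abort("observed abundances must be positive", "mranet_domain_error")
  }
  x <- as.double(observed)
  if (space == "response") {
    if (is.null(basal) || basal <= 0) {
      mra_abort("fold-change space needs a positive `basal`",
                "mranet_domain_error")
    }
    fc <- x / basal
    preds <- c(mean = mean(fc), gmean = exp(mean(log(fc))), max = max(fc)) * basal
  } else {
    preds <- c(mean = mean(x), gmean = exp(mean(log(x))), max = max(x))
  }
  tibble::tibble(method = names(preds), prediction = unname(preds))
}

#' Benchmark prediction methods against observed abundances
#'
#' Computes per-gene relative errors `|pred - obs| / obs` for each method and
#' compares methods pairwise with a paired two-sided Wilcoxon signed-rank
#' test. Genes with zero observed abundance are skipped with a warning.
#'
#' @param predicted Tibble with columns `gene`, `method`, `predicted`.
#' @param observed Tibble with columns `gene`, `observed`.
#' @return An object of class `udmra_benchmark`: `errors` (tibble `gene`,
#'   `method`, `rel_error`), `summary` (median relative error per method),
#'   `tests` (pairwise Wilcoxon p-values).
#' @export
benchmark_predictions <- function(predicted, observed) {
  if (dplyr::n_distinct(observed$gene) < 2L) {
    mra_abort("benchmarking needs at least 2 genes", "mranet_validation_error")
  }
  zero <- observed$gene[observed$observed == 0]
  if (length(zero)) {
    warn(paste0("skipping gene(s) with zero observed abundance: ",
                paste(zero, collapse = ", ")))
    observed <- observed[observed$observed != 0, ]
  }
  errors <- predicted |>
    dplyr::inner_join(observed, by = "gene") |>
    dplyr::mutate(rel_error = abs(.data$predicted - .data$observed) /
                    abs(.data$observed)) |>
    dplyr::select("gene", "method", "rel_error")
  summary <- errors |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(median_rel_error = median(.data$rel_error),
                     mean_rel_error = mean(.data$rel_error),
                     n = dplyr::n(), .groups = "drop")
  methods <- sort(unique(errors$method))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(p) {
    a <- errors$rel_error[errors$method == p[1]][
      order(errors$gene[errors$method == p[1]])]
    b <- errors$rel_error[errors$method == p[2]][
      order(errors$gene[errors$method == p[2]])]
    d <- a - b
    if (all(d == 0)) {
      pval <- 1
    } else {
      pval <- suppressWarnings(
        wilcox.test(a, b, paired = TRUE, alternative = "two.sided")$p.value)
    }
    tibble::tibble(method_a = p[1], method_b = p[2], p_value = pval,
                   n = length(a))
  })
  structure(list(errors = errors, summary = summary, tests = tests),
            class = "udmra_benchmark")
}

#' @export
print.udmra_benchmark <- function(x, ...) {
  cat("<udmra_benchmark> median relative errors:\n")
  print(x$summary)
  cat("pairwise two-sided Wilcoxon signed-rank tests:\n")
  print(x$tests)
  invisible(x)
}

#' @method tidy udmra_benchmark
#' @export
tidy.udmra_benchmark <- function(x, ...) {
  x$errors
}

#' @method glance udmra_benchmark
#' @export
glance.udmra_benchmark <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$summary, "method", "median_rel_error"),
    names_from = "method", values_from = "median_rel_error",
    names_prefix = "median_")
}

#' Boxplot of per-method relative prediction errors
#'
#' @param object A `udmra_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot udmra_benchmark
#' @export
autoplot.udmra_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = .data$method, y = .data$rel_error)) +
    ggplot2::geom_boxplot(outlier.shape = 21) +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = NULL, y = "relative error",
                  title = "Prediction accuracy by method") +
    ggplot2::theme_minimal()
}
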