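# Standard SPC control-chart constants for subgroup sizes 2..10.
# d2(n) is the expected range of n i.i.d. standard normal variables; D4(n)
# (and D3) bound the range of an in-control subgroup relative to the mean
# range. Embedded so no table lookup happens at run time.
.spc_d2 <- c(`2` = 1.128, `3` = 1.693, `4` = 2.059, `5` = 2.326,
             `6` = 2.534, `7` = 2.704, `8` = 2.847, `9` = 2.970, `10` = 3.078)
.spc_d4 <- c(`2` = 3.267, `3` = 2.574, `4` = 2.282, `5` = 2.114,
             `6` = 2.004, `7` = 1.924, `8` = 1.864, `9` = 1.816, `10` = 1.777)
.spc_d3_lower <- c(`2` = 0, `3` = 0, `4` = 0, `5` = 0, `6` = 0,
                   `7` = 0.076, `8` = 0.136, `9` = 0.184, `10` = 0.223)

#' Hartley's constant d2
#'
#' `d2(n)` is the expected range of `n` independent standard normal
#' variables. Dividing an observed mean subgroup range by `d2(n)` yields an
#' unbiased estimate of the standard deviation, the classical range-based
#' estimator of statistical process control for small series.
#'
#' @param n Subgroup size, between 2 and 10.
#' @return The constant as a double (`hartley_d2(2)` is 1.128).
#' @export
hartley_d2 <- function(n) {
  spc_constant(.spc_d2, n, "d2")
}

#' @rdname hartley_d2
#' @details `spc_d4()` returns the upper range-chart control factor D4 used
#'   by the out-of-control exclusion rule of [spc_population_sd()], and
#'   `spc_d3()` the corresponding lower factor (0 for subgroup sizes up to 6).
#' @export
spc_d4 <- function(n) {
  spc_constant(.spc_d4, n, "D4")
}

#' @rdname hartley_d2
#' @export
spc_d3 <- function(n) {
  spc_constant(.spc_d3_lower, n, "D3")
}

spc_constant <- function(table, n, what) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L || n > 10L) {
    mra_abort(
      paste0(what, " is tabulated for subgroup sizes 2 to 10; got ", n,
             " (a single observation has no range)"),
      "mranet_domain_error")
  }
  unname(table[as.character(n)])
}

#' Range-based standard deviation for subgrouped replicates
#'
#' Estimates the intra-subgroup standard deviation of a small replicate
#' series with the SPC range method: the mean of the per-subgroup ranges
#' divided by Hartley's constant `d2(n_r)`. Subgroups are the biological
#' replicates; members are the technical replicates. With the usual design of
#' 3 biological x 2 technical replicates this uses the mean of the three
#' absolute duplicate differences divided by `d2(2) = 1.128`.
#'
#' @param subgroups A numeric matrix with one row per subgroup (size
#'   `k_t x n_r`), or a list of equal-length numeric vectors.
#' @return An object of class `spc_estimate`: a list with `s_intra`,
#'   `mean_range`, `d2`, `k_t`, `n_r`.
#' @examples
#' spc_intra_sd(rbind(c(1, 2), c(5, 7), c(10, 13)))
#' @export
spc_intra_sd <- function(subgroups) {
  if (is.list(subgroups)) {
    sizes <- lengths(subgroups)
    if (length(unique(sizes)) != 1L) {
      mra_abort("all subgroups must have the same size",
                "mranet_validation_error")
    }
    subgroups <- do.call(rbind, subgroups)
  }
  subgroups <- as.matrix(subgroups)
  if (!all(is.finite(subgroups))) {
    mra_abort("subgroup values must be finite", "mranet_domain_error")
  }
  k_t <- nrow(subgroups)
  n_r <- ncol(subgroups)
  if (k_t < 1L) {
    mra_abort("at least one subgroup is required", "mranet_validation_error")
  }
  d2 <- hartley_d2(n_r)
  ranges <- apply(subgroups, 1, function(x) max(x) - min(x))
  mean_range <- mean(ranges)
  structure(
    list(s_intra = mean_range / d2, mean_range = mean_range,
         ranges = ranges, d2 = d2, k_t = k_t, n_r = n_r),
    class = "spc_estimate")
}

#' @export
print.spc_estimate <- function(x, ...) {
  cat("<spc_estimate> s_intra = ", format(x$s_intra, digits = 6),
      " (mean range ", format(x$mean_range, digits = 6),
      " / d2(", x$n_r, ") = ", x$d2, "; ", x$k_t, " subgroups)\n", sep = "")
  invisible(x)
}

#' Pooled gene-population standard deviation with out-of-control exclusion
#'
#' For sequencing-style data with very few replicates, the per-cell SPC
#' estimator has too few degrees of freedom, so the variance of a response
#' column is learned collectively across a gene population: each gene's
#' replicates form one subgroup, the mean range over retained genes is
#' converted to a standard deviation via `d2`, and genes whose range is out
#' of control under the configured rule are excluded iteratively until the
#' retained set reaches a fixed point.
#'
#' The default `"range"` rule excludes a gene whose subgroup range exceeds
#' `D4(n) * mean range` (the classical range-chart upper control limit; a
#' lower limit `D3(n) * mean range` applies only for subgroup sizes above 6,
#' where D3 > 0). The `"individuals"` rule instead excludes genes whose mean
#' response deviates from the population mean by more than `3 * sigma`.
#' `"none"` disables exclusion, giving the plain pooled estimator.
#'
#' @param responses Numeric matrix or data frame, rows = genes (rownames used
#'   as identifiers), columns = replicate measurements of the response under
#'   one perturbation. At least 2 replicates and 10 genes.
#' @param rule Out-of-control rule: `"range"`, `"individuals"` or `"none"`.
#' @param min_genes Abort if fewer genes than this remain (the population is
#'   too heterogeneous to pool).
#' @param max_iter Safety bound on the exclusion loop.
#' @return An object of class `spc_population`: `sigma`, `retained_genes`,
#'   `excluded_genes` (tibble with the exclusion iteration), `n_iterations`,
#'   `mean_range`, `d2`, `rule`.
#' @export
spc_population_sd <- function(responses, rule = c("range", "individuals", "none"),
                              min_genes = 5L, max_iter = 100L) {
  rule <- match.arg(rule)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  if (!all(is.finite(responses))) {
    mra_abort("responses must be finite", "mranet_domain_error")
  }
  if (ncol(responses) < 2L) {
    mra_abort("at least 2 replicates per gene are required",
              "mranet_validation_error")
  }
  if (nrow(responses) < 10L) {
    mra_abort("pooling needs a population: at least 10 genes required",
              "mranet_validation_error")
  }
  genes <- rownames(responses)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(responses)))
  n_r <- ncol(responses)
  d2 <- hartley_d2(n_r)
  ranges <- setNames(apply(responses, 1, function(x) max(x) - min(x)), genes)
  means <- setNames(rowMeans(responses), genes)

  retained <- genes
  excluded <- tibble::tibble(gene = character(), iteration = integer())
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (length(retained) < min_genes) {
      mra_abort(
        paste0("fewer than ", min_genes, " genes remain under control; ",
               "the population is too heterogeneous to pool"),
        "mranet_degenerate")
    }
    mean_range <- mean(ranges[retained])
    sigma <- mean_range / d2
    out <- switch(rule,
      none = character(),
      range = {
        upper <- spc_d4(n_r) * mean_range
        lower <- spc_d3(n_r) * mean_range
        retained[ranges[retained] > upper | ranges[retained] < lower]
      },
      individuals = {
        center <- mean(means[retained])
        retained[abs(means[retained] - center) > 3 * sigma]
      })
    if (length(out) == 0L || iter >= max_iter) break
    excluded <- dplyr::bind_rows(
      excluded, tibble::tibble(gene = out, iteration = iter))
    retained <- setdiff(retained, out)
  }
  structure(
    list(sigma = sigma, mean_range = mean_range, d2 = d2,
         retained_genes = retained, excluded_genes = excluded,
         n_iterations = iter, rule = rule, n_r = n_r),
    class = "spc_population")
}

#' @export
print.spc_population <- function(x, ...) {
  cat("<spc_population> sigma = ", format(x$sigma, digits = 6),
      " from ", length(x$retained_genes), " genes (",
      nrow(x$excluded_genes), " excluded in ", x$n_iterations,
      " iteration(s), rule '", x$rule, "')\n", sep = "")
  invisible(x)
}

#' @method tidy spc_population
#' @export
tidy.spc_population <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(gene = x$retained_genes, status = "retained",
                   iteration = NA_integer_),
    tibble::tibble(gene = x$excluded_genes$gene, status = "excluded",
                   iteration = x$excluded_genes$iteration))
}

#' Population standard deviations for every perturbation column
#'
#' Convenience wrapper applying [spc_population_sd()] to each perturbation of
#' a gene x replicate x perturbation response table.
#'
#' @param responses A tibble with columns `gene`, `perturbation`, `replicate`,
#'   `response`.
#' @inheritParams spc_population_sd
#' @return A tibble with one row per perturbation: `perturbation`, `sigma`,
#'   `n_retained`, `n_excluded`, `n_iterations`.
#' @export
spc_population_sd_by_column <- function(responses,
                                        rule = c("range", "individuals", "none"),
                                        min_genes = 5L) {
  rule <- match.arg(rule)
  purrr::map_dfr(split(responses, responses$perturbation), function(df) {
    wide <- tidyr::pivot_wider(df[, c("gene", "replicate", "response")],
                               names_from = "replicate",
                               values_from = "response")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$gene
    fit <- spc_population_sd(m, rule = rule, min_genes = min_genes)
    tibble::tibble(
      perturbation = df$perturbation[1],
      sigma = fit$sigma,
      n_retained = length(fit$retained_genes),
      n_excluded = nrow(fit$excluded_genes),
      n_iterations = fit$n_iterations)
  })
}
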