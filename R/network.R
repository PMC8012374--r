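#' Infer a local response network from a global response matrix
#'
#' Solves the MRA system `r R = -P` in two steps: with the diagonal of the
#' connection-coefficient matrix normalized to -1, the perturbation
#' magnitudes are `P[i] = 1 / (R^-1)[i, i]` and the connection coefficients
#' are `r = -[diag(R^-1)]^-1 R^-1`. `r[i, j]` is the direct (local) effect of
#' module `j` on module `i`, normalized by basal activities; `P[i]` is the
#' relative direct effect of the elementary perturbation on its own module.
#'
#' @param R Square numeric global response matrix with identical row and
#'   column module order (rows respond, columns are perturbed).
#' @param max_condition Reject matrices whose 2-norm condition number exceeds
#'   this bound instead of silently amplifying noise.
#' @return An object of class `mra_network` with elements `r` (connection
#'   coefficients, diagonal exactly -1), `P` (named perturbation magnitudes),
#'   `modules`, `R`, and `condition_number`.
#' @examples
#' R <- matrix(c(-0.5, 0.3, 0.2, -0.8), 2, 2,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' infer_network(R)
#' @export
infer_network <- function(R, max_condition = 1e8) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) {
    mra_abort("global response matrix must be square", "mranet_validation_error")
  }
  if (!all(is.finite(R))) {
    mra_abort("global response matrix contains non-finite entries",
              "mranet_domain_error")
  }
  mods <- rownames(R)
  if (is.null(mods)) {
    mods <- paste0("M", seq_len(nrow(R)))
    dimnames(R) <- list(mods, mods)
  }
  kap <- kappa(R, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    mra_abort(
      paste0("global response matrix is singular or ill-conditioned ",
             "(condition number ", format(kap, digits = 4),
             " > ", format(max_condition), ")"),
      "mranet_singular", condition_number = kap)
  }
  Rinv <- solve(R)
  d <- diag(Rinv)
  zero <- which(d == 0 | !is.finite(d))
  if (length(zero)) {
    mra_abort(
      paste0("perturbation magnitude undefined for module(s): ",
             paste(mods[zero], collapse = ", "),
             " (zero diagonal entry of R^-1)"),
      "mranet_singular")
  }
  P <- 1 / d
  r <- -Rinv / d        # row i divided by (R^-1)[i,i]
  diag(r) <- -1         # enforced exactly, not left to rounding
  dimnames(r) <- list(mods, mods)
  structure(
    list(r = r, P = setNames(P, mods), modules = mods, R = R,
         condition_number = kap),
    class = "mra_network"
  )
}

#' Construct a network object from known coefficients
#'
#' Mainly used for ground truths and for reloading exported networks.
#'
#' @param r Connection-coefficient matrix with diagonal -1.
#' @param P Perturbation magnitudes (length `nrow(r)`, nonzero).
#' @param modules Optional module identifiers (defaults to `rownames(r)`).
#' @return An `mra_network`.
#' @export
mra_network <- function(r, P, modules = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) {
    mra_abort("`r` must be square", "mranet_validation_error")
  }
  if (any(diag(r) != -1)) {
    mra_abort("the diagonal of `r` must be exactly -1",
              "mranet_validation_error")
  }
  if (is.null(modules)) modules <- rownames(r)
  if (is.null(modules)) modules <- paste0("M", seq_len(nrow(r)))
  if (length(P) != nrow(r) || any(!is.finite(P)) || any(P == 0)) {
    mra_abort("`P` must be a finite, nonzero vector of length nrow(r)",
              "mranet_validation_error")
  }
  dimnames(r) <- list(modules, modules)
  structure(
    list(r = r, P = setNames(as.double(P), modules), modules = modules,
         R = reconstruct_response_impl(r, P, modules),
         condition_number = kappa(r, exact = TRUE)),
    class = "mra_network"
  )
}

reconstruct_response_impl <- function(r, P, modules) {
  R <- -solve(r) %*% diag(P, nrow(r))
  dimnames(R) <- list(modules, modules)
  R
}

#' Reconstruct the global response matrix implied by a network
#'
#' Computes `-r^-1 diag(P)`; for a network inferred from a matrix `R` this
#' reproduces `R` to solver tolerance.
#'
#' @param net An `mra_network`.
#' @return Numeric matrix with module dimnames.
#' @export
reconstruct_response <- function(net) {
  stopifnot(inherits(net, "mra_network"))
  reconstruct_response_impl(net$r, net$P, net$modules)
}

check_weights <- function(net, weights) {
  n <- length(net$modules)
  if (!is.null(names(weights))) {
    miss <- setdiff(names(weights), net$modules)
    if (length(miss)) {
      mra_abort(paste0("unknown module(s) in perturbation weights: ",
                       paste(miss, collapse = ", ")),
                "mranet_validation_error")
    }
    w <- setNames(numeric(n), net$modules)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != n) {
      mra_abort(paste0("perturbation weight vector must have length ", n),
                "mranet_validation_error")
    }
    w <- setNames(as.double(weights), net$modules)
  }
  if (any(!is.finite(w))) {
    mra_abort("perturbation weights must be finite", "mranet_domain_error")
  }
  if (all(w == 0)) {
    mra_abort("a combined perturbation needs at least one nonzero weight",
              "mranet_validation_error")
  }
  w
}

#' Predict module responses under a combined perturbation
#'
#' A combined perturbation is a weighted sum of the elementary perturbations:
#' weight 1 applies an elementary perturbation at full strength, fractional
#' weights scale it (linearity between perturbation strength and parameter
#' change is assumed). The predicted relative changes are `-r^-1 diag(P) c`.
#'
#' @param net An `mra_network`.
#' @param weights Numeric weight vector over elementary perturbations, either
#'   of full length in module order or named by module (missing modules get
#'   weight 0). Must have at least one nonzero entry.
#' @return Named numeric vector of predicted relative changes per module.
#' @examples
#' R <- matrix(c(-0.5, 0.3, 0.2, -0.8), 2, 2)
#' net <- infer_network(R)
#' predict_response(net, c(1, 0)) # equals column 1 of R
#' @export
predict_response <- function(net, weights) {
  stopifnot(inherits(net, "mra_network"))
  w <- check_weights(net, weights)
  v <- tryCatch(solve(net$r, -(net$P * w)),
                error = function(e) {
                  mra_abort("connection-coefficient matrix is singular",
                            "mranet_singular")
                })
  setNames(as.vector(v), net$modules)
}

#' Predict module abundances under a combined perturbation
#'
#' Converts the predicted relative changes `v` of [predict_response()] back to
#' the abundance scale by inverting the symmetric relative difference:
#' `x = basal * (2 + v) / (2 - v)`. The inversion requires `|v| < 2`;
#' predictions outside that range cannot correspond to any positive abundance
#' and raise a saturation error naming the module.
#'
#' @inheritParams predict_response
#' @param basal Positive basal abundances, one per module (recycled names as
#'   in `net$modules`).
#' @return Named numeric vector of predicted abundances.
#' @export
predict_abundance <- function(net, weights, basal) {
  v <- predict_response(net, weights)
  if (length(basal) != length(v) || any(!is.finite(basal)) || any(basal <= 0)) {
    mra_abort("`basal` must be positive and of length equal to the module count",
              "mranet_domain_error")
  }
  sat <- which(abs(v) >= 2)
  if (length(sat)) {
    mra_abort(
      paste0("predicted relative change outside (-2, 2) for module(s): ",
             paste(net$modules[sat], collapse = ", ")),
      "mranet_saturation")
  }
  setNames(invert_relative_change(v, as.double(basal)), net$modules)
}

#' @export
print.mra_network <- function(x, digits = 3, ...) {
  cat("<mra_network> ", length(x$modules), " modules (condition number ",
      format(x$condition_number, digits = 4), ")\n", sep = "")
  cat("connection coefficients r (column acts on row):\n")
  print(round(x$r, digits))
  cat("perturbation magnitudes P:\n")
  print(round(x$P, digits))
  invisible(x)
}

#' Tidy a fitted network into an edge table
#'
#' @param x An `mra_network`.
#' @param ci Optional CI table from [bootstrap_network()]; when given, the
#'   columns `lower`, `upper` and `significant` are joined onto the edges.
#' @param ... Unused.
#' @return A tibble with one row per directed edge (off-diagonal coefficient):
#'   `from`, `to`, `coefficient`, `sign`.
#' @method tidy mra_network
#' @export
tidy.mra_network <- function(x, ci = NULL, ...) {
  n <- length(x$modules)
  idx <- which(row(x$r) != col(x$r))
  out <- tibble::tibble(
    from = x$modules[col(x$r)[idx]],
    to = x$modules[row(x$r)[idx]],
    coefficient = x$r[idx],
    sign = ifelse(x$r[idx] >= 0, "+", "-")
  )
  out <- dplyr::arrange(out, match(.data$from, x$modules),
                        match(.data$to, x$modules))
  if (!is.null(ci)) {
    cc <- dplyr::filter(tidy(ci), .data$type == "connection")
    out <- dplyr::left_join(
      out, dplyr::select(cc, "from", "to", "lower", "upper", "significant"),
      by = c("from", "to"))
  }
  out
}

#' @method glance mra_network
#' @export
glance.mra_network <- function(x, ...) {
  off <- x$r[row(x$r) != col(x$r)]
  tibble::tibble(
    n_modules = length(x$modules),
    condition_number = x$condition_number,
    max_abs_coefficient = max(abs(off)),
    n_positive = sum(off > 0),
    n_negative = sum(off < 0)
  )
}

#' Heatmap of connection coefficients
#'
#' @param object An `mra_network`.
#' @param ... Unused.
#' @return A ggplot object; tiles show `r[to, from]`, i.e. the direct effect
#'   of the column module on the row module.
#' @method autoplot mra_network
#' @export
autoplot.mra_network <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$from, object$modules),
                                   y = factor(.data$to, rev(object$modules)),
                                   fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$coefficient))) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "acting module", y = "responding module",
                  fill = "coefficient",
                  title = "Local response (connection) coefficients") +
    ggplot2::theme_minimal()
}

#' @export
plot.mra_network <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}

#' Write or read a network as delimited text
#'
#' `write_network()` writes `r.tsv` (connection coefficients) and `P.tsv`
#' (perturbation magnitudes) into a directory, with module identifiers as
#' headers and full double precision. `read_network()` loads them back.
#'
#' @param net An `mra_network`.
#' @param dir Directory path (created if needed).
#' @return `write_network()` returns `dir` invisibly; `read_network()`
#'   returns an `mra_network`.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "mra_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_named_matrix(net$r, file.path(dir, "r.tsv"))
  readr::write_tsv(
    tibble::tibble(module = net$modules, P = sprintf("%.17g", net$P)),
    file.path(dir, "P.tsv"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  r <- read_named_matrix(file.path(dir, "r.tsv"))
  p <- readr::read_tsv(file.path(dir, "P.tsv"), show_col_types = FALSE,
                       col_types = "cc")
  mra_network(r, setNames(as.double(p$P), p$module)[rownames(r)])
}

write_named_matrix <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(apply(m, 2, sprintf, fmt = "%.17g")))
  df <- dplyr::bind_cols(tibble::tibble(module = rownames(m)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

read_named_matrix <- function(path) {
  # values are read as text and converted with as.double(), which is
  # correctly rounded, so write/read round-trips are bit-exact
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  m <- apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2), as.double)
  rownames(m) <- df[[1]]
  m
}
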