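#' Infer a network with a candidate gene replacing one module's reporter
#'
#' For screening, each candidate gene takes the place of the reference
#' reporter of one module: the replaced module's row of the global response
#' matrix becomes the candidate's responses to every elementary perturbation,
#' while the other rows are the shared modules' responses. The assembled
#' matrix is passed to [infer_network()].
#'
#' @param candidate_responses Numeric vector (length n, module order) of the
#'   candidate's symmetric relative changes under each elementary
#'   perturbation.
#' @param shared_responses Numeric (n-1) x n matrix of the non-replaced
#'   modules' responses, rows named by module.
#' @param replace Identifier of the replaced module.
#' @param modules Module order of the network (length n).
#' @param max_condition Conditioning guard forwarded to [infer_network()].
#' @return An `mra_network`.
#' @export
infer_candidate_network <- function(candidate_responses, shared_responses,
                                    replace, modules, max_condition = 1e8) {
  n <- length(modules)
  if (!replace %in% modules) {
    mra_abort(paste0("`replace` must be one of: ",
                     paste(modules, collapse = ", ")),
              "mranet_validation_error")
  }
  if (length(candidate_responses) != n) {
    mra_abort(paste0("candidate responses must have length ", n),
              "mranet_validation_error")
  }
  shared_responses <- as.matrix(shared_responses)
  others <- setdiff(modules, replace)
  if (!all(others %in% rownames(shared_responses))) {
    mra_abort("`shared_responses` must have rows named by the shared modules",
              "mranet_validation_error")
  }
  R <- matrix(NA_real_, n, n, dimnames = list(modules, modules))
  R[replace, ] <- as.double(candidate_responses)
  R[others, ] <- shared_responses[others, , drop = FALSE]
  infer_network(R, max_condition = max_condition)
}

#' Distance between two inferred networks
#'
#' Compares the connection-coefficient matrices of two networks over their
#' off-diagonal entries flattened in a fixed row-major order. The fixed -1
#' diagonal carries no information and is excluded by default (a flag
#' restores it for parity experiments). `euclidean` is the l2 norm of the
#' difference; `one_minus_correlation` is 1 minus the Pearson correlation of
#' the two coefficient vectors (scale-free, in \[0, 2\]).
#'
#' @param a,b `mra_network` objects with identical module order.
#' @param metric `"euclidean"` or `"one_minus_correlation"`.
#' @param include_diagonal Include the constant -1 diagonal in the vectors.
#' @return A nonnegative distance.
#' @export
network_distance <- function(a, b,
                             metric = c("euclidean", "one_minus_correlation"),
                             include_diagonal = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "mra_network"), inherits(b, "mra_network"))
  if (length(a$modules) != length(b$modules) ||
      !all(a$modules == b$modules)) {
    mra_abort("networks must share dimension and module order",
              "mranet_validation_error")
  }
  va <- coefficient_vector(a$r, include_diagonal)
  vb <- coefficient_vector(b$r, include_diagonal)
  if (metric == "euclidean") {
    sqrt(sum((va - vb)^2))
  } else {
    if (sd(va) == 0 || sd(vb) == 0) {
      mra_abort("correlation distance undefined for zero-variance coefficients",
                "mranet_degenerate")
    }
    1 - cor(va, vb)
  }
}

# off-diagonal (or all) entries in row-major order
coefficient_vector <- function(r, include_diagonal = FALSE) {
  rt <- t(r)
  keep <- if (include_diagonal) rep(TRUE, length(rt)) else row(rt) != col(rt)
  rt[keep]
}

#' Rank candidate genes by network proximity to a reference
#'
#' Infers one network per candidate gene (each replacing the reference
#' reporter, see [infer_candidate_network()]), computes the Euclidean and
#' 1-correlation distances of its connection coefficients to the reference
#' network, and ranks the candidates under both metrics. Candidates whose
#' assembled response matrix is singular are flagged un-screenable and keep
#' `NA` distances/ranks rather than aborting the screen. Ties are broken by
#' panel order of the gene identifiers.
#'
#' @param reference The reference `mra_network`.
#' @param panel Tibble with a `gene` column and one response column per
#'   module (the candidate's relative change under that module's elementary
#'   perturbation).
#' @param shared_responses (n-1) x n matrix of the shared modules' responses
#'   (rows named by module).
#' @param replace Module whose reporter the candidates replace.
#' @param max_condition Conditioning guard for the per-candidate inference.
#' @return A tibble: `gene`, `euclidean`, `one_minus_correlation`,
#'   `rank_euclid`, `rank_corr`, `screenable`.
#' @export
rank_candidates <- function(reference, panel, shared_responses, replace,
                            max_condition = 1e8) {
  stopifnot(inherits(reference, "mra_network"))
  if (nrow(panel) == 0L) {
    mra_abort("empty candidate panel", "mranet_validation_error")
  }
  mods <- reference$modules
  miss <- setdiff(c("gene", mods), names(panel))
  if (length(miss)) {
    mra_abort(paste0("`panel` lacks column(s): ", paste(miss, collapse = ", ")),
              "mranet_validation_error")
  }
  res <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    resp <- as.double(panel[i, mods])
    net <- tryCatch(
      infer_candidate_network(resp, shared_responses, replace, mods,
                              max_condition = max_condition),
      mranet_error = function(e) NULL)
    if (is.null(net)) {
      return(tibble::tibble(gene = panel$gene[i], euclidean = NA_real_,
                            one_minus_correlation = NA_real_,
                            screenable = FALSE))
    }
    tibble::tibble(
      gene = panel$gene[i],
      euclidean = network_distance(net, reference, "euclidean"),
      one_minus_correlation = tryCatch(
        network_distance(net, reference, "one_minus_correlation"),
        mranet_degenerate = function(e) NA_real_),
      screenable = TRUE)
  })
  if (!any(res$screenable)) {
    mra_abort("no candidate produced an invertible response matrix",
              "mranet_degenerate")
  }
  # ties broken by panel order (stable rank on the input sequence)
  res$rank_euclid <- rank_with_order(res$euclidean)
  res$rank_corr <- rank_with_order(res$one_minus_correlation)
  res
}

rank_with_order <- function(x) {
  r <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  r[ok] <- as.integer(rank(x[ok], ties.method = "first"))
  r
}
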