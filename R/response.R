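#' Symmetric relative change between two abundances
#'
#' Computes `2 * (x_pert - x_basal) / (x_pert + x_basal)`, the symmetric
#' relative-difference estimator of a relative change. It is bounded in
#' (-2, 2) for positive abundances, antisymmetric under argument swap, and
#' avoids divisions by values close to zero, which makes it numerically
#' preferable to the plain relative difference.
#'
#' @param x_pert,x_basal Strictly positive, finite abundances (vectorized).
#' @param what Optional label(s) used in error messages to identify the
#'   offending reporter/condition cell.
#' @return Numeric vector of relative changes in (-2, 2).
#' @examples
#' symmetric_relative_change(3, 1) # 1
#' symmetric_relative_change(1, 3) # -1
#' @export
symmetric_relative_change <- function(x_pert, x_basal, what = NULL) {
  bad <- !is.finite(x_pert) | x_pert <= 0 | !is.finite(x_basal) | x_basal <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    lab <- if (!is.null(what)) paste0(" [", what[min(i, length(what))], "]") else ""
    mra_abort(
      paste0("abundances must be strictly positive and finite; got (",
             x_pert[i], ", ", x_basal[i], ")", lab),
      "mranet_domain_error")
  }
  2 * (x_pert - x_basal) / (x_pert + x_basal)
}

# inverse of the symmetric relative change: abundance implied by a relative
# change v on a basal abundance (requires |v| < 2)
invert_relative_change <- function(v, basal) {
  basal * (2 + v) / (2 - v)
}

#' Global response matrix from perturbation measurements
#'
#' Entry `[j, k]` of the global response matrix is the symmetric relative
#' change of module `j`'s reporter between the condition perturbing module
#' `k` and the basal condition. These are systems-level responses, confounded
#' by propagation through the network; [infer_network()] disentangles them
#' into direct connection coefficients.
#'
#' In `per_replicate` mode, biological replicate `i` / technical replicate
#' `r` of each perturbed condition is paired with the same `(i, r)` of the
#' basal condition, yielding `k_bio * n_tech` matrices. `pooled` mode returns
#' their element-wise mean, which is the point-estimate input of
#' [infer_network()] and the bootstrap.
#'
#' @param data A measurement tibble (see [mra_measurements()]).
#' @param design An [mra_design()].
#' @param mode `"pooled"` for the mean matrix, `"per_replicate"` for the list
#'   of replicate matrices (named `bio<i>.tech<r>`).
#' @return A numeric matrix with module dimnames, or a named list of such
#'   matrices.
#' @examples
#' design <- mra_design(c("A", "B"),
#'                      perturbations = c(pA = "A", pB = "B"),
#'                      basal = "basal", k_bio = 1, n_tech = 1)
#' data <- mra_measurements(
#'   reporter = rep(c("A", "B"), 3),
#'   condition = rep(c("basal", "pA", "pB"), each = 2),
#'   bio_rep = 1, tech_rep = 1,
#'   value = c(10, 20, 5, 20, 10, 30)
#' )
#' global_response(data, design)
#' @export
global_response <- function(data, design, mode = c("pooled", "per_replicate")) {
  mode <- match.arg(mode)
  validate_measurements(data, design)
  mods <- design$modules
  n <- length(mods)
  key <- paste(data$reporter, data$condition, data$bio_rep, data$tech_rep,
               sep = "\r")
  vals <- setNames(data$value, key)
  lookup <- function(reporter, condition, i, r) {
    unname(vals[paste(reporter, condition, i, r, sep = "\r")])
  }
  reps <- expand.grid(tech = seq_len(design$n_tech),
                      bio = seq_len(design$k_bio))[, c("bio", "tech")]
  out <- vector("list", nrow(reps))
  names(out) <- paste0("bio", reps$bio, ".tech", reps$tech)
  for (q in seq_len(nrow(reps))) {
    i <- reps$bio[q]; r <- reps$tech[q]
    R <- matrix(NA_real_, n, n, dimnames = list(mods, mods))
    for (k in seq_len(n)) {
      cond <- condition_for(design, mods[k])
      for (j in seq_len(n)) {
        rep_j <- design$reporters[[mods[j]]]
        R[j, k] <- symmetric_relative_change(
          lookup(rep_j, cond, i, r),
          lookup(rep_j, design$basal, i, r),
          what = paste0(rep_j, " / ", cond, " vs ", design$basal,
                        " (bio ", i, ", tech ", r, ")"))
      }
    }
    out[[q]] <- R
  }
  if (mode == "per_replicate") out else Reduce(`+`, out) / length(out)
}
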