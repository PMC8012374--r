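#' Define a synthetic ground-truth network
#'
#' A ground truth fixes the connection coefficients `r` (diagonal -1), the
#' perturbation magnitudes `P`, basal abundances, and a replicate noise
#' model. The implied global response matrix `R = -r^-1 diag(P)` must have
#' all entries inside (-2, 2) — otherwise no positive abundances can realize
#' those responses through the symmetric relative difference and the truth
#' is rejected at construction.
#'
#' The noise model mirrors a biological x technical replicate hierarchy: a
#' biological component shared by the technical replicates of one
#' preparation, plus an independent technical component. In
#' `"log_abundance"` space the components act multiplicatively on
#' abundances (log-normal measurement error, the realistic qPCR/RNA-seq
#' model); in `"response"` space they act additively on the global response
#' coefficients themselves, matching the bootstrap's Gaussian-noise-on-R
#' assumption exactly.
#'
#' @param r Connection-coefficient matrix, diagonal -1.
#' @param P Nonzero perturbation magnitudes (negative for inhibitory
#'   perturbations such as siRNA or ligand removal).
#' @param basal Positive basal abundances per module.
#' @param sigma_bio,sigma_tech Nonnegative noise standard deviations for the
#'   biological and technical components.
#' @param noise_space `"log_abundance"` or `"response"`.
#' @param modules Optional module identifiers.
#' @param max_condition Reject truths whose implied `R` is worse conditioned
#'   than this.
#' @return An object of class `mra_truth` with elements `r`, `P`, `basal`,
#'   `R` (implied responses), `modules` and the noise settings.
#' @export
mra_truth <- function(r, P, basal, sigma_bio = 0.1, sigma_tech = 0.05,
                      noise_space = c("log_abundance", "response"),
                      modules = NULL, max_condition = 1e3) {
  noise_space <- match.arg(noise_space)
  net <- mra_network(r, P, modules = modules)
  if (length(basal) != length(net$modules) || any(basal <= 0) ||
      any(!is.finite(basal))) {
    mra_abort("`basal` must be positive, one value per module",
              "mranet_domain_error")
  }
  if (sigma_bio < 0 || sigma_tech < 0) {
    mra_abort("noise standard deviations must be >= 0", "mranet_domain_error")
  }
  kap <- kappa(net$R, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    mra_abort(
      paste0("implied global response matrix is ill-conditioned (",
             format(kap, digits = 4), " > ", format(max_condition), ")"),
      "mranet_singular")
  }
  if (any(abs(net$R) >= 2)) {
    mra_abort(
      "implied global responses reach magnitude 2; no positive abundances can realize this truth",
      "mranet_domain_error")
  }
  structure(
    list(r = net$r, P = net$P, basal = setNames(as.double(basal), net$modules),
         R = net$R, modules = net$modules, sigma_bio = sigma_bio,
         sigma_tech = sigma_tech, noise_space = noise_space),
    class = "mra_truth")
}

#' @export
print.mra_truth <- function(x, ...) {
  cat("<mra_truth> ", length(x$modules), " modules, noise (bio ",
      x$sigma_bio, ", tech ", x$sigma_tech, ") in ", x$noise_space,
      " space\n", sep = "")
  invisible(x)
}

#' Draw a random well-conditioned ground truth
#'
#' Rejection-samples connection coefficients (uniform off-diagonals),
#' perturbation magnitudes (uniform magnitude in `p_range`, negative sign by
#' default, emulating inhibitory perturbations) and basal abundances until
#' the implied global response matrix is well conditioned with all entries
#' in (-2, 2). Uses the current RNG state; seed the session (or pass `seed`)
#' for reproducibility.
#'
#' @param n Module count.
#' @param coef_max Off-diagonal coefficients are drawn from
#'   `U(-coef_max, coef_max)`.
#' @param p_range Magnitude range of the perturbation magnitudes.
#' @param basal_range Range of basal abundances.
#' @param max_condition Conditioning bound on the implied `R`.
#' @param seed Optional seed set before drawing.
#' @param ... Passed to [mra_truth()] (noise settings).
#' @return An `mra_truth`.
#' @export
random_mra_truth <- function(n, coef_max = 0.9, p_range = c(0.3, 1.5),
                             basal_range = c(5, 50), max_condition = 1e3,
                             seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(1000L)) {
    r <- matrix(runif(n * n, -coef_max, coef_max), n, n)
    diag(r) <- -1
    P <- -runif(n, p_range[1], p_range[2])
    basal <- runif(n, basal_range[1], basal_range[2])
    tr <- tryCatch(
      mra_truth(r, P, basal, max_condition = max_condition, ...),
      mranet_error = function(e) NULL)
    if (!is.null(tr)) return(tr)
  }
  mra_abort("could not draw an admissible ground truth in 1000 tries",
            "mranet_degenerate")
}

#' Canonical experiment design for a ground truth
#'
#' Conditions are named `basal` and `pert_<module>`; the replicate structure
#' defaults to the 3 biological x 2 technical design.
#'
#' @param truth An `mra_truth` (or module character vector).
#' @param k_bio,n_tech Replicate structure.
#' @return An `mra_design`.
#' @export
truth_design <- function(truth, k_bio = 3L, n_tech = 2L) {
  mods <- if (inherits(truth, "mra_truth")) truth$modules else as.character(truth)
  mra_design(
    modules = mods,
    perturbations = setNames(mods, paste0("pert_", mods)),
    basal = "basal",
    k_bio = k_bio, n_tech = n_tech)
}


#' Simulate a replicate-structured perturbation dataset
#'
#' Generates the abundance table an experiment under the given design would
#' produce if the truth's linear local-response model held exactly: the
#' noiseless perturbed abundance of module `j` under condition `k` is
#' `basal_j (2 + R[j,k]) / (2 - R[j,k])`, and replicate noise is layered on
#' according to the truth's noise model. With zero noise the full inference
#' pipeline recovers the truth exactly; this is the package's central
#' self-consistency oracle.
#'
#' In `"log_abundance"` space every measured value (basal condition
#' included) gets a multiplicative log-normal error with a biological
#' component shared within each (condition, biological replicate) pair —
#' each treatment well is an independent preparation — plus an independent
#' technical component. In `"response"` space the noise is added directly to
#' the per-replicate global response coefficients and basal measurements
#' stay exact, so the recomputed per-replicate `R` matrices are exactly
#' `R_true + noise`.
#'
#' @param truth An [mra_truth()].
#' @param design An [mra_design()] with matching module count (default: the
#'   canonical [truth_design()]).
#' @param seed Optional seed; identical seeds give byte-identical tables.
#' @return A measurement tibble (see [mra_measurements()]).
#' @export
simulate_dataset <- function(truth, design = truth_design(truth), seed = NULL) {
  stopifnot(inherits(truth, "mra_truth"))
  if (length(design$modules) != length(truth$modules)) {
    mra_abort("design and truth module counts differ",
              "mranet_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  mods <- design$modules
  n <- length(mods)
  # truth columns/rows follow its own module order; align by position
  R_true <- truth$R
  dimnames(R_true) <- list(mods, mods)
  basal <- setNames(unname(truth$basal), mods)
  conds <- c(design$basal, names(design$perturbations))
  noiseless <- cbind(
    basal,
    vapply(seq_len(n), function(k) invert_relative_change(R_true[, k], basal),
           numeric(n)))
  colnames(noiseless) <- conds

  rows <- list()
  for (i in seq_len(design$k_bio)) {
    if (truth$noise_space == "response") {
      bio_noise <- matrix(rnorm(n * n, 0, truth$sigma_bio), n, n)
      for (rr in seq_len(design$n_tech)) {
        Rrep <- R_true + bio_noise +
          matrix(rnorm(n * n, 0, truth$sigma_tech), n, n)
        # redraw the technical component of out-of-range cells so the
        # symmetric relative difference stays representable (only relevant
        # at large noise levels)
        if (truth$sigma_tech > 0) {
          for (tries in seq_len(100L)) {
            bad <- abs(Rrep) >= 2
            if (!any(bad)) break
            Rrep[bad] <- R_true[bad] + bio_noise[bad] +
              rnorm(sum(bad), 0, truth$sigma_tech)
          }
        }
        if (any(abs(Rrep) >= 2)) {
          mra_abort("response-space noise repeatedly left (-2, 2)",
                    "mranet_degenerate")
        }
        vals <- cbind(basal,
                      vapply(seq_len(n), function(k)
                        invert_relative_change(Rrep[, k], basal), numeric(n)))
        colnames(vals) <- conds
        rows[[length(rows) + 1L]] <- tibble::tibble(
          reporter = rep(unname(design$reporters[mods]), times = length(conds)),
          condition = rep(conds, each = n),
          bio_rep = i, tech_rep = rr,
          value = as.vector(vals))
      }
    } else {
      # one biological draw per (condition, module), shared across tech reps
      bio_noise <- matrix(rnorm(n * length(conds), 0, truth$sigma_bio),
                          n, length(conds))
      for (rr in seq_len(design$n_tech)) {
        tech_noise <- matrix(rnorm(n * length(conds), 0, truth$sigma_tech),
                             n, length(conds))
        vals <- noiseless * exp(bio_noise + tech_noise)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          reporter = rep(unname(design$reporters[mods]), times = length(conds)),
          condition = rep(conds, each = n),
          bio_rep = i, tech_rep = rr,
          value = as.vector(vals))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  check_measurements(out)
  out
}

#' Simulate a panel of appended genes
#'
#' Each synthetic gene is defined by a coefficient row over the core
#' modules: its noiseless response to elementary perturbation `q_k` is the
#' row dotted with the core modules' relative changes under `q_k` (column
#' `k` of the truth's `R`), exactly the unidirectional-MRA generative model.
#' Rows implying responses at magnitude 2 or beyond are rejected by name.
#'
#' @param truth An [mra_truth()].
#' @param gene_rows Optional tibble with `gene`, `basal_abundance` and one
#'   coefficient column per module; when absent, `n_genes` random rows are
#'   drawn (`U(-coef_max, coef_max)` coefficients).
#' @param n_genes Number of random genes when `gene_rows` is NULL.
#' @param coef_max Range of random coefficients.
#' @param sigma Optional response-space noise sd added per replicate; the
#'   default 0 returns noiseless responses.
#' @param k_bio,n_tech Replicate structure used when `sigma > 0` (noise has
#'   a shared biological and an independent technical component of sd
#'   `sigma` each in equal parts).
#' @param seed Optional seed.
#' @return A tibble with `gene`, `basal_abundance`, one (pooled) response
#'   column per module, and a `coef_<module>` column per module with the
#'   generating truth row.
#' @export
simulate_gene_panel <- function(truth, gene_rows = NULL, n_genes = 20,
                                coef_max = 0.8, sigma = 0, k_bio = 3L,
                                n_tech = 2L, seed = NULL) {
  stopifnot(inherits(truth, "mra_truth"))
  if (!is.null(seed)) set.seed(seed)
  mods <- truth$modules
  n <- length(mods)
  if (is.null(gene_rows)) {
    gene_rows <- tibble::tibble(
      gene = sprintf("gene%03d", seq_len(n_genes)),
      basal_abundance = runif(n_genes, 5, 50))
    coefs <- matrix(runif(n_genes * n, -coef_max, coef_max), n_genes, n)
    colnames(coefs) <- mods
    gene_rows <- dplyr::bind_cols(gene_rows, tibble::as_tibble(coefs))
  }
  miss <- setdiff(c("gene", "basal_abundance", mods), names(gene_rows))
  if (length(miss)) {
    mra_abort(paste0("`gene_rows` lacks column(s): ",
                     paste(miss, collapse = ", ")),
              "mranet_validation_error")
  }
  coefs <- as.matrix(gene_rows[, mods, drop = FALSE])
  resp <- coefs %*% truth$R        # gene x perturbation noiseless responses
  bad <- which(apply(abs(resp) >= 2, 1, any))
  if (length(bad)) {
    mra_abort(
      paste0("gene row(s) imply responses outside (-2, 2): ",
             paste(gene_rows$gene[bad], collapse = ", ")),
      "mranet_domain_error")
  }
  if (sigma > 0) {
    reps <- array(0, dim = c(nrow(resp), n, k_bio * n_tech))
    q <- 0L
    s_comp <- sigma / sqrt(2)
    for (i in seq_len(k_bio)) {
      bio <- matrix(rnorm(length(resp), 0, s_comp), nrow(resp), n)
      for (rr in seq_len(n_tech)) {
        q <- q + 1L
        reps[, , q] <- resp + bio +
          matrix(rnorm(length(resp), 0, s_comp), nrow(resp), n)
      }
    }
    resp <- apply(reps, c(1, 2), mean)
    resp <- pmin(pmax(resp, -1.999), 1.999)
  }
  colnames(resp) <- mods
  out <- tibble::tibble(gene = gene_rows$gene,
                        basal_abundance = gene_rows$basal_abundance)
  out <- dplyr::bind_cols(out, tibble::as_tibble(resp))
  truth_cols <- tibble::as_tibble(coefs)
  names(truth_cols) <- paste0("coef_", mods)
  dplyr::bind_cols(out, truth_cols)
}

#' Compare an inferred network (and optional CIs) with the ground truth
#'
#' @param truth An [mra_truth()].
#' @param net The inferred `mra_network`.
#' @param ci Optional `mra_ci` from [bootstrap_network()].
#' @return A list of class `mra_recovery`: `errors` (tibble with max/mean
#'   absolute error per parameter class) and, when `ci` is given, `coverage`
#'   (per-parameter truth-in-interval indicators).
#' @export
recovery_report <- function(truth, net, ci = NULL) {
  stopifnot(inherits(truth, "mra_truth"), inherits(net, "mra_network"))
  if (length(truth$modules) != length(net$modules)) {
    mra_abort("truth and network dimensions differ", "mranet_validation_error")
  }
  off <- row(truth$r) != col(truth$r)
  err_r <- abs(net$r[off] - truth$r[off])
  err_P <- abs(unname(net$P) - unname(truth$P))
  errors <- tibble::tibble(
    class = c("connection", "magnitude"),
    max_abs_error = c(max(err_r), max(err_P)),
    mean_abs_error = c(mean(err_r), mean(err_P)))
  coverage <- NULL
  if (!is.null(ci)) {
    tab <- tidy(ci)
    mods <- net$modules
    true_val <- numeric(nrow(tab))
    for (q in seq_len(nrow(tab))) {
      i <- match(tab$to[q], mods); j <- match(tab$from[q], mods)
      true_val[q] <- if (tab$type[q] == "connection") truth$r[i, j]
                     else unname(truth$P)[i]
    }
    coverage <- tibble::tibble(
      parameter = tab$parameter, type = tab$type, truth = true_val,
      lower = tab$lower, upper = tab$upper,
      covered = tab$lower <= true_val & true_val <= tab$upper)
  }
  structure(list(errors = errors, coverage = coverage),
            class = "mra_recovery")
}

#' @export
print.mra_recovery <- function(x, ...) {
  cat("<mra_recovery>\n")
  print(x$errors)
  if (!is.null(x$coverage)) {
    cat("truth-in-CI: ", sum(x$coverage$covered), "/", nrow(x$coverage),
        "\n", sep = "")
  }
  invisible(x)
}

#' Fixture ground truths
#'
#' Small committed truths used throughout the test-suite and documentation:
#' a 3-module transcription-factor/two-corepressor motif with a strong
#' double-inhibition path, and a 4-module two-receptor crosstalk motif with
#' mixed-sign edges. All elementary perturbations are negative (ligand
#' removal / siRNA), so the perturbation magnitudes are negative. The
#' numeric values are qualitative fixtures, not estimates of any measured
#' system.
#'
#' @param ... Overrides passed to [mra_truth()] (noise settings).
#' @return An `mra_truth`.
#' @export
truth_corepressor3 <- function(...) {
  r <- rbind(
    c(-1.0, -0.8, -1.0),
    c(1.2, -1.0, 0.3),
    c(0.9, -0.4, -1.0))
  mra_truth(r, P = c(-1.1, -0.8, -0.9), basal = c(20, 8, 5),
            modules = c("TF", "coR1", "coR2"), ...)
}

#' @rdname truth_corepressor3
#' @export
truth_crosstalk4 <- function(...) {
  r <- rbind(
    c(-1.0, -0.5, -0.9, -0.7),
    c(-0.3, -1.0, -0.8, -0.5),
    c(1.0, 0.8, -1.0, -0.3),
    c(0.6, 0.3, -0.5, -1.0))
  mra_truth(r, P = c(-1.0, -0.9, -0.7, -0.8), basal = c(25, 15, 8, 5),
            modules = c("R1", "R2", "coR1", "coR2"), ...)
}
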