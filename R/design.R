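#' Describe a perturbation experiment
#'
#' An MRA experiment design names the network modules, the reporter measured
#' for each module, the basal (reference) condition, and the elementary
#' perturbation applied to each module. Every module must be the target of
#' exactly one perturbation condition and the basal condition must perturb
#' nothing; this is the elementary-perturbation assumption under which the
#' global response matrix is identifiable.
#'
#' @param modules Character vector of module identifiers, in the order used by
#'   all matrices and outputs (declaration order is preserved, never sorted).
#' @param perturbations Named character vector mapping condition identifier to
#'   the module it perturbs, e.g. `c("E2+siLCoR" = "LCoR")`.
#' @param basal Condition identifier of the unperturbed reference state.
#' @param reporters Optional named character vector mapping module to the
#'   reporter measured for it. Defaults to the module names themselves.
#' @param k_bio Number of biological replicates (independent preparations).
#' @param n_tech Number of technical replicates per biological replicate.
#'
#' @return An object of class `mra_design`.
#' @seealso [parse_condition_map()], [global_response()]
#' @examples
#' mra_design(
#'   modules = c("ER", "NRIP1", "LCoR"),
#'   perturbations = c("EtOH" = "ER", "E2+siNRIP1" = "NRIP1", "E2+siLCoR" = "LCoR"),
#'   basal = "E2"
#' )
#' @export
mra_design <- function(modules, perturbations, basal, reporters = NULL,
                       k_bio = 3L, n_tech = 2L) {
  modules <- as.character(modules)
  if (anyDuplicated(modules)) {
    mra_abort("duplicated module identifiers in `modules`",
              "mranet_validation_error")
  }
  if (length(modules) < 1L) {
    mra_abort("at least one module is required", "mranet_validation_error")
  }
  perturbations <- vapply(perturbations, as.character, character(1))
  if (is.null(names(perturbations)) || any(!nzchar(names(perturbations)))) {
    mra_abort("`perturbations` must be a named vector: condition -> module",
              "mranet_validation_error")
  }
  missing_mod <- setdiff(modules, perturbations)
  if (length(missing_mod)) {
    mra_abort(
      paste0("module(s) without an elementary perturbation: ",
             paste(missing_mod, collapse = ", ")),
      "mranet_validation_error")
  }
  dup <- perturbations[duplicated(perturbations)]
  if (length(dup)) {
    mra_abort(
      paste0("module(s) targeted by more than one condition: ",
             paste(unique(dup), collapse = ", ")),
      "mranet_validation_error")
  }
  unknown <- setdiff(perturbations, modules)
  if (length(unknown)) {
    mra_abort(
      paste0("perturbation targets not in `modules`: ",
             paste(unknown, collapse = ", ")),
      "mranet_validation_error")
  }
  basal <- as.character(basal)
  if (basal %in% names(perturbations)) {
    mra_abort("the basal condition must not perturb any module",
              "mranet_validation_error")
  }
  if (is.null(reporters)) {
    reporters <- setNames(modules, modules)
  } else {
    reporters <- vapply(reporters, as.character, character(1))
    if (!setequal(names(reporters), modules)) {
      mra_abort("`reporters` must be named by exactly the declared modules",
                "mranet_validation_error")
    }
    reporters <- reporters[modules]
  }
  k_bio <- as.integer(k_bio)
  n_tech <- as.integer(n_tech)
  if (is.na(k_bio) || k_bio < 1L || is.na(n_tech) || n_tech < 1L) {
    mra_abort("replicate counts must satisfy k_bio >= 1 and n_tech >= 1",
              "mranet_validation_error")
  }
  # keep perturbations in module order for reproducible iteration
  ord <- match(modules, perturbations)
  structure(
    list(
      modules = modules,
      reporters = reporters,
      basal = basal,
      perturbations = perturbations[ord],
      k_bio = k_bio,
      n_tech = n_tech
    ),
    class = "mra_design"
  )
}

#' @export
print.mra_design <- function(x, ...) {
  cat("<mra_design> ", length(x$modules), " modules, ",
      x$k_bio, " biological x ", x$n_tech, " technical replicates\n", sep = "")
  cat("  basal condition: ", x$basal, "\n", sep = "")
  for (cond in names(x$perturbations)) {
    cat("  ", cond, " -> ", x$perturbations[[cond]],
        " (reporter ", x$reporters[[x$perturbations[[cond]]]], ")\n", sep = "")
  }
  invisible(x)
}

#' @method tidy mra_design
#' @export
tidy.mra_design <- function(x, ...) {
  tibble::tibble(
    condition = c(x$basal, names(x$perturbations)),
    target = c("0", unname(x$perturbations))
  )
}

# condition identifier of the elementary perturbation of `module`
condition_for <- function(design, module) {
  names(design$perturbations)[match(module, design$perturbations)]
}

#' Parse a condition-to-module map
#'
#' Reads the compact `CONDITION -> MODULE` grammar used to declare which
#' experimental condition perturbs which network module. The basal condition
#' is declared with target `0` (e.g. `"E2+RA -> 0"`). Blank lines and lines
#' starting with `#` are ignored. The arrow accepts surrounding whitespace and
#' the typeset variant `- >`; `+` is an ordinary character inside condition
#' names, which are trimmed but otherwise kept verbatim.
#'
#' @param lines Character vector of map lines.
#' @return A tibble with columns `condition` and `target` (module id or `"0"`).
#' @examples
#' parse_condition_map(c("E2+RA -> 0", "E2+RA+siLCoR -> LCoR"))
#' @export
parse_condition_map <- function(lines) {
  lines <- as.character(lines)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  out <- vector("list", length(keep))
  for (idx in seq_along(keep)) {
    i <- keep[idx]
    parts <- strsplit(lines[i], "\\s*-\\s*>\\s*")[[1]]
    parts <- trimws(parts)
    if (length(parts) != 2L || any(!nzchar(parts))) {
      mra_abort(
        paste0("line ", i, ": expected 'CONDITION -> TARGET', got: ", lines[i]),
        "mranet_parse_error")
    }
    out[[idx]] <- tibble::tibble(condition = parts[1], target = parts[2])
  }
  map <- dplyr::bind_rows(out)
  if (nrow(map) == 0L) {
    mra_abort("empty condition map", "mranet_parse_error")
  }
  if (anyDuplicated(map$condition)) {
    mra_abort("duplicated condition identifiers in the map",
              "mranet_validation_error")
  }
  n_basal <- sum(map$target == "0")
  if (n_basal != 1L) {
    mra_abort(
      paste0("the map must declare exactly one basal condition ",
             "('CONDITION -> 0'); found ", n_basal),
      "mranet_validation_error")
  }
  tgt <- map$target[map$target != "0"]
  if (anyDuplicated(tgt)) {
    mra_abort(
      paste0("module(s) targeted by more than one condition: ",
             paste(unique(tgt[duplicated(tgt)]), collapse = ", ")),
      "mranet_validation_error")
  }
  map
}

#' @rdname parse_condition_map
#' @param path Path of a text file containing map lines.
#' @export
read_condition_map <- function(path) {
  parse_condition_map(readLines(path, warn = FALSE))
}

#' Build an experiment design from a condition map
#'
#' Modules are taken in the order their perturbation conditions appear in the
#' map.
#'
#' @param map A tibble as returned by [parse_condition_map()].
#' @inheritParams mra_design
#' @return An `mra_design`.
#' @export
design_from_map <- function(map, reporters = NULL, k_bio = 3L, n_tech = 2L) {
  pert <- map[map$target != "0", ]
  mra_design(
    modules = pert$target,
    perturbations = setNames(pert$target, pert$condition),
    basal = map$condition[map$target == "0"],
    reporters = reporters,
    k_bio = k_bio,
    n_tech = n_tech
  )
}
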