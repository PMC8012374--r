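#' Measurement tables
#'
#' Abundance measurements are kept in a long tibble with one row per observed
#' value and columns `reporter`, `condition`, `bio_rep`, `tech_rep`, `value`.
#' Values are strictly positive relative abundances (qPCR-derived quantities,
#' reporter readouts, or normalized counts); absolute quantitation is not
#' needed because all downstream quantities are relative changes.
#'
#' @param reporter,condition Character vectors.
#' @param bio_rep,tech_rep Integer replicate indices (1-based).
#' @param value Strictly positive numeric abundances.
#' @return A validated measurement tibble.
#' @export
mra_measurements <- function(reporter, condition, bio_rep, tech_rep, value) {
  out <- tibble::tibble(
    reporter = as.character(reporter),
    condition = as.character(condition),
    bio_rep = as.integer(bio_rep),
    tech_rep = as.integer(tech_rep),
    value = as.double(value)
  )
  check_measurements(out)
  out
}

check_measurements <- function(data) {
  req <- c("reporter", "condition", "bio_rep", "tech_rep", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    mra_abort(paste0("measurement table lacks column(s): ",
                     paste(miss, collapse = ", ")),
              "mranet_validation_error")
  }
  bad <- which(!is.finite(data$value) | data$value <= 0)
  if (length(bad)) {
    i <- bad[1]
    mra_abort(
      paste0("non-positive or non-finite abundance at (reporter=",
             data$reporter[i], ", condition=", data$condition[i],
             ", bio_rep=", data$bio_rep[i], ", tech_rep=", data$tech_rep[i],
             "): ", data$value[i],
             if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)") else ""),
      "mranet_domain_error")
  }
  key <- paste(data$reporter, data$condition, data$bio_rep, data$tech_rep,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    mra_abort(paste0("duplicated measurement key: ",
                     gsub("\r", " / ", d, fixed = TRUE)),
              "mranet_validation_error")
  }
  invisible(data)
}

#' Read and write measurement tables
#'
#' Two plain-text dialects are supported. `long` is a delimited file with the
#' five measurement columns. `wide` has one row per reporter and one column
#' per `condition.bio.tech` combination (the last two dot-separated tokens of
#' a column label are the replicate indices). Values are written with 17
#' significant digits so that write/read round-trips are bit-exact for
#' doubles.
#'
#' @param path File path.
#' @param dialect `"long"` or `"wide"`.
#' @param delim Field delimiter (default tab).
#' @return `read_measurements()` returns a measurement tibble;
#'   `write_measurements()` returns `path` invisibly.
#' @export
read_measurements <- function(path, dialect = c("long", "wide"), delim = "\t") {
  dialect <- match.arg(dialect)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (dialect == "long") {
    miss <- setdiff(c("reporter", "condition", "bio_rep", "tech_rep", "value"),
                    names(raw))
    if (length(miss)) {
      mra_abort(paste0("long measurement file lacks column(s): ",
                       paste(miss, collapse = ", ")),
                "mranet_parse_error")
    }
    val <- suppressWarnings(as.double(raw$value))
    if (anyNA(val)) {
      i <- which(is.na(val))[1]
      mra_abort(paste0("non-numeric value '", raw$value[i], "' at row ", i),
                "mranet_parse_error")
    }
    out <- mra_measurements(raw$reporter, raw$condition,
                            raw$bio_rep, raw$tech_rep, val)
  } else {
    if (names(raw)[1] != "reporter") {
      mra_abort("wide measurement file must start with a 'reporter' column",
                "mranet_parse_error")
    }
    long <- tidyr::pivot_longer(raw, -"reporter",
                                names_to = "label", values_to = "value")
    m <- regmatches(long$label,
                    regexec("^(.*)\\.([0-9]+)\\.([0-9]+)$", long$label))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) {
      mra_abort(paste0("wide column label not of the form condition.bio.tech: ",
                       long$label[which(bad)[1]]),
                "mranet_parse_error")
    }
    val <- suppressWarnings(as.double(long$value))
    if (anyNA(val)) {
      i <- which(is.na(val))[1]
      mra_abort(paste0("non-numeric value '", long$value[i],
                       "' for reporter ", long$reporter[i],
                       ", column ", long$label[i]),
                "mranet_parse_error")
    }
    out <- mra_measurements(
      reporter = long$reporter,
      condition = vapply(m, `[`, character(1), 2L),
      bio_rep = as.integer(vapply(m, `[`, character(1), 3L)),
      tech_rep = as.integer(vapply(m, `[`, character(1), 4L)),
      value = val
    )
  }
  out
}

#' @rdname read_measurements
#' @param data A measurement tibble.
#' @export
write_measurements <- function(data, path, dialect = c("long", "wide"),
                               delim = "\t") {
  dialect <- match.arg(dialect)
  check_measurements(data)
  fmt <- function(x) sprintf("%.17g", x)
  if (dialect == "long") {
    out <- dplyr::mutate(data, value = fmt(.data$value))
  } else {
    out <- data |>
      dplyr::mutate(label = paste(.data$condition, .data$bio_rep,
                                  .data$tech_rep, sep = "."),
                    value = fmt(.data$value)) |>
      dplyr::select("reporter", "label", "value") |>
      tidyr::pivot_wider(names_from = "label", values_from = "value")
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Check that measurements cover an experiment design
#'
#' Verifies that every (reporter, condition, biological replicate, technical
#' replicate) cell required by the design is present. Missing cells are
#' reported in the error.
#'
#' @param data A measurement tibble.
#' @param design An [mra_design()].
#' @return `data`, invisibly.
#' @export
validate_measurements <- function(data, design) {
  check_measurements(data)
  conditions <- c(design$basal, names(design$perturbations))
  grid <- tidyr::expand_grid(
    reporter = unname(design$reporters),
    condition = conditions,
    bio_rep = seq_len(design$k_bio),
    tech_rep = seq_len(design$n_tech)
  )
  have <- paste(data$reporter, data$condition, data$bio_rep, data$tech_rep,
                sep = "\r")
  want <- paste(grid$reporter, grid$condition, grid$bio_rep, grid$tech_rep,
                sep = "\r")
  miss <- grid[!(want %in% have), ]
  if (nrow(miss)) {
    shown <- utils::head(
      paste0("(", miss$reporter, ", ", miss$condition, ", bio ", miss$bio_rep,
             ", tech ", miss$tech_rep, ")"), 10L)
    mra_abort(
      paste0(nrow(miss), " missing measurement cell(s): ",
             paste(shown, collapse = "; "),
             if (nrow(miss) > 10) " ..." else ""),
      "mranet_missing_data",
      missing = miss)
  }
  invisible(data)
}
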