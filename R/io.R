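.measurement_cols <- c("indicator", "treatment", "value", "value_before",
                       "soil_total_hm", "metal")

parse_value_token <- function(tok, line, col) {
  tok <- trimws(tok)
  if (tok == "" || is.na(tok)) return(NA_real_)
  if (grepl("^>", tok)) {
    # censored reading such as ">3" (stability beyond the observation
    # window): parsed as just above the bound
    v <- suppressWarnings(as.numeric(sub("^>", "", tok)))
    if (is.na(v)) stop(sprintf("line %d: malformed numeric '%s' in %s",
                               line, tok, col), call. = FALSE)
    return(v + 1e-6)
  }
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) stop(sprintf("line %d: malformed numeric '%s' in %s",
                             line, tok, col), call. = FALSE)
  v
}

#' Read a measurement table
#'
#' CSV with header \code{indicator,treatment,value,value_before,
#' soil_total_hm,metal} (trailing columns optional, blank where not
#' applicable; comma separator, dot decimal, UTF-8). Values of the form
#' \code{">3"} (beyond the observation window) are parsed as just above the
#' bound. Each record is validated against the indicator registry: unknown
#' indicator names, duplicate (indicator, treatment) pairs, negative
#' concentrations and missing companion values (before-value for
#' reduction-rate indicators, soil total for BAF indicators) are rejected
#' with the offending line number.
#'
#' @param path CSV file path.
#' @param registry an \code{indicator_registry} used for validation.
#' @return data.frame with the measurement columns plus \code{value_raw}
#'   (the original value token, preserved for lossless re-serialization).
#' @export
read_measurements <- function(path, registry = default_registry()) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c("indicator", "treatment", "value"), names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(.measurement_cols, names(df))) df[[col]] <- ""
  if (nrow(df) == 0L) {
    warning("measurement file has no data rows", call. = FALSE)
    out <- data.frame(indicator = character(), treatment = character(),
                      value = numeric(), value_before = numeric(),
                      soil_total_hm = numeric(), metal = character(),
                      value_raw = character(), stringsAsFactors = FALSE)
    return(out)
  }

  line <- seq_len(nrow(df)) + 1L  # header is line 1
  unknown <- !df$indicator %in% names(registry)
  if (any(unknown)) {
    stop(sprintf("line %d: unknown indicator '%s'",
                 line[unknown][1L], df$indicator[unknown][1L]), call. = FALSE)
  }
  key <- paste(df$indicator, df$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("line %d: duplicate record for indicator '%s', treatment '%s'",
                 line[i], df$indicator[i], df$treatment[i]), call. = FALSE)
  }

  out <- data.frame(
    indicator = df$indicator, treatment = df$treatment,
    value = vapply(seq_len(nrow(df)), function(i)
      parse_value_token(df$value[i], line[i], "value"), numeric(1)),
    value_before = vapply(seq_len(nrow(df)), function(i)
      parse_value_token(df$value_before[i], line[i], "value_before"), numeric(1)),
    soil_total_hm = vapply(seq_len(nrow(df)), function(i)
      parse_value_token(df$soil_total_hm[i], line[i], "soil_total_hm"), numeric(1)),
    metal = df$metal, value_raw = trimws(df$value),
    stringsAsFactors = FALSE
  )

  for (i in seq_len(nrow(out))) {
    d <- registry[[out$indicator[i]]]
    if (is.na(out$value[i]) || out$value[i] < 0) {
      stop(sprintf("line %d: value must be a nonnegative number", line[i]),
           call. = FALSE)
    }
    if (d$transform == "reduction_rate" &&
        (is.na(out$value_before[i]) || out$value_before[i] <= 0)) {
      stop(sprintf("line %d: indicator '%s' needs value_before > 0",
                   line[i], d$name), call. = FALSE)
    }
    if (d$transform == "baf" &&
        (is.na(out$soil_total_hm[i]) || out$soil_total_hm[i] <= 0)) {
      stop(sprintf("line %d: indicator '%s' needs soil_total_hm > 0",
                   line[i], d$name), call. = FALSE)
    }
  }
  out
}

#' Write a measurement table
#'
#' Serializes a measurement data.frame back to the documented CSV layout,
#' using the preserved raw value tokens when present so that a read/write
#' cycle is byte-identical.
#'
#' @param measurements measurement data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v) || (is.character(v) && v == "")) "" else as.character(v)
    }, character(1))
    out
  }
  value <- if ("value_raw" %in% names(measurements)) {
    measurements$value_raw
  } else {
    fmt(measurements$value)
  }
  lines <- c(
    "indicator,treatment,value,value_before,soil_total_hm,metal",
    paste(measurements$indicator, measurements$treatment, value,
          fmt(measurements$value_before), fmt(measurements$soil_total_hm),
          fmt(measurements$metal), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write an evaluation report
#'
#' Emits a machine-readable JSON report (full precision, stable key order)
#' and optionally a Markdown summary with display rounding (scores to 2
#' decimals, composite scores to 3). The report echoes the per-indicator
#' scores, composite score, grade, compliance flags, missing-indicator
#' warnings and verdicts.
#'
#' @param ev a \code{stab_evaluation} from [evaluate_stabilization()].
#' @param path output JSON path.
#' @param md_path optional output Markdown path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(ev, path, md_path = NULL) {
  stopifnot(inherits(ev, "stab_evaluation"))
  trt <- lapply(ev$treatments, function(t) {
    list(si = t$si, grade = t$grade,
         missing = as.list(t$missing),
         noncompliant = as.list(t$noncompliant))
  })
  verd <- lapply(ev$verdicts, function(v) {
    list(grade_before = v$grade_before, grade_after = v$grade_after,
         step = v$step, verdict = v$verdict)
  })
  payload <- list(
    before = ev$before,
    after = as.list(ev$after),
    scores = ev$scores[, c("indicator", "treatment", "value", "transformed",
                           "score", "group", "curve")],
    treatments = trt,
    verdicts = verd
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  if (!is.null(md_path)) {
    lines <- c("# Stabilization-effect evaluation", "",
               sprintf("Before-state: `%s`", ev$before), "",
               "| treatment | Si | grade | non-compliant |",
               "|---|---|---|---|")
    for (tr in names(ev$treatments)) {
      t <- ev$treatments[[tr]]
      lines <- c(lines, sprintf(
        "| %s | %.3f | %s | %s |", tr, round_half_up(t$si, 3), t$grade,
        if (length(t$noncompliant) > 0L)
          paste(t$noncompliant, collapse = ", ") else "-"))
    }
    lines <- c(lines, "", "| comparison | step | verdict |", "|---|---|---|")
    for (tr in names(ev$verdicts)) {
      v <- ev$verdicts[[tr]]
      lines <- c(lines, sprintf("| %s vs %s | %+d | %s |",
                                tr, ev$before, v$step, v$verdict))
    }
    writeLines(lines, md_path)
  }
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path JSON file written by [write_report()].
#' @return nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Locate a packaged fixture by name
#'
#' @param name one of \code{"hierarchy"} (the expert-derived weight tree),
#'   \code{"registry"} (the 16-indicator registry) or
#'   \code{"measurements"} (the pot-experiment table).
#' @return file path inside the installed package.
#' @export
stabeval_fixture <- function(name = c("hierarchy", "registry", "measurements")) {
  name <- match.arg(name)
  file <- switch(name,
                 hierarchy = "hierarchy_weights.json",
                 registry = "indicator_registry.json",
                 measurements = "pot_experiment_measurements.csv")
  system.file("extdata", file, package = "stabeval", mustWork = TRUE)
}
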