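#' S-type standardized scoring function
#'
#' Piecewise-linear non-decreasing membership: 0 below \code{L}, a linear
#' ramp \code{(x - L) / (H - L)} on \code{[L, H]}, and 1 above \code{H}.
#' Used for indicators where more is better up to a saturation value
#' (SOM, CEC, available N/P/K, production, biomass, stability, and the
#' available-heavy-metal reduction rate).
#'
#' @param x indicator value(s), in the indicator's units.
#' @param L lower threshold (score 0 at and below); defaults to 0.
#' @param H upper threshold (score 1 at and above).
#' @return score(s) in [0, 1].
#' @examples
#' score_s_type(18.21, L = 6, H = 40)  # 0.359...
#' @export
score_s_type <- function(x, L = 0, H) {
  if (L >= H) stop("thresholds must satisfy L < H", call. = FALSE)
  pmin(1, pmax(0, (x - L) / (H - L)))
}

#' Inverse-S standardized scoring function
#'
#' Piecewise-linear non-increasing membership: 1 below \code{L}, a falling
#' ramp \code{(H - x) / (H - L)} on \code{[L, H]}, and 0 above \code{H}.
#' Used where less is better (heavy-metal concentrations, bio-accumulation
#' factors, cost).
#'
#' @inheritParams score_s_type
#' @return score(s) in [0, 1].
#' @examples
#' score_inverse_s(46, L = 10, H = 100)  # 0.6
#' @export
score_inverse_s <- function(x, L = 0, H) {
  if (L >= H) stop("thresholds must satisfy L < H", call. = FALSE)
  pmin(1, pmax(0, (H - x) / (H - L)))
}

#' Parabolic (midpoint-type) standardized scoring function
#'
#' Trapezoidal membership: 0 outside \code{[L1, H1]}, rising limb
#' \code{(x - L1) / (L - L1)} on \code{[L1, L)}, plateau 1 on
#' \code{[L, H]}, falling limb \code{(H1 - x) / (H1 - H)} on
#' \code{(H, H1]}. Continuous and unimodal. Used for pH, where both low and
#' high values harm soil health.
#'
#' @param x indicator value(s).
#' @param L1,L,H,H1 thresholds, strictly increasing: score 0 at \code{L1}
#'   and \code{H1}, score 1 on the plateau \code{[L, H]}.
#' @return score(s) in [0, 1].
#' @examples
#' score_parabolic(7.27, 3, 5, 7, 9)  # 0.865
#' @export
score_parabolic <- function(x, L1, L, H, H1) {
  if (!(L1 < L && L < H && H < H1)) {
    stop("thresholds must satisfy L1 < L < H < H1", call. = FALSE)
  }
  up <- (x - L1) / (L - L1)
  down <- (H1 - x) / (H1 - H)
  pmin(1, pmax(0, pmin(up, down)))
}

#' Round half away from zero
#'
#' Decimal display rounding with ties going up in magnitude (0.945 -> 0.95
#' at 2 digits), as used for the published score tables; base \code{round()}
#' rounds half to even. A small guard absorbs binary floating-point
#' representation error in values intended as exact decimals.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Score one measurement against its indicator definition
#'
#' Applies the indicator's transform (raw value, available-heavy-metal
#' reduction rate, bio-accumulation factor, or ratio to a local reference)
#' and then its response curve with the registry thresholds. A negative
#' reduction rate (the available metal increased) scores 0 with a warning.
#' Group-I indicators with a configured \code{standard_limit} additionally
#' report a compliance flag (\code{value <= limit}); compliance never alters
#' the score.
#'
#' @param def an indicator definition from the registry.
#' @param m a one-row measurement: list or data.frame row with
#'   \code{indicator}, \code{treatment}, \code{value} and, as required by
#'   the transform, \code{value_before} (reduction rate) or
#'   \code{soil_total_hm} (BAF).
#' @return list with \code{indicator}, \code{treatment}, \code{value},
#'   \code{transformed}, \code{score}, \code{curve}, \code{group},
#'   \code{compliant} (NA when no limit is configured).
#' @export
score_indicator <- function(def, m) {
  def <- validate_indicator(def)
  value <- as.numeric(m$value)
  transformed <- switch(
    def$transform,
    raw = value,
    reduction_rate = {
      xb <- suppressWarnings(as.numeric(m$value_before %||% NA))
      if (is.na(xb) || xb <= 0) stop(sprintf(
        "indicator '%s': reduction rate needs value_before > 0", def$name),
        call. = FALSE)
      reduction_rate(xb, value)
    },
    baf = {
      soil <- suppressWarnings(as.numeric(m$soil_total_hm %||% NA))
      if (is.na(soil) || soil <= 0) stop(sprintf(
        "indicator '%s': BAF needs soil_total_hm > 0", def$name),
        call. = FALSE)
      baf(value, soil)
    },
    ratio_to_reference = {
      ref <- def$reference_value
      if (is.null(ref) || is.na(ref) || ref <= 0) stop(sprintf(
        "indicator '%s': ratio transform needs a positive reference_value in the registry",
        def$name), call. = FALSE)
      ratio_indicator(value, ref)
    }
  )
  th <- def$thresholds
  x <- if (def$transform == "reduction_rate") max(0, transformed) else transformed
  score <- switch(
    def$curve,
    s_type = score_s_type(x, th$L %||% 0, th$H),
    inverse_s = score_inverse_s(x, th$L %||% 0, th$H),
    parabolic = score_parabolic(x, th$L1, th$L, th$H, th$H1)
  )
  compliant <- NA
  if (!is.null(def$standard_limit)) compliant <- value <= def$standard_limit
  list(indicator = def$name, treatment = m$treatment %||% NA_character_,
       value = value, transformed = transformed, score = score,
       curve = def$curve, group = def$group, compliant = compliant)
}

#' Score a table of measurements
#'
#' Dispatches every measurement row through [score_indicator()] using its
#' registry definition.
#'
#' @param measurements data.frame as returned by [read_measurements()] or
#'   [make_study()]: columns \code{indicator}, \code{treatment},
#'   \code{value}, and optionally \code{value_before},
#'   \code{soil_total_hm}, \code{metal}.
#' @param registry an \code{indicator_registry}.
#' @return data.frame with one row per measurement: \code{indicator},
#'   \code{treatment}, \code{value}, \code{transformed}, \code{score},
#'   \code{curve}, \code{group}, \code{compliant}.
#' @examples
#' scores <- score_measurements(pot_experiment())
#' subset(scores, treatment == "HAP")
#' @export
score_measurements <- function(measurements, registry = default_registry()) {
  stopifnot(is.data.frame(measurements))
  unknown <- setdiff(unique(measurements$indicator), names(registry))
  if (length(unknown) > 0L) {
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    m <- as.list(measurements[i, , drop = FALSE])
    as.data.frame(score_indicator(registry[[m$indicator]], m),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
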