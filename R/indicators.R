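#' Bio-accumulation factor (BAF)
#'
#' Ratio of the heavy-metal concentration in a crop tissue to the
#' concentration in the soil, expressed as a percentage:
#' \code{100 * crop / soil}. Quantifies how strongly the plant takes up the
#' metal, and hence how well a stabilization treatment suppresses uptake.
#'
#' @param crop_hm tissue concentration, mg/kg (>= 0).
#' @param soil_hm soil concentration, mg/kg (> 0).
#' @return BAF in percent.
#' @examples
#' baf(2.30, 5.0)  # 46
#' @export
baf <- function(crop_hm, soil_hm) {
  if (any(soil_hm <= 0)) stop("soil concentration must be > 0", call. = FALSE)
  if (any(crop_hm < 0)) stop("crop concentration must be >= 0", call. = FALSE)
  100 * crop_hm / soil_hm
}

#' Classify a bio-accumulation factor
#'
#' Four uptake classes: very weak (BAF <= 1\%), weak (1--10\%], moderate
#' (10--100\%], strong (> 100\%). Upper-closed intervals.
#'
#' @param x BAF percentage(s), >= 0.
#' @return character vector in
#'   \code{c("very_weak", "weak", "moderate", "strong")}.
#' @export
baf_class <- function(x) {
  if (any(x < 0)) stop("BAF must be nonnegative", call. = FALSE)
  out <- character(length(x))
  out[x <= 1] <- "very_weak"
  out[x > 1 & x <= 10] <- "weak"
  out[x > 10 & x <= 100] <- "moderate"
  out[x > 100] <- "strong"
  out
}

#' Reduction rate of available heavy metal
#'
#' Fractional decrease of the available (bioavailable) heavy-metal
#' concentration from before to after treatment,
#' \code{100 * (before - after) / before} percent. A negative rate (the
#' available fraction increased) is returned with a warning; downstream
#' scoring treats it as 0.
#'
#' @param xb concentration before stabilization, mg/kg (> 0).
#' @param xa concentration after stabilization, mg/kg (>= 0).
#' @return reduction rate in percent.
#' @examples
#' reduction_rate(2.85, 2.14)  # 24.9 (to 1 d.p.)
#' @export
reduction_rate <- function(xb, xa) {
  if (any(xb <= 0)) stop("before-value must be > 0", call. = FALSE)
  if (any(xa < 0)) stop("after-value must be >= 0", call. = FALSE)
  r <- 100 * (xb - xa) / xb
  if (any(r < 0)) {
    warning("available heavy metal increased after treatment (negative reduction rate)",
            call. = FALSE)
  }
  r
}

#' Grade a reduction rate
#'
#' Equidistant four-grade scale on [0, 100]\%: poor [0, 25), medium
#' [25, 50), good [50, 75), excellent [75, 100]. Lower-closed intervals.
#'
#' @param alpha reduction rate(s) in percent, within [0, 100].
#' @return character vector in \code{c("poor", "medium", "good", "excellent")}.
#' @export
alpha_grade <- function(alpha) {
  if (any(alpha < 0 | alpha > 100)) {
    stop("reduction rate must lie in [0, 100] percent", call. = FALSE)
  }
  out <- character(length(alpha))
  out[alpha < 25] <- "poor"
  out[alpha >= 25 & alpha < 50] <- "medium"
  out[alpha >= 50 & alpha < 75] <- "good"
  out[alpha >= 75] <- "excellent"
  out
}

#' Ratio of a measurement to its local reference
#'
#' Production, biomass and cost enter the evaluation as ratios:
#' production = actual / average local production, biomass = crop weight /
#' average local crop weight, cost = cost / crop revenue. The reference is a
#' mandatory configuration input, never estimated from the data.
#'
#' @param actual measured value (>= 0).
#' @param reference reference value (> 0).
#' @return the ratio \code{actual / reference}.
#' @export
ratio_indicator <- function(actual, reference) {
  if (any(reference <= 0)) stop("reference value must be > 0", call. = FALSE)
  actual / reference
}

# ---- indicator registry -----------------------------------------------------

.registry_transforms <- c("raw", "reduction_rate", "baf", "ratio_to_reference")
.registry_curves <- c("s_type", "inverse_s", "parabolic")

validate_indicator <- function(d) {
  for (f in c("name", "group", "transform", "curve")) {
    if (is.null(d[[f]])) stop(sprintf("indicator missing field '%s'", f),
                              call. = FALSE)
  }
  if (!d$group %in% c("I", "II", "III")) {
    stop(sprintf("indicator '%s': group must be I, II or III", d$name),
         call. = FALSE)
  }
  if (!d$transform %in% .registry_transforms) {
    stop(sprintf("indicator '%s': unknown transform '%s'", d$name, d$transform),
         call. = FALSE)
  }
  if (!d$curve %in% .registry_curves) {
    stop(sprintf("indicator '%s': unknown curve '%s'", d$name, d$curve),
         call. = FALSE)
  }
  th <- d$thresholds
  if (d$curve == "parabolic") {
    need <- c("L1", "L", "H", "H1")
    if (!all(need %in% names(th))) stop(sprintf(
      "indicator '%s': parabolic curve needs thresholds L1, L, H, H1", d$name),
      call. = FALSE)
    v <- unlist(th[need])
    if (any(diff(v) <= 0)) stop(sprintf(
      "indicator '%s': thresholds must satisfy L1 < L < H < H1", d$name),
      call. = FALSE)
  } else {
    if (is.null(th$H)) stop(sprintf(
      "indicator '%s': curve needs threshold H", d$name), call. = FALSE)
    if (is.null(th$L)) d$thresholds$L <- 0
    if (d$thresholds$L >= th$H) stop(sprintf(
      "indicator '%s': thresholds must satisfy L < H", d$name), call. = FALSE)
  }
  if (d$transform == "ratio_to_reference" &&
      !is.null(d$reference_value) && d$reference_value <= 0) {
    stop(sprintf("indicator '%s': reference_value must be > 0", d$name),
         call. = FALSE)
  }
  d
}

#' Load an indicator registry
#'
#' The registry defines, for each indicator, its evaluation group (I:
#' governed by a national standard; II: gradable under farmland
#' classification management; III: dynamic, no external criterion), the
#' transform applied to the raw measurement (\code{raw},
#' \code{reduction_rate}, \code{baf}, \code{ratio_to_reference}), the
#' response curve (\code{s_type}, \code{inverse_s}, \code{parabolic}) and
#' its thresholds, plus optional \code{reference_value} (ratio indicators)
#' and \code{standard_limit} (group-I compliance checks). User entries merge
#' over the packaged defaults by indicator name.
#'
#' @param path optional JSON or YAML registry file with entries to override
#'   or extend the defaults.
#' @param base registry to merge into; defaults to the packaged registry.
#' @return named list of indicator definitions,
#'   class \code{"indicator_registry"}.
#' @export
read_registry <- function(path = NULL, base = default_registry()) {
  reg <- base
  if (!is.null(path)) {
    entries <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    }
    if (!is.null(entries$indicators)) entries <- entries$indicators
    for (d in entries) {
      d <- validate_indicator(modifyList(reg[[d$name]] %||% list(), d))
      reg[[d$name]] <- d
    }
  }
  class(reg) <- "indicator_registry"
  reg
}

#' The packaged 16-indicator registry
#'
#' Soil: pH, SOM, CEC, A-N, A-P, A-K, AHM, THM; crop: biomass, production,
#' heavy metal in edible/above-ground/root parts; amendment: cost,
#' amendment heavy metal, stability. Thresholds follow the farmland
#' classification-management grades; heavy-metal thresholds default to
#' cadmium limits and can be reconfigured per metal via [read_registry()].
#'
#' @return an \code{indicator_registry}.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "indicator_registry.json",
                      package = "stabeval", mustWork = TRUE)
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  reg <- list()
  for (d in entries) reg[[d$name]] <- validate_indicator(d)
  class(reg) <- "indicator_registry"
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
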