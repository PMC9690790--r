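#' Composite weighted score
#'
#' The comprehensive score of one treatment is the weighted sum
#' \eqn{S_i = \sum_i \omega_i X_i} of its normalized indicator scores, with
#' \eqn{\omega_i} the comprehensive indicator weights. Indicators that carry
#' a weight but were not measured contribute 0 and are listed as missing;
#' by default the weights are \emph{not} renormalized over the measured
#' subset, so an incompletely measured treatment is scored against the full
#' system (this is the published convention). Set \code{renormalize = TRUE}
#' to rescale instead.
#'
#' @param scores named numeric vector of indicator scores in [0, 1].
#' @param weights named numeric vector of comprehensive weights covering at
#'   least every scored indicator.
#' @param renormalize divide by the total weight of the scored indicators.
#' @return list with \code{si}, \code{missing} (weighted indicators without
#'   a score) and \code{weight_used} (total weight of scored indicators).
#' @examples
#' composite_score(c(pH = 1, SOM = 0.5), c(pH = 0.6, SOM = 0.4))
#' @export
composite_score <- function(scores, weights, renormalize = FALSE) {
  if (is.null(names(scores)) || is.null(names(weights))) {
    stop("scores and weights must be named by indicator", call. = FALSE)
  }
  orphan <- setdiff(names(scores), names(weights))
  if (length(orphan) > 0L) {
    stop("scored indicator(s) without a weight: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  missing <- setdiff(names(weights), names(scores))
  si <- sum(weights[names(scores)] * scores)
  wu <- sum(weights[names(scores)])
  if (renormalize) si <- si / wu
  list(si = si, missing = missing, weight_used = wu)
}

.grades <- c("I", "II", "III", "IV", "V")

#' Grade a composite score
#'
#' Equidistant five-grade scale on the composite score: I (0.8, 1],
#' II (0.6, 0.8], III (0.4, 0.6], IV (0.2, 0.4], V [0, 0.2]. Grade I is
#' best. A score of exactly 0 is grade V.
#'
#' @param si composite score(s) in [0, 1].
#' @return character grade(s) among \code{"I".."V"}.
#' @examples
#' si_grade(c(0.165, 0.371, 0.471))  # "V" "IV" "III"
#' @export
si_grade <- function(si) {
  if (any(si < 0 | si > 1)) stop("composite score must lie in [0, 1]",
                                 call. = FALSE)
  idx <- 5L - findInterval(si, c(0.2, 0.4, 0.6, 0.8), left.open = FALSE)
  # findInterval with left.open=FALSE counts x >= cut; bins here are
  # lower-open/upper-closed, so move exact cut points down a grade.
  at_cut <- si %in% c(0.2, 0.4, 0.6, 0.8)
  idx[at_cut] <- idx[at_cut] + 1L
  .grades[idx]
}

#' Before/after stabilization verdict
#'
#' Compares the soil-quality grade before and after remediation. The grade
#' step is \code{S = index(before) - index(after)} with I = 1 (best) to
#' V = 5, so a positive step means the grade improved. Verdicts: S > 1
#' excellent, S = 1 good, S = 0 qualified, S = -1 poor, S < -1 very poor.
#'
#' @param grade_before,grade_after grades \code{"I".."V"} from [si_grade()].
#' @return object of class \code{"stab_verdict"}: list with
#'   \code{grade_before}, \code{grade_after}, \code{step} and
#'   \code{verdict}.
#' @examples
#' stabilization_verdict("V", "III")  # step 2, excellent
#' @export
stabilization_verdict <- function(grade_before, grade_after) {
  ib <- match(grade_before, .grades)
  ia <- match(grade_after, .grades)
  if (is.na(ib) || is.na(ia)) stop("grades must be one of I..V", call. = FALSE)
  s <- ib - ia
  verdict <- if (s > 1) "excellent" else if (s == 1) "good" else
    if (s == 0) "qualified" else if (s == -1) "poor" else "very_poor"
  structure(list(grade_before = grade_before, grade_after = grade_after,
                 step = s, verdict = verdict),
            class = "stab_verdict")
}

#' @export
print.stab_verdict <- function(x, ...) {
  cat(sprintf("Stabilization verdict: %s (grade %s -> %s, step %+d)\n",
              x$verdict, x$grade_before, x$grade_after, x$step))
  invisible(x)
}

#' Evaluate stabilization treatments end to end
#'
#' Scores every measurement, forms the composite score and grade per
#' treatment, and issues a verdict for each treated condition against the
#' untreated (before) condition. Group-I compliance failures are surfaced
#' as flags, never folded into the score.
#'
#' @param measurements measurement table (see [read_measurements()]).
#' @param before treatment label of the pre-stabilization (control) state.
#' @param after character vector of treated conditions; defaults to all
#'   other treatments in the table.
#' @param registry an \code{indicator_registry}.
#' @param weights named comprehensive weights; defaults to the packaged
#'   expert-derived weights as published ([default_weights()]).
#' @param renormalize_missing passed to [composite_score()].
#' @return object of class \code{"stab_evaluation"}: list with
#'   \code{scores} (per-measurement data.frame), \code{treatments} (per
#'   treatment: \code{si}, \code{grade}, \code{missing},
#'   \code{noncompliant}), and \code{verdicts} (one \code{stab_verdict}
#'   per after-treatment).
#' @examples
#' ev <- evaluate_stabilization(pot_experiment(), before = "control")
#' ev$treatments$HAP$si
#' ev$verdicts$HAP$verdict
#' @export
evaluate_stabilization <- function(measurements, before,
                                   after = NULL,
                                   registry = default_registry(),
                                   weights = default_weights(),
                                   renormalize_missing = FALSE) {
  scored <- score_measurements(measurements, registry)
  trts <- unique(scored$treatment)
  if (!before %in% trts) {
    stop(sprintf("before-treatment '%s' not present in the data", before),
         call. = FALSE)
  }
  if (is.null(after)) after <- setdiff(trts, before)

  per_trt <- lapply(stats::setNames(trts, trts), function(tr) {
    sub <- scored[scored$treatment == tr, , drop = FALSE]
    s <- stats::setNames(sub$score, sub$indicator)
    cs <- composite_score(s, weights, renormalize = renormalize_missing)
    noncompliant <- sub$indicator[!is.na(sub$compliant) & !sub$compliant]
    list(si = cs$si, grade = si_grade(min(1, cs$si)), missing = cs$missing,
         weight_used = cs$weight_used, noncompliant = noncompliant)
  })

  verdicts <- lapply(stats::setNames(after, after), function(tr) {
    stabilization_verdict(per_trt[[before]]$grade, per_trt[[tr]]$grade)
  })

  structure(list(scores = scored, treatments = per_trt,
                 before = before, after = after, verdicts = verdicts),
            class = "stab_evaluation")
}

#' @export
print.stab_evaluation <- function(x, ...) {
  cat("Stabilization-effect evaluation\n")
  for (tr in names(x$treatments)) {
    t <- x$treatments[[tr]]
    cat(sprintf("  %-10s Si = %.3f  grade %-3s", tr, t$si, t$grade))
    if (length(t$noncompliant) > 0L) {
      cat("  [non-compliant: ", paste(t$noncompliant, collapse = ", "), "]",
          sep = "")
    }
    cat("\n")
  }
  for (tr in names(x$verdicts)) {
    v <- x$verdicts[[tr]]
    cat(sprintf("  %s vs %s: %s (grade %s -> %s)\n", tr, x$before,
                v$verdict, v$grade_before, v$grade_after))
  }
  invisible(x)
}
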