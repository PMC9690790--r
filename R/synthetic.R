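# Run code under a temporary RNG state; NULL seed leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a consistent-up-to-noise judgment matrix
#'
#' Builds the matrix an expert holding true weights \code{w} would state:
#' upper-triangle entries \code{b_ij = (w_i / w_j) * exp(eps_ij)} with
#' independent Gaussian noise \code{eps_ij} on the log-ratio scale (the
#' minimal perturbation model that keeps entries positive), optionally
#' snapped to the nearest Saaty scale value in log space. The lower triangle
#' is set to the exact reciprocal of the upper triangle after rounding, so
#' reciprocity always holds exactly.
#'
#' With \code{noise = 0} and no rounding the matrix is perfectly consistent
#' and [priority_vector()] recovers \code{w} exactly.
#'
#' @param w positive ground-truth weights summing to 1.
#' @param noise standard deviation of the log-ratio perturbation (>= 0).
#' @param saaty_round snap entries to the Saaty 1--9 scale (as a
#'   questionnaire form would force).
#' @param seed optional integer; fixes the output without disturbing the
#'   caller's RNG stream.
#' @return a \code{judgment_matrix}.
#' @examples
#' m <- make_consistent_matrix(c(0.6, 0.3, 0.1), noise = 0)
#' priority_vector(m)
#' @export
make_consistent_matrix <- function(w, noise = 0, saaty_round = FALSE,
                                   seed = NULL) {
  stopifnot(all(w > 0), abs(sum(w) - 1) < 1e-6, noise >= 0)
  n <- length(w)
  with_seed(seed, {
    m <- matrix(1, n, n)
    log_saaty <- log(saaty_scale())
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        b <- (w[i] / w[j]) * exp(stats::rnorm(1, 0, noise))
        if (saaty_round) {
          b <- saaty_scale()[which.min(abs(log(b) - log_saaty))]
        }
        m[i, j] <- b
        m[j, i] <- 1 / b
      }
    }
    judgment_matrix(m, labels = names(w), strict = saaty_round)
  })
}

#' Simulate an expert panel
#'
#' Draws \code{n_experts} independent judgment matrices around a shared
#' ground truth with [make_consistent_matrix()]. Deterministic under
#' \code{seed}: the same seed yields an identical panel.
#'
#' @inheritParams make_consistent_matrix
#' @param n_experts panel size.
#' @return list of \code{judgment_matrix} objects.
#' @examples
#' panel <- make_panel(c(0.5, 0.3, 0.2), n_experts = 5, noise = 0.1, seed = 1)
#' aggregate_experts(panel)$weights
#' @export
make_panel <- function(w, n_experts, noise = 0, saaty_round = FALSE,
                       seed = NULL) {
  stopifnot(n_experts >= 1)
  with_seed(seed, {
    lapply(seq_len(n_experts), function(i) {
      make_consistent_matrix(w, noise = noise, saaty_round = saaty_round)
    })
  })
}

#' Generate a synthetic measurement study
#'
#' Starts from a truth table in measurement format and applies independent
#' multiplicative log-normal noise to the measured values (emulating
#' analytical replicate scatter), leaving paired before-values and soil
#' totals at their design settings so that every generated row still
#' satisfies the measurement invariants. With \code{noise = 0} the truth
#' table is returned unchanged, so a truth table set to the packaged pot
#' experiment reproduces the packaged fixture exactly.
#'
#' @param truth data.frame in measurement format (columns \code{indicator},
#'   \code{treatment}, \code{value}, optional \code{value_before},
#'   \code{soil_total_hm}, \code{metal}); see [pot_experiment()] for the
#'   packaged design.
#' @param noise standard deviation of the log-normal multiplicative noise
#'   on \code{value} (>= 0).
#' @param seed optional integer seed.
#' @return measurement data.frame.
#' @examples
#' head(make_study(pot_experiment(), noise = 0.05, seed = 7))
#' @export
make_study <- function(truth, noise = 0, seed = NULL) {
  stopifnot(is.data.frame(truth), noise >= 0,
            all(c("indicator", "treatment", "value") %in% names(truth)))
  if (any(truth$value < 0, na.rm = TRUE)) {
    stop("truth values must be nonnegative", call. = FALSE)
  }
  with_seed(seed, {
    out <- truth
    if (noise > 0) {
      out$value <- out$value * exp(stats::rnorm(nrow(out), 0, noise))
    }
    out
  })
}

#' The packaged pot-experiment measurement table
#'
#' Measured indicator values for a ryegrass pot experiment on soil spiked
#' with 5 mg/kg Cd: an untreated control and two amendments, 1\% reed
#' biochar (RBC) and 1\% hydroxyapatite (HAP), sampled after 70 days.
#' Available-heavy-metal rows carry the control concentration as the paired
#' before-value; crop heavy-metal rows carry the 5 mg/kg spike as the soil
#' total for the bio-accumulation factor. The control column has 10
#' measured indicators (amendment heavy metal and stability do not apply to
#' an untreated pot); each amendment has 12.
#'
#' @return measurement data.frame (34 rows).
#' @export
pot_experiment <- function() {
  read_measurements(system.file("extdata", "pot_experiment_measurements.csv",
                                package = "stabeval", mustWork = TRUE))
}
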