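#' Configure a transformed up-down staircase
#'
#' A continuous n-down/1-up staircase adapts the test-stimulus intensity to
#' hold discrimination accuracy at the rule's equilibrium (70.7\% correct for
#' the 2-down/1-up rule used here). The test intensity moves up by one step
#' after every incorrect response and down by one step after `n_down`
#' consecutive correct responses, and is clamped to `[min_test, max_test]`.
#'
#' @param reference_intensity Intensity of the fixed reference stimulus
#'   (\% contrast or degrees C).
#' @param start_test_intensity Test intensity on the first trial.
#' @param step Step size (same units, > 0).
#' @param max_test_intensity Upper cap on the test intensity (e.g. 43.0 C for
#'   innocuous warmth, 50.0 C for noxious heat).
#' @param min_test_intensity Lower cap; defaults to one step above the
#'   reference so test and reference never coincide.
#' @param n_down Number of consecutive correct responses required before the
#'   intensity is decreased (2 for the standard 70.7\% rule).
#' @return An object of class `staircase_config`.
#' @examples
#' staircase_config(38, 40, 0.5, 43)   # innocuous warmth
#' staircase_config(45, 47, 0.5, 50)   # noxious heat
#' staircase_config(50, 70, 3, 100)    # visual contrast, percent units
#' @export
staircase_config <- function(reference_intensity, start_test_intensity, step,
                             max_test_intensity,
                             min_test_intensity = reference_intensity + step,
                             n_down = 2L) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a single positive number", call. = FALSE)
  if (n_down < 1L) stop("`n_down` must be >= 1", call. = FALSE)
  if (!(reference_intensity < min_test_intensity))
    stop("reference_intensity must lie below min_test_intensity", call. = FALSE)
  if (min_test_intensity > start_test_intensity ||
      start_test_intensity > max_test_intensity)
    stop("require min_test <= start_test <= max_test", call. = FALSE)
  structure(
    list(reference_intensity = reference_intensity,
         start_test_intensity = start_test_intensity,
         step = step,
         max_test_intensity = max_test_intensity,
         min_test_intensity = min_test_intensity,
         n_down = as.integer(n_down)),
    class = "staircase_config")
}

#' Initialise a staircase
#'
#' @param config A [staircase_config()].
#' @param record_history Keep the per-trial (intensity, correct) trajectory
#'   in the state. Disable for long diagnostic runs where the caller records
#'   the trajectory itself.
#' @return An object of class `staircase_state` holding the current test
#'   intensity, the consecutive-correct counter, the trial index, and the
#'   trajectory history.
#' @export
init_staircase <- function(config, record_history = TRUE) {
  stopifnot(inherits(config, "staircase_config"))
  # intensities kept as integer step offsets from the start value so that a
  # long trajectory never drifts from the step lattice
  structure(
    list(config = config,
         offset = 0L,
         k_min = as.integer(round((config$min_test_intensity -
                                     config$start_test_intensity) / config$step)),
         k_max = as.integer(round((config$max_test_intensity -
                                     config$start_test_intensity) / config$step)),
         consecutive_correct = 0L,
         trial_index = 0L,
         record_history = isTRUE(record_history),
         history = list(intensity = numeric(0), correct = logical(0))),
    class = "staircase_state")
}

#' Current test intensity of a staircase
#'
#' @param state A `staircase_state`.
#' @return The test intensity in stimulus units.
#' @export
staircase_intensity <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  state$config$start_test_intensity + state$offset * state$config$step
}

#' Advance a staircase by one trial
#'
#' Applies the n-down/1-up rule: an incorrect response raises the test
#' intensity by one step; the `n_down`-th consecutive correct response lowers
#' it by one step. The consecutive-correct counter resets to zero after any
#' intensity change, and intensities are clamped to the configured bounds.
#'
#' @param state A `staircase_state`.
#' @param correct Logical; was the response on this trial correct?
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  intensity_now <- staircase_intensity(state)
  if (!correct) {
    state$offset <- min(state$offset + 1L, state$k_max)
    state$consecutive_correct <- 0L
  } else if (state$consecutive_correct + 1L >= state$config$n_down) {
    state$offset <- max(state$offset - 1L, state$k_min)
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
  }
  state$trial_index <- state$trial_index + 1L
  if (state$record_history) {
    state$history$intensity <- c(state$history$intensity, intensity_now)
    state$history$correct <- c(state$history$correct, correct)
  }
  state
}

#' Equilibrium accuracy of an n-down/1-up staircase
#'
#' The transformed up-down rule converges where the probability of `n_down`
#' consecutive correct responses equals the probability of a single error,
#' i.e. at the accuracy p* solving p*^n_down = 1/2.
#'
#' @param n_down Number of consecutive correct responses required for a
#'   decrement (>= 1).
#' @return The asymptotic proportion correct (0.7071 for `n_down = 2`).
#' @export
asymptotic_accuracy <- function(n_down) {
  if (!is.numeric(n_down) || length(n_down) != 1L || n_down < 1)
    stop("`n_down` must be a single number >= 1", call. = FALSE)
  0.5^(1 / n_down)
}

#' Run a staircase against a simulated observer
#'
#' Drives a staircase with a stationary observer whose probability of a
#' correct response is a monotone function of the test-minus-reference
#' intensity difference. Used for convergence diagnostics and calibration.
#'
#' @param config A [staircase_config()].
#' @param p_correct A function mapping the (non-negative) intensity difference
#'   to the probability of a correct response.
#' @param n_trials Number of simulated trials.
#' @return A data frame with one row per trial: `trial`, `intensity`,
#'   `delta` (test minus reference) and `correct`.
#' @export
run_staircase <- function(config, p_correct, n_trials) {
  state <- init_staircase(config, record_history = FALSE)
  intensity <- numeric(n_trials)
  correct <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    intensity[t] <- staircase_intensity(state)
    delta <- intensity[t] - config$reference_intensity
    correct[t] <- stats::runif(1) < p_correct(delta)
    state <- update_staircase(state, correct[t])
  }
  data.frame(trial = seq_len(n_trials), intensity = intensity,
             delta = intensity - config$reference_intensity, correct = correct)
}
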