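#' Simulated observer for the frequency-discrimination task
#'
#' Two-interval forced choice: the probability of a correct judgment of
#' which interval held the higher frequency is
#' `0.5 + 0.5 * pnorm((log(delta) - log(alpha)) / beta)`, a cumulative
#' Gaussian psychometric function in log frequency-difference with a 50%
#' guessing floor. At `delta = alpha` the observer is 75% correct.
#'
#' @param delta_pct frequency difference between the two sounds, percent.
#' @param alpha_pct 75%-correct point of the observer, percent.
#' @param beta log-domain spread of the psychometric function.
#' @return Logical: correct response (random).
#' @export
observer_respond <- function(delta_pct, alpha_pct = 4, beta = 0.6) {
  if (any(delta_pct <= 0)) stop("delta_pct must be positive")
  pc <- 0.5 + 0.5 * pnorm((log(delta_pct) - log(alpha_pct)) / beta)
  runif(length(delta_pct)) < pc
}

#' One adaptive staircase step
#'
#' Two-up/one-down rule on a multiplicative step: after two consecutive
#' correct responses the frequency difference is divided by
#' `step_factor` (harder), after any incorrect response it is multiplied
#' (easier); the difference never falls below `floor_pct`. This rule
#' converges to the 70.7%-correct point.
#'
#' @param state list with `delta_pct`, `correct_streak`.
#' @param correct logical response to the trial just presented.
#' @param step_factor multiplicative step (> 1).
#' @param floor_pct smallest allowed difference, percent.
#' @return Updated state.
#' @export
staircase_step <- function(state, correct, step_factor = 1.12,
                           floor_pct = 0.25) {
  if (correct) {
    state$correct_streak <- state$correct_streak + 1
    if (state$correct_streak >= 2) {
      state$delta_pct <- max(state$delta_pct / step_factor, floor_pct)
      state$correct_streak <- 0
    }
  } else {
    state$delta_pct <- state$delta_pct * step_factor
    state$correct_streak <- 0
  }
  state
}

#' Simulate a session of interleaved staircases
#'
#' Each run interleaves two independent two-up/one-down staircases by a
#' seeded coin flip per trial. The run's threshold estimate is the mean
#' frequency difference over the latter half of its trials, and the next
#' run's staircases start 30% above that estimate.
#'
#' @param n_runs number of runs.
#' @param trials_per_run trials per run (the imaging design yields 25
#'   sound pairs per 6-min run).
#' @param alpha_pct,beta observer parameters, see [observer_respond()].
#' @param start_delta_pct initial frequency difference, percent.
#' @param step_factor staircase step.
#' @param reinit_factor multiplier applied to the previous run's threshold
#'   for the next run's start.
#' @param seed RNG seed.
#' @return List: `runs` (data frame with `run`, `threshold_pct`,
#'   `pct_correct`, `pct_correct_latter`, `n_trials`), `trials` (per-trial
#'   log with `run`, `trial`, `staircase`, `delta_pct`, `correct`),
#'   `pct_correct` (session), `pct_correct_latter` (latter halves only).
#' @export
run_staircase_session <- function(n_runs = 11, trials_per_run = 25,
                                  alpha_pct = 4, beta = 0.6,
                                  start_delta_pct = 8, step_factor = 1.12,
                                  reinit_factor = 1.3, seed = 1) {
  stopifnot(n_runs >= 1, trials_per_run >= 2)
  trials <- vector("list", n_runs)
  runs <- data.frame(run = seq_len(n_runs), threshold_pct = NA_real_,
                     pct_correct = NA_real_, pct_correct_latter = NA_real_,
                     n_trials = trials_per_run)
  start <- start_delta_pct
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      st <- list(list(delta_pct = start, correct_streak = 0),
                 list(delta_pct = start, correct_streak = 0))
      log <- data.frame(run = r, trial = seq_len(trials_per_run),
                        staircase = NA_integer_, delta_pct = NA_real_,
                        correct = NA)
      for (tr in seq_len(trials_per_run)) {
        s <- sample.int(2, 1)
        delta <- st[[s]]$delta_pct
        corr <- observer_respond(delta, alpha_pct, beta)
        st[[s]] <- staircase_step(st[[s]], corr, step_factor)
        log$staircase[tr] <- s
        log$delta_pct[tr] <- delta
        log$correct[tr] <- corr
      }
      latter <- log$trial > trials_per_run / 2
      runs$threshold_pct[r] <- mean(log$delta_pct[latter])
      runs$pct_correct[r] <- 100 * mean(log$correct)
      runs$pct_correct_latter[r] <- 100 * mean(log$correct[latter])
      trials[[r]] <- log
      start <- reinit_factor * runs$threshold_pct[r]
    }
  })
  trials <- do.call(rbind, trials)
  list(runs = runs, trials = trials,
       pct_correct = 100 * mean(trials$correct),
       pct_correct_latter = mean(runs$pct_correct_latter))
}

#' Analytic convergence point of the two-up/one-down rule
#'
#' The staircase equilibrates where the probability of two consecutive
#' correct responses equals one half, i.e. at the 1/sqrt(2) = 70.7%
#' correct point; for the simulated observer this difference solves the
#' psychometric equation in closed form.
#'
#' @param alpha_pct,beta observer parameters.
#' @return Frequency difference (percent) at which the observer is
#'   70.7% correct.
#' @export
staircase_converged_delta <- function(alpha_pct = 4, beta = 0.6) {
  target <- 1 / sqrt(2)
  exp(log(alpha_pct) + beta * qnorm((target - 0.5) / 0.5))
}
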