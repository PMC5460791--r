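#' Create a single adaptive staircase track
#'
#' One-up one-down track over test forces: choosing the reference action
#' decrements the next test force by `step`, choosing the test action
#' increments it. Forces are clamped to `bounds`; a direction change of the
#' applied (post-clamp) step counts as one inversion, and a force that stays
#' clamped at a boundary for two consecutive trials also counts one
#' inversion so that the track can terminate. A track is complete after
#' `n_inversions` inversions.
#'
#' @param start_force Starting test force, N (within `bounds`).
#' @param step Step size, N (default 2).
#' @param bounds Force clamp, N (default `c(0, 16)`).
#' @param n_inversions Inversions required for completion (default 7).
#' @return An object of class `staircase`.
#' @export
new_staircase <- function(start_force, step = 2, bounds = c(0, 16),
                          n_inversions = 7) {
  if (start_force < bounds[1] || start_force > bounds[2])
    stop("start_force outside bounds")
  structure(list(
    force = start_force,
    step = step,
    bounds = bounds,
    n_inversions = n_inversions,
    last_move = "none",
    inversion_count = 0L,
    boundary_streak = 0L,
    inversion_forces = numeric(0),
    forces = numeric(0),
    choices = character(0)
  ), class = "staircase")
}

#' Initialise the staircase pair for one condition
#'
#' Each condition runs two interleaved tracks, one starting at 0 N and the
#' other at the 16 N manipulator ceiling, to compensate hysteresis.
#'
#' @param condition One row of an experiment design (see [exp2_design()]);
#'   only used for its staircase parameters, which are the task defaults.
#' @return List of two `staircase` objects at 0 and 16 N.
#' @export
init_staircase_pair <- function(condition = NULL) {
  list(new_staircase(0), new_staircase(16))
}

#' Advance a staircase by one choice
#'
#' @param s A `staircase` object.
#' @param choice `"reference"` (force goes down) or `"test"` (force goes up).
#' @return The updated `staircase`.
#' @export
update_staircase <- function(s, choice = c("reference", "test")) {
  choice <- match.arg(choice)
  if (staircase_complete(s))
    stop("cannot update a complete staircase")
  presented <- s$force
  s$forces <- c(s$forces, presented)
  s$choices <- c(s$choices, choice)
  proposed <- presented + if (choice == "test") s$step else -s$step
  clamped <- min(max(proposed, s$bounds[1]), s$bounds[2])
  delta <- clamped - presented
  if (delta == 0) {
    # clamped at a boundary without moving
    s$boundary_streak <- s$boundary_streak + 1L
    if (s$boundary_streak >= 2L) {
      s$inversion_count <- s$inversion_count + 1L
      s$inversion_forces <- c(s$inversion_forces, presented)
      s$boundary_streak <- 0L
    }
  } else {
    move <- if (delta > 0) "up" else "down"
    if (s$last_move != "none" && move != s$last_move) {
      s$inversion_count <- s$inversion_count + 1L
      s$inversion_forces <- c(s$inversion_forces, presented)
    }
    s$last_move <- move
    s$boundary_streak <- 0L
  }
  s$force <- clamped
  s
}

#' Has a staircase collected all its inversions?
#'
#' @param s A `staircase` object.
#' @return `TRUE` once the inversion count has reached its target.
#' @export
staircase_complete <- function(s) {
  s$inversion_count >= s$n_inversions
}

#' Equivalent force estimated from staircase inversions
#'
#' The asymptotic force onto which an adaptive track converges, estimated
#' as the arithmetic mean of the test forces at inversion trials, pooled
#' over the two tracks of a condition's pair.
#'
#' @param pair A list of `staircase` objects (typically the completed pair).
#' @param drop_first Number of initial inversions of each track to exclude
#'   before averaging (default 0: all inversions are used).
#' @return Mean inversion force, N (within the staircase bounds).
#' @export
equivalent_force_from_inversions <- function(pair, drop_first = 0) {
  if (inherits(pair, "staircase")) pair <- list(pair)
  forces <- unlist(lapply(pair, function(s) {
    f <- s$inversion_forces
    if (drop_first > 0 && length(f) > drop_first) f[-seq_len(drop_first)]
    else if (drop_first > 0) numeric(0)
    else f
  }))
  if (length(forces) == 0)
    stop("no inversions recorded: cannot estimate an equivalent force")
  mean(forces)
}

# ---- experiment designs ----------------------------------------------------

#' Condition schedule for the repeated-movement experiment
#'
#' Eight conditions: four reference force levels (0, 3, 6, 9 N) crossed with
#' two movement directions. The reference action is the same movement
#' performed twice; the test action is a single movement whose force the
#' staircase adapts. All movements have a 120 mm amplitude and an 800-1300 ms
#' duration window.
#'
#' @return A data frame with one row per condition.
#' @export
exp2_design <- function() {
  d <- expand.grid(F_R = c(0, 3, 6, 9),
                   direction = c("inward", "outward"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    condition_id = seq_len(nrow(d)),
    experiment = 2L,
    session = "none",
    F_R = d$F_R,
    direction = d$direction,
    test_level = "none",
    n_ref_repeats = 2L,
    amplitude_mm = 120,
    ref_amplitude_mm = 120,
    duration_window_ms = "800-1300",
    ref_duration_ms = 1050,
    test_duration_ms = 1050,
    stringsAsFactors = FALSE
  )
}

#' Condition schedule for the duration/amplitude experiment
#'
#' Eight conditions per session: two reference forces (6, 10 N) crossed with
#' two reference directions and two test levels of the session variable.
#' In the amplitude session all movements share one duration window
#' (800-1250 ms) and amplitudes are 120/160/200 mm (reference at 160 mm);
#' in the duration session all movements have a 160 mm amplitude and the
#' test duration windows are 0-800 ms (low) or 1300-2000 ms (high) against
#' a medium 800-1300 ms reference. Test movements run in the direction
#' opposite to the reference. Nominal durations (window midpoints) are
#' attached for simulation.
#'
#' @param session `"amplitude"` or `"duration"`.
#' @return A data frame with one row per condition.
#' @export
exp1_design <- function(session = c("amplitude", "duration")) {
  session <- match.arg(session)
  d <- expand.grid(F_R = c(6, 10),
                   direction = c("inward", "outward"),
                   test_level = c("low", "high"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(d)
  out <- data.frame(
    condition_id = seq_len(n),
    experiment = 1L,
    session = session,
    F_R = d$F_R,
    direction = d$direction,      # reference movement direction
    test_level = d$test_level,
    n_ref_repeats = 1L,
    stringsAsFactors = FALSE
  )
  if (session == "amplitude") {
    out$amplitude_mm <- ifelse(d$test_level == "low", 120, 200)
    out$ref_amplitude_mm <- 160
    out$duration_window_ms <- "800-1250"
    out$ref_duration_ms <- 1025
    out$test_duration_ms <- 1025
  } else {
    out$amplitude_mm <- 160
    out$ref_amplitude_mm <- 160
    out$duration_window_ms <- ifelse(d$test_level == "low", "0-800", "1300-2000")
    out$ref_duration_ms <- 1050
    out$test_duration_ms <- ifelse(d$test_level == "low", 400, 1650)
  }
  out
}

#' Maximum movement duration of a session
#'
#' @param session `"amplitude"` (1250 ms) or `"duration"` (2000 ms).
#' @return `d_mmax` in ms.
#' @export
session_d_mmax <- function(session = c("amplitude", "duration")) {
  session <- match.arg(session)
  if (session == "amplitude") 1250 else 2000
}

#' Target hold duration equalising subtrial length (single-movement design)
#'
#' After target acquisition the cursor must be held for
#' `d_h = 100 + d_mmax - d_m` ms, so that every subtrial lasts the same
#' regardless of movement duration; this removes temporal discounting as a
#' confound.
#'
#' @param d_m Movement duration, ms (must not exceed `d_mmax`).
#' @param d_mmax Session maximum movement duration, ms; either a number or a
#'   session name understood by [session_d_mmax()].
#' @return Hold duration in ms (always >= 100).
#' @export
hold_duration <- function(d_m, d_mmax) {
  if (is.character(d_mmax)) d_mmax <- session_d_mmax(d_mmax)
  if (any(d_m > d_mmax))
    stop("movement duration exceeds the session maximum d_mmax")
  100 + d_mmax - d_m
}

#' Subtrial timing for the repeated-movement experiment
#'
#' Every subtrial lasts exactly `total` ms (4000 ms): after the movement(s)
#' an additional waiting time tops the subtrial up to the fixed total. For a
#' repeated reference action the two movements are separated by a 500 ms
#' hold at the intermediate target.
#'
#' @param d_m Movement duration(s), ms; one value per movement in the
#'   subtrial (length 1 for a test action, 2 for the repeated reference).
#' @param inter_hold Hold between repeated movements, ms (default 500).
#' @param total Total subtrial duration, ms (default 4000).
#' @return List with components `movement`, `wait` and `total` (ms).
#' @export
exp2_subtrial_timing <- function(d_m, inter_hold = 500, total = 4000) {
  moving <- sum(d_m) + if (length(d_m) > 1) (length(d_m) - 1) * inter_hold else 0
  wait <- total - moving
  if (wait < 0)
    stop("movement durations exceed the fixed subtrial duration")
  list(movement = moving, wait = wait, total = moving + wait)
}

# ---- session runner --------------------------------------------------------

#' Run all staircases of a design against an observer
#'
#' Creates the staircase pair for each condition of `design` and interleaves
#' all incomplete tracks uniformly at random (the scheduling uses the
#' current RNG state; seed upstream for reproducibility). At each trial the
#' scheduled track's current force is presented, the observer chooses, and
#' the track advances.
#'
#' @param design A design data frame ([exp1_design()] / [exp2_design()]).
#' @param observer `function(condition, F_T)` returning `"reference"` or
#'   `"test"` (a condition is one row of `design`).
#' @param subject_id Identifier written into the trial table.
#' @param max_trials Safety cap on the total number of trials.
#' @return List with `trials` (a trial-table data frame, one row per trial)
#'   and `staircases` (per condition, the completed pair).
#' @export
run_staircase_session <- function(design, observer, subject_id = 1L,
                                  max_trials = 10000L) {
  pairs <- lapply(seq_len(nrow(design)), function(i) init_staircase_pair(design[i, ]))
  n_tracks <- 2L * nrow(design)
  cond_of <- rep(seq_len(nrow(design)), each = 2L)
  track_of <- rep(1:2, nrow(design))
  rows <- vector("list", max_trials)
  trial <- 0L
  repeat {
    active <- which(!vapply(seq_len(n_tracks), function(k) {
      staircase_complete(pairs[[cond_of[k]]][[track_of[k]]])
    }, logical(1)))
    if (length(active) == 0) break
    k <- if (length(active) == 1) active else sample(active, 1L)
    ci <- cond_of[k]; ti <- track_of[k]
    cond <- design[ci, ]
    s <- pairs[[ci]][[ti]]
    F_T <- s$force
    choice <- observer(cond, F_T)
    if (isTRUE(choice) || identical(choice, "reference")) choice <- "reference"
    else choice <- "test"
    pairs[[ci]][[ti]] <- update_staircase(s, choice)
    trial <- trial + 1L
    if (trial > max_trials) stop("staircase session exceeded max_trials")
    rows[[trial]] <- data.frame(
      subject_id = subject_id,
      experiment = cond$experiment,
      session = cond$session,
      condition_id = cond$condition_id,
      staircase_id = ti,
      trial_index = trial,
      F_R_N = cond$F_R,
      F_T_N = F_T,
      direction = cond$direction,
      amplitude_mm = cond$amplitude_mm,
      duration_window_ms = cond$duration_window_ms,
      n_ref_repeats = cond$n_ref_repeats,
      choice = choice,
      stringsAsFactors = FALSE
    )
  }
  list(trials = do.call(rbind, rows[seq_len(trial)]), staircases = pairs)
}
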