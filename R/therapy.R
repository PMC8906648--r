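#' Continuous maximum-tolerated-dose schedule
#'
#' @param day Day index (>= 0); vectorized.
#' @return Dose 1 for every day.
#' @export
dose_ctmtd <- function(day) {
  if (any(day < 0)) stop("'day' must be >= 0")
  rep(1L, length(day))
}

#' Adaptive-therapy controller state
#'
#' The adaptive controller is a two-phase state machine: it emits full dose
#' while "on", switches off when the total population drops below
#' `rho * N0_ref`, and switches back on once the population regrows to
#' `N0_ref`. It starts in the "on" phase.
#'
#' @param N0_ref Reference (initial) population used for both thresholds.
#' @return An object of class `at_state`.
#' @export
at_state <- function(N0_ref) {
  stopifnot(is.numeric(N0_ref), N0_ref > 0)
  structure(list(phase = "on", N0_ref = N0_ref), class = "at_state")
}

#' One adaptive-therapy controller evaluation
#'
#' Evaluated once per day before the dynamics step, using the previous day's
#' closing population: the phase transition is applied first, then the dose
#' for the coming day is emitted. Pausing uses a strict inequality
#' (`N < rho * N0_ref`), resumption a non-strict one (`N >= N0_ref`).
#'
#' @param state An [at_state()] object.
#' @param N Current total population.
#' @param params A [model_params()] object (supplies `rho`).
#' @return List with `dose` (0 or 1) and the updated `state`.
#' @examples
#' st <- at_state(5000)
#' dose_at(st, 2499, model_params())$dose # 0: pause below rho * N0
#' @export
dose_at <- function(state, N, params) {
  stopifnot(inherits(state, "at_state"), N >= 0)
  if (state$phase == "on" && N < params$rho * state$N0_ref) state$phase <- "off"
  else if (state$phase == "off" && N >= state$N0_ref) state$phase <- "on"
  list(dose = if (state$phase == "on") 1L else 0L, state = state)
}

# coerce the various trajectory representations to a day-indexed N vector
as_N_series <- function(x) {
  if (inherits(x, "tumor_sim")) x <- x$ts
  if (is.data.frame(x)) {
    if (!all(c("day", "N") %in% names(x)))
      stop("data frame must have 'day' and 'N' columns")
    x <- x[order(x$day), ]
    if (!identical(as.integer(x$day), seq_len(nrow(x)) - 1L))
      stop("'day' must run 0, 1, 2, ...")
    return(x$N)
  }
  if (is.numeric(x)) return(as.numeric(x))
  stop("cannot interpret trajectory input")
}

#' Time to tumour progression
#'
#' First day on which the total population reaches
#' `progression_factor * N0` (120% of the initial burden by default). Days
#' are counted from 0, the first element of the series.
#'
#' @param x A total-population trajectory: a numeric vector indexed from day
#'   0, a data frame with `day` and `N` columns, or a [simulate_tumor()]
#'   result.
#' @param N0 Reference initial population; defaults to the day-0 value of the
#'   series.
#' @param progression_factor Progression threshold multiplier.
#' @return The progression day, or `NA` if the threshold is never reached
#'   (censored at the end of the series).
#' @examples
#' detect_ttp(c(5000, 5400, 6050)) # day 2
#' @export
detect_ttp <- function(x, N0 = NULL, progression_factor = 1.2) {
  N <- as_N_series(x)
  if (length(N) == 0) stop("empty trajectory")
  if (is.null(N0)) N0 <- N[1]
  hit <- which(N >= progression_factor * N0)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1] - 1L)
}

#' Time for the resistant population to reach 50% of the initial burden
#'
#' @param x A [simulate_tumor()] result, or a data frame with `day` and `R`
#'   columns, or a numeric R-cell trajectory indexed from day 0.
#' @param N0 Initial total population (defaults to `S + R` at day 0 when a
#'   simulation or data frame is given).
#' @param frac Fraction of `N0` that defines the event (default 0.5).
#' @return The first qualifying day, or `NA` if censored.
#' @export
detect_tr50 <- function(x, N0 = NULL, frac = 0.5) {
  if (inherits(x, "tumor_sim")) x <- x$ts
  if (is.data.frame(x)) {
    if (is.null(N0)) N0 <- x$N[x$day == 0]
    R <- x$R[order(x$day)]
  } else {
    R <- as.numeric(x)
    if (is.null(N0)) stop("'N0' is required for a bare numeric series")
  }
  hit <- which(R >= frac * N0)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1] - 1L)
}

#' Count treatment cycles in a dose series
#'
#' A cycle is a maximal block of consecutive "on" days, so an uninterrupted
#' schedule counts as one cycle and `1,0,1,0,...` counts one per "on" block.
#'
#' @param dose Integer vector of per-day doses (0/1), starting with 1.
#' @return Number of on-blocks started.
#' @examples
#' count_cycles(c(1, 1, 0, 0, 1, 1)) # 2
#' @export
count_cycles <- function(dose) {
  dose <- as.integer(dose)
  if (length(dose) == 0) return(0L)
  if (dose[1] != 1L) stop("dose series must start with treatment on")
  if (!all(dose %in% c(0L, 1L))) stop("doses must be 0 or 1")
  sum(dose == 1L & c(1L, dose[-length(dose)]) != 1L) + 1L
}

#' Time gained by adaptive therapy
#'
#' `TG = TTP(AT) - TTP(CT-MTD)` on seed-paired runs. Censored arms give
#' `NA`.
#'
#' @param ttp_at,ttp_ct Progression days (possibly `NA`) or
#'   [simulate_tumor()] results.
#' @return The time gain in days, or `NA` if either arm is censored.
#' @export
time_gain <- function(ttp_at, ttp_ct) {
  if (inherits(ttp_at, "tumor_sim")) ttp_at <- ttp_at$outcome$ttp
  if (inherits(ttp_ct, "tumor_sim")) ttp_ct <- ttp_ct$outcome$ttp
  ttp_at - ttp_ct
}
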