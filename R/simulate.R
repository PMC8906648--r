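#' Simulate one tumour realization
#'
#' Runs the stochastic lattice model for `days` simulated days under a
#' treatment strategy. Each day the dose controller is evaluated on the
#' previous day's closing population, then every cell alive at the day's
#' start is processed once in a freshly shuffled order: with probability `m`
#' it attempts migration to a free neighbouring site (the attempt ends its
#' turn); otherwise with probability `r_j + d_T` an event occurs, which is a
#' division attempt with probability `r_j / (r_j + d_T)` and natural death
#' otherwise. A sensitive cell attempting division under dose is killed with
#' probability `delta_D`; a surviving attempt places one daughter uniformly
#' at random among the free capacity slots of the von Neumann neighbourhood
#' (plus the mother's own spare slot when `K = 2`), or is blocked if there is
#' none. Cells on CAF sites divide with probability `alpha * r_j`.
#'
#' @param params A [model_params()] object.
#' @param lattice Optional initial [new_lattice()]; built by [seed_cells()]
#'   from `r_pattern`, `clump_side` and `caf_layout` when omitted.
#' @param strategy `"ctmtd"` (continuous full dose), `"at"` (adaptive
#'   on-off therapy) or `"none"` (no drug).
#' @param seed Integer seed; the same seed, parameters and lattice reproduce
#'   the run bit-for-bit, and the dynamics stream is shared between
#'   strategies so AT/CT-MTD pairs agree until their doses first diverge.
#' @param r_pattern,clump_side,caf_layout Passed to [seed_cells()] when
#'   `lattice` is `NULL`.
#' @param days Number of days to simulate (defaults to `params$T_end`).
#' @param snapshot_days Integer days (0-based) at which to record grid
#'   snapshots.
#' @param record_neighborhood Record daily mean neighbourhood counts
#'   (see [neighborhood_counts()]).
#' @param drug_check_after_space If `TRUE`, the drug-death check of a
#'   division attempt is made only after free space has been confirmed, so a
#'   fully blocked sensitive cell cannot drug-die. Default `FALSE`: the drug
#'   check comes first.
#' @param engine_seed Override for the internal dynamics stream seed
#'   (advanced; used to align a lesion of a virtual patient with a
#'   single-lesion run).
#'
#' @return An object of class `tumor_sim` with components `ts` (data frame
#'   `day`, `S`, `R`, `N`, `dose`), `tallies` (per-day event counts),
#'   `nbhd` (daily mean neighbourhood counts or `NULL`), `snapshots`,
#'   `lattice` (initial state), `final` (closing state) and `outcome`
#'   (`ttp`, `censored`, `cycles`, `tr50`).
#' @examples
#' p <- model_params(T_end = 30)
#' sim <- simulate_tumor(p, strategy = "ctmtd", seed = 1)
#' head(sim$ts)
#' @export
simulate_tumor <- function(params, lattice = NULL,
                           strategy = c("ctmtd", "at", "none"), seed = 1L,
                           r_pattern = "clumped", clump_side = 40L,
                           caf_layout = "NoF", days = params$T_end,
                           snapshot_days = integer(0),
                           record_neighborhood = FALSE,
                           drug_check_after_space = FALSE,
                           engine_seed = NULL) {
  stopifnot(inherits(params, "tumor_params"))
  strategy <- match.arg(strategy)
  if (is.null(lattice))
    lattice <- seed_cells(params, r_pattern, clump_side, caf_layout, seed = seed)
  stopifnot(inherits(lattice, "tumor_lattice"))
  if (lattice$K != params$K)
    stop("lattice K does not match params K")
  if (is.null(engine_seed)) engine_seed <- lesion_seed(seed, 1L)
  n0 <- lattice_counts(lattice)[["N"]]

  res <- .abm_run(list(engine_lesion(lattice, params, engine_seed)),
                  rho = params$rho, n0_ref = n0,
                  strategy = if (strategy == "at") 1L else 0L,
                  const_dose = if (strategy == "ctmtd") 1 else 0,
                  days = as.integer(days),
                  drug_check_after_space = drug_check_after_space,
                  record_nbhd = record_neighborhood,
                  snapshot_days = as.integer(snapshot_days))

  tsm <- res$ts[[1]]
  dose <- as.integer(res$dose)
  ts <- data.frame(day = 0:days, S = tsm[, "S"], R = tsm[, "R"], N = tsm[, "N"],
                   dose = c(dose, dose[length(dose)]))
  tallies <- as.data.frame(res$tallies[[1]])
  tallies$day <- seq_len(days)
  nbhd <- if (record_neighborhood) {
    nb <- as.data.frame(res$nbhd[[1]]); nb$day <- 0:days; nb
  } else NULL
  final <- new_lattice(res$grids[[1]]$nS, res$grids[[1]]$nR, lattice$caf,
                       lattice$K)
  snaps <- lapply(res$snapshots, function(per) per[[1]])

  ttp <- detect_ttp(ts$N, N0 = n0, progression_factor = params$progression_factor)
  cycles <- if (strategy == "none" || length(dose) == 0 || dose[1] != 1L) 0L else {
    upto <- if (is.na(ttp)) length(dose) else max(ttp, 1L)
    count_cycles(dose[seq_len(upto)])
  }
  out <- list(params = params, strategy = strategy, seed = seed,
              drug_check_after_space = drug_check_after_space,
              ts = ts, tallies = tallies, nbhd = nbhd, snapshots = snaps,
              lattice = lattice, final = final,
              outcome = list(ttp = ttp, censored = is.na(ttp),
                             cycles = cycles,
                             tr50 = detect_tr50(ts, N0 = n0)))
  class(out) <- "tumor_sim"
  out
}

#' Advance a lattice by one day under a fixed dose
#'
#' Single-step access to the update kernel, mainly for inspection and
#' testing. Returns the updated lattice and the day's event tally.
#'
#' @param lattice A [new_lattice()] object.
#' @param dose Drug dose for the day, 0 or 1.
#' @param params A [model_params()] object.
#' @param seed Integer seed for the day's randomness.
#' @param drug_check_after_space See [simulate_tumor()].
#' @return List with `lattice` (updated) and `tally` (named numeric vector).
#' @export
advance <- function(lattice, dose, params, seed = 1L,
                    drug_check_after_space = FALSE) {
  stopifnot(inherits(lattice, "tumor_lattice"), inherits(params, "tumor_params"))
  if (!dose %in% c(0, 1)) stop("'dose' must be 0 or 1")
  res <- .abm_run(list(engine_lesion(lattice, params, lesion_seed(seed, 1L))),
                  rho = params$rho, n0_ref = 1, strategy = 0L,
                  const_dose = dose, days = 1L,
                  drug_check_after_space = drug_check_after_space,
                  record_nbhd = FALSE, snapshot_days = integer(0))
  list(lattice = new_lattice(res$grids[[1]]$nS, res$grids[[1]]$nR,
                             lattice$caf, lattice$K),
       tally = res$tallies[[1]][1, ])
}

#' @export
print.tumor_sim <- function(x, ...) {
  o <- x$outcome
  cat(sprintf("tumor_sim: %s, seed %s, %d days on %d x %d (K = %d)\n",
              toupper(x$strategy), format(x$seed), nrow(x$ts) - 1L,
              x$lattice$side, x$lattice$side, x$lattice$K))
  n0 <- x$ts$N[1]
  cat(sprintf("  N: %d -> %d (S %d / R %d at end)\n", n0,
              x$ts$N[nrow(x$ts)], x$ts$S[nrow(x$ts)], x$ts$R[nrow(x$ts)]))
  if (o$censored) {
    cat("  progression: censored (threshold never reached)\n")
  } else {
    cat(sprintf("  progression: day %d (>= %.0f%% of N0), %d treatment cycle(s)\n",
                o$ttp, 100 * x$params$progression_factor, o$cycles))
  }
  if (!is.na(o$tr50)) cat(sprintf("  TR50: day %d\n", o$tr50))
  invisible(x)
}

#' @export
summary.tumor_sim <- function(object, ...) {
  c(object$outcome[c("ttp", "censored", "cycles", "tr50")],
    list(final_S = object$ts$S[nrow(object$ts)],
         final_R = object$ts$R[nrow(object$ts)],
         days = nrow(object$ts) - 1L))
}

#' Plot a simulated trajectory
#'
#' Draws the S, R and total cell populations over time, shades treatment-off
#' days, and marks the progression threshold and day.
#'
#' @param x A [simulate_tumor()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.tumor_sim <- function(x, ...) {
  ts <- x$ts
  graphics::plot(ts$day, ts$N, type = "l", lwd = 2, xlab = "day",
                 ylab = "cells", ylim = c(0, max(ts$N) * 1.05), ...)
  off <- ts$day[ts$dose == 0]
  if (length(off)) graphics::rug(off, col = "grey70")
  graphics::lines(ts$day, ts$S, col = "steelblue")
  graphics::lines(ts$day, ts$R, col = "darkorange")
  graphics::abline(h = x$params$progression_factor * ts$N[1],
                   col = "cyan3", lty = 2)
  if (!x$outcome$censored)
    graphics::abline(v = x$outcome$ttp, col = "cyan3", lty = 2)
  graphics::legend("topleft", c("N", "S", "R"), lwd = c(2, 1, 1),
                   col = c("black", "steelblue", "darkorange"), bty = "n")
  invisible(x)
}

#' Write a time-series CSV
#'
#' @param x A [simulate_tumor()] result or [run_cohort()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(x, path) {
  df <- if (inherits(x, "tumor_sim")) x$ts
        else if (inherits(x, "tumor_cohort")) x$timeseries
        else stop("unsupported object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
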