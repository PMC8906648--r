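#' Neighbourhood competition counts
#'
#' For every focal cell of the requested kind, counts the sensitive cells
#' (`NS`), resistant cells (`NR`) and empty capacity slots (`NE`) over its
#' von Neumann neighbourhood; with `K = 2` the other slot of the focal
#' cell's own site is included, so the interior identity is
#' `NS + NR + NE = 4` for `K = 1` and `9` for `K = 2`.
#'
#' @param lattice A [new_lattice()] object.
#' @param focal_kind `"S"` or `"R"`: the kind of focal cell.
#' @return List with `counts` (one row per focal cell, columns `NS`, `NR`,
#'   `NE`) and `mean` (named mean triple; `NaN`s when no focal cell exists).
#' @examples
#' lat <- seed_cells(model_params(N0 = 50), "random", seed = 1)
#' neighborhood_counts(lat, "R")$mean
#' @export
neighborhood_counts <- function(lattice, focal_kind = c("S", "R")) {
  stopifnot(inherits(lattice, "tumor_lattice"))
  focal_kind <- match.arg(focal_kind)
  L <- lattice$side; K <- lattice$K
  nS <- lattice$nS; nR <- lattice$nR
  free <- K - nS - nR

  shift_sum <- function(m) {
    out <- matrix(0, L, L)
    out[, -L] <- out[, -L] + m[, -1]    # east neighbour
    out[, -1] <- out[, -1] + m[, -L]    # west
    out[-L, ] <- out[-L, ] + m[-1, ]    # south
    out[-1, ] <- out[-1, ] + m[-L, ]    # north
    out
  }
  NS <- shift_sum(nS); NR <- shift_sum(nR); NE <- shift_sum(free)
  if (K > 1) { # focal cell also sees its own site's other slot(s)
    NS <- NS + nS - (focal_kind == "S")
    NR <- NR + nR - (focal_kind == "R")
    NE <- NE + free
  }
  focal <- if (focal_kind == "S") nS else nR
  idx <- which(focal > 0L)
  if (length(idx) == 0L)
    return(list(counts = matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, c("NS", "NR", "NE"))),
                mean = c(NS = NaN, NR = NaN, NE = NaN)))
  reps <- focal[idx]
  counts <- cbind(NS = rep(NS[idx], reps), NR = rep(NR[idx], reps),
                  NE = rep(NE[idx], reps))
  list(counts = counts, mean = colMeans(counts))
}

#' Area of impact of a CAF layout
#'
#' Counts the fibroblast sites lying inside the inner square
#' `[margin + 1, L - margin]^2`. CAF sites within `margin` of the boundary
#' cannot influence the time to progression, because progression occurs
#' before the growing tumour reaches them.
#'
#' @param caf A logical CAF mask, or a [new_lattice()] object.
#' @param margin Width of the excluded boundary band (default 10 sites).
#' @return Integer count of CAF sites inside the inner square.
#' @examples
#' area_of_impact(caf_mask("FC"), margin = 10) # 1024: fully inside
#' @export
area_of_impact <- function(caf, margin = 10L) {
  if (inherits(caf, "tumor_lattice")) caf <- caf$caf
  L <- nrow(caf)
  margin <- as.integer(margin)
  if (margin < 0L || margin >= L / 2) stop("'margin' must lie in [0, L/2)")
  inner <- (margin + 1L):(L - margin)
  sum(caf[inner, inner])
}

#' Average rate of change of a mean trajectory
#'
#' `(N(t1) - N(t0)) / (t1 - t0)` in cells/day, on a day-indexed series.
#'
#' @param x A trajectory as accepted by [detect_ttp()].
#' @param t0,t1 Days with `t0 < t1`, both within the series.
#' @return The average rate in cells per day (negative for decline).
#' @export
trajectory_rates <- function(x, t0, t1) {
  N <- as_N_series(x)
  if (t0 >= t1) stop("'t0' must be < 't1'")
  if (t0 < 0 || t1 > length(N) - 1L) stop("days outside the recorded series")
  (N[t1 + 1L] - N[t0 + 1L]) / (t1 - t0)
}

#' Write per-day neighbourhood summaries to CSV
#'
#' Columns: `day`, `realization`, `focal_kind`, `mean_NE`, `mean_NS`,
#' `mean_NR` (one row per day, realization and focal kind).
#'
#' @param x A [run_cohort()] result with recorded neighbourhood summaries,
#'   or a single [simulate_tumor()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_neighborhood <- function(x, path) {
  df <- if (inherits(x, "tumor_cohort")) x$neighborhood
        else if (inherits(x, "tumor_sim")) {
          if (is.null(x$nbhd)) stop("neighbourhood summaries were not recorded")
          nb <- x$nbhd
          rbind(
            data.frame(day = nb$day, realization = 1L, focal_kind = "S",
                       mean_NE = nb$S_NE, mean_NS = nb$S_NS, mean_NR = nb$S_NR),
            data.frame(day = nb$day, realization = 1L, focal_kind = "R",
                       mean_NE = nb$R_NE, mean_NS = nb$R_NS, mean_NR = nb$R_NR))
        } else stop("unsupported object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
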