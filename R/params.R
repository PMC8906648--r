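#' Model parameters
#'
#' Collects all rates, probabilities and structural constants of the lattice
#' model into a validated parameter object. Defaults are the base
#' parameterization used throughout: a sensitive-cell division probability of
#' 0.027 per day, a 30% fitness cost of resistance (`r_R = 0.7 * r_S`), a
#' natural death probability `d_T = 0.3 * r_S` shared by both cell types, and
#' a drug-induced death probability of 0.75 applied to sensitive cells during
#' a division attempt under full dose. All rates are per-day Bernoulli
#' probabilities; the time step is one day.
#'
#' @param r_S Sensitive-cell division probability per day.
#' @param r_R Resistant-cell division probability per day. Defaults to the
#'   30%-cost value `0.7 * r_S`.
#' @param d_T Natural (drug-independent) death probability per day for both
#'   cell types. Defaults to `0.3 * r_S`.
#' @param delta_D Probability that a sensitive cell attempting division under
#'   unit drug dose is killed by the drug. Resistant cells never drug-die.
#' @param m Migration probability per day. A cell that attempts migration
#'   (successfully or not) does nothing else that day. Typical values are
#'   multiples of `r_S` between 0 and `4 * r_S`.
#' @param alpha CAF growth-promotion factor: a cell sitting on a
#'   fibroblast-masked site divides with probability `alpha * r_j` instead of
#'   `r_j`. Only relevant when a CAF layout is present.
#' @param K Per-site carrying capacity, 1 or 2 cells.
#' @param rho Adaptive-therapy pause threshold: treatment stops once the
#'   total population falls below `rho * N0` and resumes at `N0`.
#' @param N0 Initial total cell count.
#' @param f0 Initial resistant fraction, in percent (0-100).
#' @param L Lattice side length (the domain is `L x L` with closed
#'   boundaries).
#' @param T_end Simulation end time in days.
#' @param progression_factor Progression threshold multiplier: progression is
#'   declared when the total population reaches
#'   `progression_factor * N0` (default 120%).
#'
#' @return An object of class `tumor_params` (a named list).
#' @examples
#' p <- model_params()
#' p$r_R / p$r_S # 0.7: fitness cost of resistance
#' @export
model_params <- function(r_S = 0.027, r_R = (1 - 0.3) * r_S, d_T = 0.3 * r_S,
                         delta_D = 0.75, m = 0, alpha = 2, K = 1, rho = 0.5,
                         N0 = 5000, f0 = 10, L = 100, T_end = 2000,
                         progression_factor = 1.2) {
  p <- list(r_S = r_S, r_R = r_R, d_T = d_T, delta_D = delta_D, m = m,
            alpha = alpha, K = K, rho = rho, N0 = N0, f0 = f0, L = L,
            T_end = T_end, progression_factor = progression_factor)
  validate_params(p)
}

validate_params <- function(p) {
  prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm), call. = FALSE)
  }
  for (nm in c("r_S", "r_R", "d_T", "delta_D", "m", "rho")) prob(p[[nm]], nm)
  if (p$rho <= 0 || p$rho >= 1) stop("'rho' must lie strictly in (0, 1)")
  if (!p$K %in% c(1L, 2L)) stop("'K' must be 1 or 2")
  p$K <- as.integer(p$K)
  if (p$alpha < 0) stop("'alpha' must be non-negative")
  if (p$alpha * max(p$r_S, p$r_R) + p$d_T > 1)
    stop("'alpha' too large: alpha * r_j + d_T must stay <= 1")
  if (p$f0 < 0 || p$f0 > 100) stop("'f0' must be a percentage in [0, 100]")
  if (p$L < 3) stop("'L' must be at least 3")
  p$L <- as.integer(p$L)
  if (p$N0 < 0 || p$N0 > p$K * p$L^2) stop("'N0' exceeds the domain capacity K * L^2")
  p$N0 <- as.integer(round(p$N0))
  if (p$T_end < 1) stop("'T_end' must be a positive number of days")
  p$T_end <- as.integer(p$T_end)
  if (p$progression_factor <= 1) stop("'progression_factor' must exceed 1")
  structure(p, class = "tumor_params")
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("On-lattice tumour model parameters\n")
  cat(sprintf("  domain           : %d x %d, K = %d cells/site, closed boundary\n",
              x$L, x$L, x$K))
  cat(sprintf("  division/day     : r_S = %.4g, r_R = %.4g (cost %.0f%%)\n",
              x$r_S, x$r_R, 100 * (1 - x$r_R / x$r_S)))
  cat(sprintf("  death/day        : d_T = %.4g natural, delta_D = %.3g drug (S only)\n",
              x$d_T, x$delta_D))
  cat(sprintf("  migration/day    : m = %.4g (= %.2g x r_S)\n", x$m, x$m / x$r_S))
  cat(sprintf("  CAF promotion    : alpha = %.3g\n", x$alpha))
  cat(sprintf("  initial state    : N0 = %d, f0 = %.3g%% resistant\n", x$N0, x$f0))
  cat(sprintf("  therapy          : AT pause below %.0f%% of N0, progression at %.0f%%\n",
              100 * x$rho, 100 * x$progression_factor))
  cat(sprintf("  horizon          : T = %d days\n", x$T_end))
  invisible(x)
}

# evaluate code with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# per-lesion engine seed derived from the user-facing realization seed;
# stays below 2^31 so it can also seed R's own RNG for lattice construction
lesion_seed <- function(seed, lesion = 1L) {
  (abs(seed) * 7 + lesion * 104729) %% (.Machine$integer.max - 1) + 1
}
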