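#' Specify one metastatic lesion
#'
#' @param side Lattice side length of the lesion's domain.
#' @param visible Whether the lesion is detectable at diagnosis. Invisible
#'   lesions start with 10% of a visible lesion's cell count but still count
#'   towards the systemic burden that drives the dose controller.
#' @param n0 Initial total cell count in the lesion.
#' @param f0 Initial resistant percentage.
#' @param r_pattern Resistant-cell dispersion pattern within the lesion.
#' @param clump_side Side of the centred clump for `"clumped"`.
#' @param caf `"none"` or `"scattered"` (random non-overlapping 10 x 10
#'   fibroblast clumps covering about 10% of the domain).
#' @param m Per-day migration probability for cells in this lesion.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(side = 200L, visible = TRUE, n0 = 5000L, f0 = 10,
                        r_pattern = c("clumped", "random", "uniform"),
                        clump_side = 40L, caf = c("none", "scattered"),
                        m = 0) {
  r_pattern <- match.arg(r_pattern)
  caf <- match.arg(caf)
  structure(list(side = as.integer(side), visible = visible,
                 n0 = as.integer(round(n0)), f0 = f0, r_pattern = r_pattern,
                 clump_side = as.integer(clump_side), caf = caf, m = m),
            class = "lesion_spec")
}

#' Default four-lesion virtual-patient cases
#'
#' Builds the lesion list for one of the four cases. The three visible
#' lesions are fixed across cases: lesion 1 has scattered fibroblasts and no
#' migration, lesion 2 has no fibroblasts and migration at `r_S`, lesion 3
#' has neither. The fourth, initially invisible lesion varies by case:
#'
#' * Case I - no fibroblasts, migration on (`m = r_S`);
#' * Case II - no fibroblasts, migration off;
#' * Case III - fibroblasts, migration on;
#' * Case IV - fibroblasts, migration off.
#'
#' Visible lesions start with `visible_n0` cells (10% resistant, clumped);
#' the invisible lesion starts with 10% of that, either clumped in a
#' centred 60 x 60 square or dispersed at random.
#'
#' @param case `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param invisible_pattern `"clumped"` or `"random"` placement of the
#'   invisible lesion's cells.
#' @param visible_n0 Initial cell count of each visible lesion.
#' @param side Domain side length of every lesion.
#' @param r_S Sensitive division probability, used to set "migration on"
#'   (`m = r_S`).
#' @return List of four [lesion_spec()] objects (the invisible one last).
#' @export
patient_case <- function(case = c("I", "II", "III", "IV"),
                         invisible_pattern = c("clumped", "random"),
                         visible_n0 = 5000L, side = 200L, r_S = 0.027) {
  case <- match.arg(case)
  invisible_pattern <- match.arg(invisible_pattern)
  vis_clump <- min(40L, side)
  vis <- list(
    lesion_spec(side, TRUE, visible_n0, clump_side = vis_clump,
                caf = "scattered", m = 0),
    lesion_spec(side, TRUE, visible_n0, clump_side = vis_clump,
                caf = "none", m = r_S),
    lesion_spec(side, TRUE, visible_n0, clump_side = vis_clump,
                caf = "none", m = 0))
  inv_caf <- if (case %in% c("III", "IV")) "scattered" else "none"
  inv_m <- if (case %in% c("I", "III")) r_S else 0
  inv <- lesion_spec(side, FALSE, round(0.1 * visible_n0),
                     r_pattern = invisible_pattern,
                     clump_side = min(60L, side),
                     caf = inv_caf, m = inv_m)
  c(vis, list(inv))
}

#' Simulate a multi-lesion virtual patient
#'
#' Runs several independent lesion domains under one systemic dose
#' controller: each day the controller reads the summed population of all
#' lesions (including any invisible one) and the same dose is applied to
#' every lesion's update. Reports the systemic time to progression (total
#' burden reaching 120% of the total initial burden) and the emergence time
#' of the invisible lesion (its population reaching 50% of its domain's
#' carrying capacity `K * side^2`).
#'
#' @param lesions List of [lesion_spec()] objects, e.g. from
#'   [patient_case()].
#' @param strategy `"ctmtd"` or `"at"`.
#' @param params A [model_params()] object supplying the shared rates
#'   (`r_S`, `r_R`, `d_T`, `delta_D`, `alpha`, `K`, `rho`,
#'   `progression_factor`); per-lesion `m` comes from each spec.
#' @param days Days to simulate.
#' @param seed Integer seed; lesion `k` derives its own independent stream
#'   from it, so a lesion's trajectory under a constant dose matches the
#'   single-lesion simulator run at the same derived seed.
#' @param record_neighborhood Record per-day neighbourhood means per lesion.
#' @return An object of class `tumor_patient` with per-lesion time series
#'   (`ts`: long data frame `day`, `lesion`, `S`, `R`, `N`, `dose`), the
#'   dose series, `ttp`, `et` (both `NA` if censored), and the inputs.
#' @examples
#' specs <- patient_case("I", "clumped", visible_n0 = 300, side = 50)
#' pp <- model_params(L = 50, T_end = 50, m = 0)
#' pat <- simulate_patient(specs, "at", pp, days = 20, seed = 1)
#' @export
simulate_patient <- function(lesions, strategy = c("ctmtd", "at"),
                             params = model_params(L = 200L, T_end = 3500L),
                             days = params$T_end, seed = 1L,
                             record_neighborhood = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(length(lesions) >= 1L,
            all(vapply(lesions, inherits, logical(1), "lesion_spec")))
  n_invisible <- sum(!vapply(lesions, `[[`, logical(1), "visible"))
  if (n_invisible > 1L) stop("at most one invisible lesion is supported")

  lat <- vector("list", length(lesions))
  eng <- vector("list", length(lesions))
  for (k in seq_along(lesions)) {
    sp <- lesions[[k]]
    pk <- params
    pk$L <- sp$side; pk$N0 <- sp$n0; pk$f0 <- sp$f0; pk$m <- sp$m
    pk <- validate_params(pk)
    sk <- lesion_seed(seed, k)
    caf <- if (sp$caf == "scattered")
      caf_mask("FR", sp$side, n_clumps = round(0.1 * sp$side^2 / 100), seed = sk)
    else matrix(FALSE, sp$side, sp$side)
    lat[[k]] <- seed_cells(pk, sp$r_pattern, sp$clump_side, seed = sk, caf = caf)
    eng[[k]] <- engine_lesion(lat[[k]], pk, sk)
  }
  n0_each <- vapply(lat, function(l) lattice_counts(l)[["N"]], numeric(1))
  n0_total <- sum(n0_each)

  res <- .abm_run(eng, rho = params$rho, n0_ref = n0_total,
                  strategy = if (strategy == "at") 1L else 0L,
                  const_dose = 1, days = as.integer(days),
                  drug_check_after_space = FALSE,
                  record_nbhd = record_neighborhood,
                  snapshot_days = integer(0))

  dose <- as.integer(res$dose)
  ts <- do.call(rbind, lapply(seq_along(lesions), function(k) {
    m <- res$ts[[k]]
    data.frame(day = 0:days, lesion = k, S = m[, "S"], R = m[, "R"],
               N = m[, "N"], dose = c(dose, dose[length(dose)]))
  }))
  total_N <- rowSums(vapply(res$ts, function(m) m[, "N"],
                            numeric(days + 1L)))
  ttp <- detect_ttp(total_N, N0 = n0_total,
                    progression_factor = params$progression_factor)
  et <- NA_integer_
  inv <- which(!vapply(lesions, `[[`, logical(1), "visible"))
  if (length(inv) == 1L) {
    cap <- params$K * lesions[[inv]]$side^2
    hit <- which(res$ts[[inv]][, "N"] >= 0.5 * cap)
    et <- if (length(hit)) as.integer(hit[1] - 1L) else NA_integer_
  }
  structure(list(lesions = lesions, strategy = strategy, params = params,
                 seed = seed, ts = ts, dose = dose, total_N = total_N,
                 n0 = n0_each, ttp = ttp, et = et,
                 invisible_lesion = if (length(inv)) inv else NA_integer_),
            class = "tumor_patient")
}

#' @export
print.tumor_patient <- function(x, ...) {
  cat(sprintf("tumor_patient: %d lesions, %s, %d days, seed %s\n",
              length(x$lesions), toupper(x$strategy),
              length(x$total_N) - 1L, format(x$seed)))
  cat(sprintf("  total burden: %d -> %d\n", round(x$total_N[1]),
              round(x$total_N[length(x$total_N)])))
  cat(sprintf("  systemic TTP: %s   invisible-lesion ET: %s\n",
              ifelse(is.na(x$ttp), "censored", x$ttp),
              ifelse(is.na(x$et), "censored", x$et)))
  invisible(x)
}

#' Write virtual-patient outputs to CSV
#'
#' Writes one time-series CSV per lesion plus `patient_outcomes.csv`
#' (strategy, ET, TTP, censoring flags).
#'
#' @param patient A [simulate_patient()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_patient <- function(patient, dir = ".") {
  stopifnot(inherits(patient, "tumor_patient"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(patient$lesions)) {
    p <- file.path(dir, sprintf("lesion_%d_timeseries.csv", k))
    utils::write.csv(patient$ts[patient$ts$lesion == k, ], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "patient_outcomes.csv")
  utils::write.csv(data.frame(strategy = patient$strategy,
                              et = patient$et, et_censored = is.na(patient$et),
                              ttp = patient$ttp,
                              ttp_censored = is.na(patient$ttp)),
                   p, row.names = FALSE)
  invisible(c(paths, p))
}
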