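#' Run a cohort of seed-paired realizations
#'
#' Simulates `n_realizations` virtual tumours per treatment strategy, with
#' realization `i` using seed `base_seed + i - 1` for both its initial
#' lattice and its dynamics stream. When several strategies are requested
#' they share lattices and streams ("seed-paired"), so per-realization time
#' gains are well defined.
#'
#' @param params A [model_params()] object.
#' @param r_pattern,clump_side,caf_layout Initial configuration, passed to
#'   [seed_cells()].
#' @param strategies Character vector, subset of `c("ctmtd", "at")`.
#' @param n_realizations Number of realizations per strategy (default 30).
#' @param base_seed First realization seed.
#' @param days Days to simulate (defaults to `params$T_end`).
#' @param record_neighborhood Record daily mean neighbourhood counts per
#'   realization.
#' @param caf_fixed_seed If non-`NULL`, random CAF layouts (`FR`) are drawn
#'   once with this seed and frozen across realizations; by default they are
#'   re-drawn per realization.
#' @param drug_check_after_space See [simulate_tumor()].
#'
#' @return An object of class `tumor_cohort` with components:
#'   `outcomes` (per realization and strategy: `seed`, `strategy`, `ttp`,
#'   `censored`, `cycles`, `tr50`), `tg` (per-seed time gains when both
#'   strategies ran), `mean_traj` (per strategy: data frame `day`, `S`, `R`,
#'   `N` of across-realization means), `mean_ttp` (progression day of each
#'   mean trajectory), `timeseries` (long per-realization `day`, `S`, `R`,
#'   `N`, `dose`, `realization`, `strategy`), and `neighborhood` (long daily
#'   means per realization, or `NULL`).
#' @examples
#' p <- model_params(N0 = 300, L = 30, T_end = 50)
#' coh <- run_cohort(p, "random", strategies = "ctmtd", n_realizations = 2,
#'                   base_seed = 1)
#' coh$mean_ttp
#' @export
run_cohort <- function(params, r_pattern = "clumped", clump_side = 40L,
                       caf_layout = "NoF", strategies = c("ctmtd", "at"),
                       n_realizations = 30L, base_seed = 1L,
                       days = params$T_end, record_neighborhood = FALSE,
                       caf_fixed_seed = NULL, drug_check_after_space = FALSE) {
  stopifnot(inherits(params, "tumor_params"))
  strategies <- match.arg(strategies, c("ctmtd", "at"), several.ok = TRUE)
  n_realizations <- as.integer(n_realizations)
  stopifnot(n_realizations >= 1L)
  caf_frozen <- if (!is.null(caf_fixed_seed))
    caf_mask(caf_layout, params$L, seed = caf_fixed_seed) else NULL

  seeds <- base_seed + seq_len(n_realizations) - 1L
  outcomes <- list(); ts_rows <- list(); nb_rows <- list()
  Nmat <- list(); Smat <- list(); Rmat <- list()
  for (s in strategies) {
    Nmat[[s]] <- matrix(NA_real_, days + 1L, n_realizations)
    Smat[[s]] <- matrix(NA_real_, days + 1L, n_realizations)
    Rmat[[s]] <- matrix(NA_real_, days + 1L, n_realizations)
  }

  for (i in seq_len(n_realizations)) {
    lat <- seed_cells(params, r_pattern, clump_side, caf_layout,
                      seed = seeds[i], caf = caf_frozen)
    for (s in strategies) {
      sim <- simulate_tumor(params, lattice = lat, strategy = s,
                            seed = seeds[i], days = days,
                            record_neighborhood = record_neighborhood,
                            drug_check_after_space = drug_check_after_space)
      o <- sim$outcome
      outcomes[[length(outcomes) + 1L]] <- data.frame(
        seed = seeds[i], strategy = s,
        ttp = if (o$censored) days else o$ttp, censored = o$censored,
        cycles = o$cycles,
        tr50 = if (is.na(o$tr50)) NA_integer_ else o$tr50)
      Smat[[s]][, i] <- sim$ts$S
      Rmat[[s]][, i] <- sim$ts$R
      Nmat[[s]][, i] <- sim$ts$N
      ts <- sim$ts; ts$realization <- i; ts$strategy <- s
      ts_rows[[length(ts_rows) + 1L]] <- ts
      if (record_neighborhood) {
        nb <- sim$nbhd
        nb_rows[[length(nb_rows) + 1L]] <- rbind(
          data.frame(day = nb$day, realization = i, strategy = s,
                     focal_kind = "S", mean_NE = nb$S_NE, mean_NS = nb$S_NS,
                     mean_NR = nb$S_NR),
          data.frame(day = nb$day, realization = i, strategy = s,
                     focal_kind = "R", mean_NE = nb$R_NE, mean_NS = nb$R_NS,
                     mean_NR = nb$R_NR))
      }
    }
  }

  outcomes <- do.call(rbind, outcomes)
  mean_traj <- lapply(strategies, function(s)
    data.frame(day = 0:days, S = rowMeans(Smat[[s]]), R = rowMeans(Rmat[[s]]),
               N = rowMeans(Nmat[[s]])))
  names(mean_traj) <- strategies
  mean_ttp <- vapply(strategies, function(s)
    as.double(detect_ttp(mean_traj[[s]]$N, N0 = mean_traj[[s]]$N[1],
                         progression_factor = params$progression_factor)),
    numeric(1))

  tg <- NULL
  if (all(c("ctmtd", "at") %in% strategies)) {
    oc <- outcomes[outcomes$strategy == "ctmtd", ]
    oa <- outcomes[outcomes$strategy == "at", ]
    tg <- data.frame(seed = oc$seed,
                     ttp_ct = oc$ttp, ttp_at = oa$ttp[match(oc$seed, oa$seed)],
                     censored = oc$censored | oa$censored[match(oc$seed, oa$seed)])
    tg$tg <- tg$ttp_at - tg$ttp_ct
  }

  structure(list(
    params = params, r_pattern = r_pattern, caf_layout = caf_layout,
    strategies = strategies, n_realizations = n_realizations,
    base_seed = base_seed, days = days,
    outcomes = outcomes, tg = tg, mean_traj = mean_traj, mean_ttp = mean_ttp,
    timeseries = do.call(rbind, ts_rows),
    neighborhood = if (record_neighborhood) do.call(rbind, nb_rows) else NULL),
    class = "tumor_cohort")
}

#' @export
print.tumor_cohort <- function(x, ...) {
  cat(sprintf("tumor_cohort: %d realization(s), %s R-cells, CAF %s, %d days\n",
              x$n_realizations, x$r_pattern, x$caf_layout, x$days))
  for (s in x$strategies) {
    o <- x$outcomes[x$outcomes$strategy == s, ]
    cat(sprintf("  %-6s mean-trajectory TTP = %s; per-run TTP mean %.0f (sd %.0f), %d censored\n",
                toupper(s),
                ifelse(is.na(x$mean_ttp[[s]]), "censored", x$mean_ttp[[s]]),
                mean(o$ttp), stats::sd(o$ttp), sum(o$censored)))
  }
  if (!is.null(x$tg)) {
    ok <- !x$tg$censored
    cat(sprintf("  time gain (AT - CT): mean %.0f, median %.0f over %d uncensored pair(s)\n",
                mean(x$tg$tg[ok]), stats::median(x$tg$tg[ok]), sum(ok)))
  }
  invisible(x)
}

#' @export
summary.tumor_cohort <- function(object, ...) {
  agg <- do.call(rbind, lapply(object$strategies, function(s) {
    o <- object$outcomes[object$outcomes$strategy == s, ]
    data.frame(strategy = s, mean_ttp_trajectory = object$mean_ttp[[s]],
               mean_ttp = mean(o$ttp), sd_ttp = stats::sd(o$ttp),
               median_ttp = stats::median(o$ttp), censored = sum(o$censored))
  }))
  list(by_strategy = agg, tg = object$tg)
}

#' Plot cohort mean trajectories
#'
#' @param x A [run_cohort()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.tumor_cohort <- function(x, ...) {
  ymax <- max(vapply(x$mean_traj, function(m) max(m$N), numeric(1)))
  cols <- c(ctmtd = "black", at = "firebrick")
  first <- TRUE
  for (s in x$strategies) {
    m <- x$mean_traj[[s]]
    if (first) {
      graphics::plot(m$day, m$N, type = "l", col = cols[[s]], lwd = 2,
                     xlab = "day", ylab = "mean cells", ylim = c(0, ymax * 1.05),
                     ...)
      first <- FALSE
    } else graphics::lines(m$day, m$N, col = cols[[s]], lwd = 2, lty = 2)
  }
  graphics::abline(h = x$params$progression_factor * x$mean_traj[[1]]$N[1],
                   col = "cyan3", lty = 3)
  graphics::legend("topleft", toupper(x$strategies), col = cols[x$strategies],
                   lwd = 2, lty = seq_along(x$strategies), bty = "n")
  invisible(x)
}

#' Two-sample t-test with star annotation
#'
#' Welch's unequal-variance t-test by default (set `var.equal = TRUE` for
#' the pooled-variance variant), with the conventional significance stars:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' `"n.s."`. Two identical samples are reported as `t = 0`, `p = 1`.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param var.equal Use the pooled-variance Student's t-test.
#' @return List with `statistic`, `p.value`, `stars` and `method`.
#' @examples
#' two_sample_ttest(1:5, 6:10)$stars
#' @export
two_sample_ttest <- function(a, b, var.equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must have at least two observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    res <- list(statistic = 0, p.value = 1)
    method <- "degenerate (identical constant samples)"
  } else {
    tt <- stats::t.test(a, b, var.equal = var.equal)
    res <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
    method <- tt$method
  }
  res$stars <- stars_label(res$p.value)
  res$method <- method
  res
}

#' @rdname two_sample_ttest
#' @param p A p-value.
#' @export
stars_label <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

#' Predefined experiment presets
#'
#' Named argument bundles for the study-level experiments: the base
#' configurations (`base-clumped`, `base-random`, `base-uniform`, with
#' variants at `N0` of 5000 or 7000 and `f0` of 10% or 1%), the migration
#' sweep (`migration-m0` ... `migration-m4`, in multiples of `r_S`), the CAF
#' layouts (`caf-NoF` ... `caf-FR`, with `-a4` variants for `alpha = 4`) and
#' the carrying-capacity variant (`capacity-K2`). Each preset fixes the
#' model parameters and initial configuration; strategies, seeds and cohort
#' size are chosen at run time.
#'
#' @param name Preset name; call `experiment_presets()` for the full list.
#' @return List with `params` and the [run_cohort()] arguments `r_pattern`,
#'   `clump_side` and `caf_layout`.
#' @examples
#' experiment_preset("migration-m2")$params$m # 0.054
#' @export
experiment_preset <- function(name) {
  all <- experiment_presets()
  if (!name %in% names(all))
    stop(sprintf("unknown preset '%s'; see experiment_presets()", name))
  all[[name]]
}

#' @rdname experiment_preset
#' @export
experiment_presets <- function() {
  out <- list()
  add <- function(nm, params, r_pattern = "clumped", caf_layout = "NoF")
    out[[nm]] <<- list(params = params, r_pattern = r_pattern,
                       clump_side = 40L, caf_layout = caf_layout)
  for (pat in c("clumped", "random", "uniform")) {
    add(paste0("base-", pat), model_params(), r_pattern = pat)
    for (n0 in c(5000L, 7000L)) for (f0 in c(10, 1))
      add(sprintf("%s-n%d-f%g", pat, n0, f0),
          model_params(N0 = n0, f0 = f0), r_pattern = pat)
  }
  for (mult in 0:4)
    add(sprintf("migration-m%d", mult), model_params(m = mult * 0.027))
  for (lay in c("NoF", "FC", "FCp", "FSq", "FSp", "FR")) {
    add(paste0("caf-", lay), model_params(alpha = 2), caf_layout = lay)
    add(paste0("caf-", lay, "-a4"), model_params(alpha = 4), caf_layout = lay)
  }
  out[["capacity-K2"]] <- list(params = model_params(K = 2),
                               r_pattern = "clumped", clump_side = 40L,
                               caf_layout = "NoF")
  out
}

#' Write per-realization outcomes to CSV
#'
#' One row per realization and strategy: `seed`, `strategy`, `ttp`,
#' `censored`, `cycles`, `tr50`.
#'
#' @param cohort A [run_cohort()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_outcomes <- function(cohort, path) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  utils::write.csv(cohort$outcomes, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort summary table to CSV
#'
#' Per-strategy means and SDs of the progression day plus, when both
#' strategies ran, the seed-paired time-gain summary and the Welch t-test
#' comparing the two arms' progression days.
#'
#' @param cohort A [run_cohort()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(cohort, path) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  s <- summary(cohort)$by_strategy
  if (!is.null(cohort$tg)) {
    oc <- cohort$outcomes
    tt <- two_sample_ttest(oc$ttp[oc$strategy == "at"],
                           oc$ttp[oc$strategy == "ctmtd"])
    s$tg_mean <- mean(cohort$tg$tg[!cohort$tg$censored])
    s$ttest_p <- tt$p.value
    s$ttest_stars <- tt$stars
  }
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}
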