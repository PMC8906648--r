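# Independent oracles and shared fixtures for the test suite.

# Analytic per-day branch probabilities for a cell with unlimited free space,
# obtained by enumerating the daily decision tree (migration gate, event
# gate, division-vs-death split, drug check). Independent of the C++ kernel.
branch_probs <- function(params, kind = "S", dose = 1, caf = FALSE) {
  r <- if (kind == "S") params$r_S else params$r_R
  if (caf) r <- r * params$alpha
  dd <- if (kind == "S") params$delta_D * dose else 0
  m <- params$m
  list(migrate = m,
       natural_death = (1 - m) * params$d_T,
       drug_death = (1 - m) * r * dd,
       division = (1 - m) * r * (1 - dd))
}

# lattice of mutually non-interacting cells: spacing >= 3 guarantees no two
# cells share a neighbourhood site, so one-day outcomes are independent
isolated_lattice <- function(L = 300L, spacing = 3L, kind = "S", K = 1L,
                             caf_all = FALSE) {
  at <- seq(2L, L - 1L, by = spacing)
  nS <- matrix(0L, L, L); nR <- matrix(0L, L, L)
  if (kind == "S") nS[at, at] <- 1L else nR[at, at] <- 1L
  caf <- matrix(caf_all, L, L)
  new_lattice(nS, nR, caf, K = K)
}

# brute-force neighbourhood counts via vnhd(), one focal cell at a time
nbhd_brute <- function(lattice, focal_kind) {
  L <- lattice$side; K <- lattice$K
  focal <- if (focal_kind == "S") lattice$nS else lattice$nR
  rows <- list()
  for (x in seq_len(L)) for (y in seq_len(L)) {
    nf <- focal[y, x]
    if (nf == 0L) next
    nb <- vnhd(x, y, L)
    cS <- cR <- cE <- 0L
    for (i in seq_len(nrow(nb))) {
      nx <- nb[i, 1]; ny <- nb[i, 2]
      cS <- cS + lattice$nS[ny, nx]
      cR <- cR + lattice$nR[ny, nx]
      cE <- cE + K - lattice$nS[ny, nx] - lattice$nR[ny, nx]
    }
    if (K > 1) {
      cS <- cS + lattice$nS[y, x] - (focal_kind == "S")
      cR <- cR + lattice$nR[y, x] - (focal_kind == "R")
      cE <- cE + K - lattice$nS[y, x] - lattice$nR[y, x]
    }
    for (rep in seq_len(nf))
      rows[[length(rows) + 1L]] <- c(NS = cS, NR = cR, NE = cE)
  }
  if (!length(rows))
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("NS", "NR", "NE"))))
  do.call(rbind, rows)
}

# Exact one-step state distribution on a tiny lattice by exhaustive
# enumeration: average over processing orders, then over every branch of the
# daily decision tree, tracking the grid state between cells. Returns a named
# probability vector keyed by the flattened final state paste(c(nS,nR)).
enumerate_step <- function(lattice, dose, params, drug_after_space = FALSE) {
  L <- lattice$side; K <- lattice$K
  cs <- which(lattice$nS > 0L | lattice$nR > 0L, arr.ind = TRUE)
  cells <- list()
  for (i in seq_len(nrow(cs))) {
    y <- cs[i, 1]; x <- cs[i, 2]
    for (k in seq_len(lattice$nS[y, x])) cells[[length(cells) + 1L]] <- list(x = x, y = y, kind = "S")
    for (k in seq_len(lattice$nR[y, x])) cells[[length(cells) + 1L]] <- list(x = x, y = y, kind = "R")
  }
  n <- length(cells)
  stopifnot(n <= 5)
  acc <- new.env(parent = emptyenv())
  add <- function(nS, nR, p) {
    key <- paste(c(nS, nR), collapse = ",")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  free_sites <- function(nS, nR, x, y) {
    nb <- vnhd(x, y, L)
    nb[nS[cbind(nb[, 2], nb[, 1])] + nR[cbind(nb[, 2], nb[, 1])] < K, ,
       drop = FALSE]
  }
  # free daughter slots: VNHD slots plus own spare when K > 1, one entry per slot
  free_slots <- function(nS, nR, x, y) {
    nb <- vnhd(x, y, L)
    out <- list()
    for (i in seq_len(nrow(nb))) {
      cap <- K - nS[nb[i, 2], nb[i, 1]] - nR[nb[i, 2], nb[i, 1]]
      if (cap > 0) for (j in seq_len(cap)) out[[length(out) + 1L]] <- nb[i, ]
    }
    if (K > 1) {
      cap <- K - nS[y, x] - nR[y, x]
      if (cap > 0) for (j in seq_len(cap)) out[[length(out) + 1L]] <- c(x, y)
    }
    out
  }
  recurse <- function(order, i, pos, nS, nR, p) {
    if (p <= 0) return()
    if (i > length(order)) { add(nS, nR, p); return() }
    ci <- order[i]
    x <- pos[[ci]][1]; y <- pos[[ci]][2]
    kind <- cells[[ci]]$kind
    alive <- pos[[ci]][3] == 1
    if (!alive) { recurse(order, i + 1L, pos, nS, nR, p); return() }
    r <- if (kind == "S") params$r_S else params$r_R
    if (lattice$caf[y, x]) r <- r * params$alpha
    dd <- if (kind == "S") params$delta_D * dose else 0
    m <- params$m
    stay_p <- 1 - m - (1 - m) * (r + params$d_T)
    # migration branch
    if (m > 0) {
      fs <- free_sites(nS, nR, x, y)
      if (nrow(fs) == 0) {
        recurse(order, i + 1L, pos, nS, nR, p * m)
      } else {
        for (t in seq_len(nrow(fs))) {
          nS2 <- nS; nR2 <- nR; pos2 <- pos
          tx <- fs[t, 1]; ty <- fs[t, 2]
          if (kind == "S") { nS2[y, x] <- nS2[y, x] - 1L; nS2[ty, tx] <- nS2[ty, tx] + 1L }
          else { nR2[y, x] <- nR2[y, x] - 1L; nR2[ty, tx] <- nR2[ty, tx] + 1L }
          pos2[[ci]] <- c(tx, ty, 1)
          recurse(order, i + 1L, pos2, nS2, nR2, p * m / nrow(fs))
        }
      }
    }
    base <- (1 - m)
    # natural death
    {
      nS2 <- nS; nR2 <- nR; pos2 <- pos
      if (kind == "S") nS2[y, x] <- nS2[y, x] - 1L else nR2[y, x] <- nR2[y, x] - 1L
      pos2[[ci]] <- c(x, y, 0)
      recurse(order, i + 1L, pos2, nS2, nR2, p * base * params$d_T)
    }
    # division attempt
    div_p <- p * base * r
    slots <- free_slots(nS, nR, x, y)
    place <- function(pp) {
      if (length(slots) == 0) { recurse(order, i + 1L, pos, nS, nR, pp); return() } # blocked
      for (sl in slots) {
        nS2 <- nS; nR2 <- nR
        if (kind == "S") nS2[sl[2], sl[1]] <- nS2[sl[2], sl[1]] + 1L
        else nR2[sl[2], sl[1]] <- nR2[sl[2], sl[1]] + 1L
        recurse(order, i + 1L, pos, nS2, nR2, pp / length(slots))
      }
    }
    kill_drug <- function(pp) {
      nS2 <- nS; nR2 <- nR; pos2 <- pos
      if (kind == "S") nS2[y, x] <- nS2[y, x] - 1L else nR2[y, x] <- nR2[y, x] - 1L
      pos2[[ci]] <- c(x, y, 0)
      recurse(order, i + 1L, pos2, nS2, nR2, pp)
    }
    if (!drug_after_space) {
      if (dd > 0) kill_drug(div_p * dd)
      place(div_p * (1 - dd))
    } else {
      if (length(slots) == 0) {
        recurse(order, i + 1L, pos, nS, nR, div_p) # blocked, no drug check
      } else {
        if (dd > 0) kill_drug(div_p * dd)
        place(div_p * (1 - dd))
      }
    }
    # stay
    recurse(order, i + 1L, pos, nS, nR, p * stay_p)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  pos0 <- lapply(cells, function(cl) c(cl$x, cl$y, 1))
  ords <- perms(seq_len(n))
  for (o in ords)
    recurse(o, 1L, pos0, lattice$nS, lattice$nR, 1 / length(ords))
  # no normalization: tests assert the enumerated masses sum to one
  unlist(as.list(acc))
}

# turn engine step replicates into a table of state keys matching the oracle
replicate_keys <- function(reps) {
  apply(reps, 1L, paste, collapse = ",")
}

# tweak fields of a parameter object (re-validate with validate_params)
within_list <- function(p, ...) {
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

withr_like_tempdir <- function() {
  d <- tempfile("latticeAT-test-")
  dir.create(d)
  d
}

# memoized cohorts shared across acceptance tests (the suite runs each
# configuration once even though several criteria consume it)
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, ...) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- run_cohort(...)
  .cohort_cache[[key]]
}
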