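#' Construct an initial cell configuration
#'
#' Places `S(0) = N0 - R(0)` sensitive cells uniformly at random over the
#' whole domain and `R(0) = round(f0/100 * N0)` resistant cells according to
#' one of three dispersion patterns:
#'
#' * `"clumped"` - uniformly at random within a centred
#'   `clump_side x clump_side` square;
#' * `"random"` - uniformly at random over the whole domain;
#' * `"uniform"` - on a deterministic, evenly spaced grid approximating
#'   maximal pairwise distance. Sensitive cells displaced by the grid are
#'   relocated to random free slots.
#'
#' No slot ever holds two cells; with `K = 2` a site may hold two.
#'
#' @param params A [model_params()] object (supplies `N0`, `f0`, `L`, `K`).
#' @param r_pattern Resistant-cell dispersion pattern.
#' @param clump_side Side of the centred square used by `"clumped"`.
#' @param caf_layout CAF layout name passed to [caf_mask()], or `"NoF"`.
#' @param seed Optional integer seed; the same seed reproduces the identical
#'   lattice. The caller's RNG state is left untouched.
#' @param caf Optional pre-built logical CAF mask overriding `caf_layout`
#'   (used, e.g., to freeze one random layout across realizations).
#' @return A [new_lattice()] object.
#' @examples
#' lat <- seed_cells(model_params(), "clumped", seed = 1)
#' lattice_counts(lat) # 4500 S, 500 R
#' @export
seed_cells <- function(params, r_pattern = c("clumped", "random", "uniform"),
                       clump_side = 40L, caf_layout = "NoF", seed = NULL,
                       caf = NULL) {
  stopifnot(inherits(params, "tumor_params"))
  r_pattern <- match.arg(r_pattern)
  L <- params$L; K <- params$K
  R0 <- as.integer(round(params$f0 / 100 * params$N0))
  S0 <- params$N0 - R0
  if (params$N0 > K * L^2) stop("N0 exceeds the domain capacity")
  if (r_pattern == "clumped") {
    clump_side <- as.integer(clump_side)
    if (clump_side < 1L || clump_side > L) stop("'clump_side' must lie in [1, L]")
    if (R0 > K * clump_side^2) stop("R(0) exceeds the clump capacity")
  }
  with_seed(seed, {
    if (is.null(caf)) caf <- caf_mask(caf_layout, L)
    nS <- matrix(0L, L, L); nR <- matrix(0L, L, L)

    # sensitive cells: uniform over all K*L^2 slots
    if (S0 > 0L) {
      slot <- sample.int(K * L^2, S0)
      site <- (slot - 1L) %/% K + 1L
      tab <- tabulate(site, nbins = L^2)
      nS[] <- as.integer(tab)
    }
    free_pool <- function(sites) {
      # one entry per free slot, carrying its site index
      cap <- K - nS[sites] - nR[sites]
      rep(sites, pmax(cap, 0L))
    }
    if (R0 > 0L) {
      if (r_pattern %in% c("clumped", "random")) {
        sites <- if (r_pattern == "random") seq_len(L^2) else {
          a <- (L - clump_side) %/% 2L + 1L
          idx <- a:(a + clump_side - 1L)
          as.vector(outer(idx, idx, function(y, x) (x - 1L) * L + y))
        }
        pool <- free_pool(sites)
        if (length(pool) < R0) stop("insufficient free capacity for R-cells")
        pick <- pool[sample.int(length(pool), R0)]
        tab <- tabulate(pick, nbins = L^2)
        nR <- nR + as.integer(tab)
      } else {
        sites <- uniform_grid_sites(L, R0)
        displaced <- 0L
        for (s in sites) {
          if (nS[s] + nR[s] >= K) { # evict one S; the R grid takes priority
            nS[s] <- nS[s] - 1L
            displaced <- displaced + 1L
          }
          nR[s] <- nR[s] + 1L
        }
        if (displaced > 0L) {
          pool <- free_pool(seq_len(L^2))
          if (length(pool) < displaced) stop("insufficient free capacity for S-cells")
          pick <- pool[sample.int(length(pool), displaced)]
          tab <- tabulate(pick, nbins = L^2)
          nS <- nS + as.integer(tab)
        }
      }
    }
    lat <- new_lattice(nS, nR, caf, K)
    lat$r_pattern <- r_pattern
    lat
  })
}

# deterministic near-square grid of R0 sites, evenly spaced over [1, L]^2
uniform_grid_sites <- function(L, R0) {
  rows <- ceiling(sqrt(R0))
  cols <- ceiling(R0 / rows)
  at <- function(i, n) as.integer(pmin(pmax(round((i - 0.5) * L / n), 1L), L))
  xs <- at(seq_len(cols), cols)
  ys <- at(seq_len(rows), rows)
  pos <- expand.grid(x = xs, y = ys)[seq_len(R0), , drop = FALSE]
  (pos$x - 1L) * L + pos$y
}

#' CAF layout masks
#'
#' Builds the static fibroblast mask for one of the named layouts, each
#' covering about 10% of a 100 x 100 domain:
#'
#' * `NoF` - no fibroblasts;
#' * `FC` - centred 32 x 32 square (1024 sites), overlapping the central
#'   R-cell clump;
#' * `FCp` - inclusive rectangle with corners (17, 35) and (49, 66)
#'   (1056 sites), partially overlapping the clump;
#' * `FSq` - hollow square between (23, 23) and (77, 77) with wall
#'   thickness 5 (1000 sites), fully surrounding the clump;
#' * `FSp` - L-shaped region with vertices (21, 25), (30, 25), (30, 71),
#'   (75, 71), (75, 80), (21, 80) (1010 sites), partially surrounding it;
#' * `FR` - `n_clumps` axis-aligned 10 x 10 squares placed uniformly at
#'   random, mutually non-overlapping and fully inside the domain.
#'
#' The fixed geometries require `L = 100`; `NoF`, `FC` and `FR` scale to
#' other side lengths. Custom geometries can be supplied as a list of
#' inclusive rectangles `c(x1, y1, x2, y2)` via `rects`.
#'
#' @param layout Layout name, or `"custom"` together with `rects`.
#' @param L Lattice side length.
#' @param n_clumps Number of random 10 x 10 clumps for `FR` (default keeps
#'   coverage at 10% of the domain).
#' @param seed Optional seed for the `FR` placement.
#' @param rects For `layout = "custom"`: list of inclusive rectangles.
#' @return An `L x L` logical matrix.
#' @examples
#' sum(caf_mask("FSq")) # 1000
#' @export
caf_mask <- function(layout = c("NoF", "FC", "FCp", "FSq", "FSp", "FR", "custom"),
                     L = 100L, n_clumps = round(0.1 * L^2 / 100), seed = NULL,
                     rects = NULL) {
  layout <- match.arg(layout)
  L <- as.integer(L)
  mask <- matrix(FALSE, L, L)
  fill <- function(mask, r) { # r = c(x1, y1, x2, y2), inclusive corners
    xs <- sort(c(r[1], r[3])); ys <- sort(c(r[2], r[4]))
    if (xs[1] < 1 || ys[1] < 1 || xs[2] > L || ys[2] > L)
      stop("rectangle outside the domain")
    mask[ys[1]:ys[2], xs[1]:xs[2]] <- TRUE
    mask
  }
  need100 <- function() if (L != 100L)
    stop("this canonical geometry is defined for L = 100; use layout = 'custom'")
  switch(layout,
    NoF = mask,
    FC = {
      side <- 32L
      if (L < side) stop("domain too small for the 32 x 32 square")
      a <- (L - side) %/% 2L + 1L
      fill(mask, c(a, a, a + side - 1L, a + side - 1L))
    },
    FCp = { need100(); fill(mask, c(17, 35, 49, 66)) },
    FSq = {
      need100()
      outer <- fill(mask, c(23, 23, 77, 77))
      outer[28:72, 28:72] <- FALSE
      outer
    },
    FSp = {
      need100()
      mask <- fill(mask, c(21, 25, 30, 80))
      fill(mask, c(30, 71, 75, 80))
    },
    FR = with_seed(seed, {
      if (L < 10L) stop("domain too small for 10 x 10 clumps")
      placed <- matrix(NA_integer_, 0, 2)
      tries <- 0L
      while (nrow(placed) < n_clumps) {
        if ((tries <- tries + 1L) > 10000L)
          stop("could not place non-overlapping CAF clumps")
        x <- sample.int(L - 9L, 1L); y <- sample.int(L - 9L, 1L)
        ok <- nrow(placed) == 0L ||
          all(abs(placed[, 1] - x) >= 10L | abs(placed[, 2] - y) >= 10L)
        if (ok) placed <- rbind(placed, c(x, y))
      }
      for (i in seq_len(nrow(placed)))
        mask <- fill(mask, c(placed[i, 1], placed[i, 2],
                             placed[i, 1] + 9L, placed[i, 2] + 9L))
      mask
    }),
    custom = {
      if (is.null(rects)) stop("layout = 'custom' requires 'rects'")
      for (r in rects) mask <- fill(mask, r)
      mask
    })
}
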