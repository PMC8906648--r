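#' Lattice state
#'
#' A `tumor_lattice` stores the occupancy of an `L x L` grid as two integer
#' count matrices (`nS`, `nR`, indexed `[y, x]`) together with the static CAF
#' mask. Coordinates are 1-based with `x` the column and `y` the row;
#' individual capacity slots within a site are unordered, so per-site counts
#' are the complete state.
#'
#' @param nS,nR Integer matrices of per-site sensitive / resistant counts.
#' @param caf Logical matrix marking fibroblast sites (defaults to none).
#' @param K Per-site carrying capacity (1 or 2).
#' @return An object of class `tumor_lattice`.
#' @export
new_lattice <- function(nS, nR = NULL, caf = NULL, K = 1L) {
  nS <- as.matrix(nS)
  L <- nrow(nS)
  if (ncol(nS) != L) stop("lattice must be square")
  if (is.null(nR)) nR <- matrix(0L, L, L)
  if (is.null(caf)) caf <- matrix(FALSE, L, L)
  storage.mode(nS) <- "integer"
  nR <- as.matrix(nR); storage.mode(nR) <- "integer"
  caf <- as.matrix(caf); storage.mode(caf) <- "logical"
  if (!all(dim(nR) == L) || !all(dim(caf) == L))
    stop("'nS', 'nR' and 'caf' must all be L x L")
  K <- as.integer(K)
  if (!K %in% c(1L, 2L)) stop("'K' must be 1 or 2")
  if (any(nS < 0L) || any(nR < 0L) || any(nS + nR > K))
    stop("site occupancy must lie in [0, K] everywhere")
  structure(list(side = L, K = K, nS = nS, nR = nR, caf = caf),
            class = "tumor_lattice")
}

#' @export
print.tumor_lattice <- function(x, ...) {
  n <- lattice_counts(x)
  cat(sprintf("tumor_lattice: %d x %d, K = %d | S = %d, R = %d, N = %d | CAF sites = %d\n",
              x$side, x$side, x$K, n[["S"]], n[["R"]], n[["N"]], sum(x$caf)))
  invisible(x)
}

#' Cell counts on a lattice
#'
#' @param lattice A [new_lattice()] object.
#' @return Named integer vector with components `S`, `R` and `N`.
#' @export
lattice_counts <- function(lattice) {
  stopifnot(inherits(lattice, "tumor_lattice"))
  s <- sum(lattice$nS); r <- sum(lattice$nR)
  c(S = s, R = r, N = s + r)
}

#' Von Neumann neighbourhood of a site
#'
#' Returns the orthogonally adjacent sites (east, west, south, north) that
#' lie inside the closed domain; the boundary never wraps, so corners have 2
#' neighbours and edges 3.
#'
#' @param x,y 1-based site coordinates (`x` = column, `y` = row).
#' @param L Lattice side length, or a [new_lattice()] object.
#' @return A two-column integer matrix of `(x, y)` neighbour coordinates.
#' @examples
#' nrow(vnhd(50, 50, 100)) # 4 in the interior
#' vnhd(1, 1, 100)         # corner: 2 neighbours
#' @export
vnhd <- function(x, y, L) {
  if (inherits(L, "tumor_lattice")) L <- L$side
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      x < 1 || x > L || y < 1 || y > L || x != round(x) || y != round(y))
    stop("coordinates must be integers in [1, L]")
  cand <- cbind(x = c(x + 1L, x - 1L, x, x), y = c(y, y, y + 1L, y - 1L))
  keep <- cand[, 1L] >= 1L & cand[, 1L] <= L & cand[, 2L] >= 1L & cand[, 2L] <= L
  m <- cand[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Free capacity of a site
#'
#' @inheritParams vnhd
#' @param lattice A [new_lattice()] object.
#' @return Integer: `K` minus the current occupancy of site `(x, y)`.
#' @export
free_capacity <- function(lattice, x, y) {
  stopifnot(inherits(lattice, "tumor_lattice"))
  vnhd(x, y, lattice$side) # reuse coordinate validation
  lattice$K - lattice$nS[y, x] - lattice$nR[y, x]
}

#' Integer snapshot coding of a lattice
#'
#' Encodes each site as 0 (empty), 1 (sensitive only), 2 (resistant only) or
#' 3 (mixed, possible when `K = 2`).
#'
#' @param lattice A [new_lattice()] object.
#' @return An `L x L` integer matrix.
#' @export
snapshot_matrix <- function(lattice) {
  stopifnot(inherits(lattice, "tumor_lattice"))
  code <- matrix(0L, lattice$side, lattice$side)
  code[lattice$nS > 0L] <- 1L
  code[lattice$nR > 0L] <- 2L
  code[lattice$nS > 0L & lattice$nR > 0L] <- 3L
  code
}

#' Write grid snapshots to CSV
#'
#' Writes one `snapshot_d{day}.csv` per recorded day (integer site codes as
#' produced by [snapshot_matrix()]) plus a `caf_mask.csv` of 0/1 flags.
#'
#' @param sim A [simulate_tumor()] result with recorded snapshots.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_snapshots <- function(sim, dir = ".") {
  stopifnot(inherits(sim, "tumor_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sim$snapshots)) {
    day <- sub("^day", "", nm)
    p <- file.path(dir, sprintf("snapshot_d%s.csv", day))
    utils::write.table(sim$snapshots[[nm]], p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "caf_mask.csv")
  utils::write.table(sim$lattice$caf * 1L, p, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paths, p))
}

# lesion spec list consumed by the C++ kernel
engine_lesion <- function(lattice, params, seed) {
  list(nS = lattice$nS, nR = lattice$nR, caf = lattice$caf, K = lattice$K,
       r_S = params$r_S, r_R = params$r_R, d_T = params$d_T,
       delta_D = params$delta_D, m = params$m, alpha = params$alpha,
       seed = as.double(seed))
}
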