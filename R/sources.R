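#' Constant-value disk source
#'
#' A disk region where the field is held at a constant value in `(0, 1]`,
#' caricaturing a blood-vessel cross section with fixed oxygen tension.
#' Pixel centers sit at integer coordinates `0 .. L-1` (row-major, 0-based);
#' a pixel belongs to the disk iff the Euclidean distance from its center to
#' the disk center is `<= radius`. The disk must be fully contained in the
#' domain under this membership rule.
#'
#' @param center_row,center_col disk center coordinates (pixels, 0-based).
#' @param radius disk radius in pixels (> 0).
#' @param value source field strength, in `(0, 1]`.
#' @return An object of class `source_disk`.
#' @export
source_disk <- function(center_row, center_col, radius, value) {
  stopifnot(is.numeric(center_row), is.numeric(center_col),
            radius > 0, value > 0, value <= 1)
  structure(list(center_row = as.double(center_row),
                 center_col = as.double(center_col),
                 radius = as.double(radius),
                 value = as.double(value)),
            class = "source_disk")
}

#' Source configuration: a set of disks on a grid
#'
#' Validates containment (no member pixel outside the lattice) and strict
#' non-overlap (pairwise center distance `> 2 * radius`, so disks cannot even
#' touch and their pixel sets are disjoint under the membership rule).
#'
#' @param disks list of [source_disk()] objects (may be empty).
#' @param grid a [grid_spec()].
#' @return An object of class `source_configuration`.
#' @export
source_configuration <- function(disks, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.list(disks))
  for (d in disks) {
    if (!inherits(d, "source_disk")) stop("disks must be source_disk objects")
    lo <- d$radius
    hi <- grid$L - 1 - d$radius
    if (d$center_row < lo || d$center_row > hi ||
        d$center_col < lo || d$center_col > hi)
      stop(sprintf("disk at (%g, %g) with radius %g is not fully contained in [0, %d]^2",
                   d$center_row, d$center_col, d$radius, grid$L - 1L))
  }
  if (length(disks) >= 2) {
    for (i in seq_len(length(disks) - 1L)) {
      for (j in seq(i + 1L, length(disks))) {
        di <- disks[[i]]; dj <- disks[[j]]
        dist <- sqrt((di$center_row - dj$center_row)^2 +
                     (di$center_col - dj$center_col)^2)
        if (dist <= di$radius + dj$radius)
          stop(sprintf("disks %d and %d overlap or touch (center distance %g <= %g)",
                       i, j, dist, di$radius + dj$radius))
      }
    }
  }
  structure(list(disks = disks, grid = grid), class = "source_configuration")
}

#' @export
print.source_configuration <- function(x, ...) {
  cat(sprintf("<source_configuration> %d disk(s) on %d x %d grid\n",
              length(x$disks), x$grid$L, x$grid$L))
  for (d in x$disks)
    cat(sprintf("  center (%g, %g), radius %g, value %.4f\n",
                d$center_row, d$center_col, d$radius, d$value))
  invisible(x)
}

#' Draw a random admissible source configuration
#'
#' Samples `n_disks` disk centers at integer pixel coordinates uniformly over
#' the admissible box `[radius, L-1-radius]^2`, rejecting draws in which any
#' pair of centers lies at distance `<= 2 * radius` (overlapping or touching
#' disks). The first disk has value 1; every further disk draws its value
#' uniformly from `(0, 1]`.
#'
#' @param grid a [grid_spec()].
#' @param radius common disk radius in pixels.
#' @param n_disks number of disks (default 2).
#' @param seed optional integer seed; when given, the draw is a pure function
#'   of the seed and does not disturb the caller's RNG stream.
#' @param max_tries rejection-sampling attempt bound; exceeding it is an error
#'   (the geometry is too crowded).
#' @return A [source_configuration()].
#' @export
sample_configuration <- function(grid, radius = 5, n_disks = 2L,
                                 seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(grid, "grid_spec"), radius > 0, n_disks >= 1)
  lo <- ceiling(radius)
  hi <- floor(grid$L - 1 - radius)
  if (hi < lo) stop("radius too large for this grid: no admissible centers")
  with_seed(seed, {
    for (attempt in seq_len(max_tries)) {
      rows <- sample(lo:hi, n_disks, replace = TRUE)
      cols <- sample(lo:hi, n_disks, replace = TRUE)
      ok <- TRUE
      if (n_disks >= 2) {
        dmat <- as.matrix(stats::dist(cbind(rows, cols)))
        ok <- all(dmat[upper.tri(dmat)] > 2 * radius)
      }
      if (ok) {
        values <- c(1, 1 - stats::runif(n_disks - 1L))  # uniform on (0, 1]
        disks <- lapply(seq_len(n_disks), function(i)
          source_disk(rows[i], cols[i], radius, values[i]))
        return(source_configuration(disks, grid))
      }
    }
    stop(sprintf("no admissible placement found in %d rejection attempts", max_tries))
  })
}

#' Rasterize a source configuration into the input image
#'
#' Produces the `L` x `L` source-layout image: pixel `(r, c)` (0-based integer
#' centers) carries the disk's value iff its Euclidean distance to the disk
#' center is `<= radius`, and 0 elsewhere. Non-overlap guarantees disks never
#' share pixels.
#'
#' @param config a [source_configuration()].
#' @return An `L` x `L` numeric matrix with values in `[0, 1]`.
#' @export
rasterize <- function(config) {
  stopifnot(inherits(config, "source_configuration"))
  L <- config$grid$L
  img <- matrix(0, L, L)
  coord <- 0:(L - 1)
  for (d in config$disks) {
    rr <- (coord - d$center_row)^2
    cc <- (coord - d$center_col)^2
    member <- outer(rr, cc, "+") <= d$radius^2
    img[member] <- d$value
  }
  img
}
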