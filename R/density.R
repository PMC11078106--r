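# Smoothed 2D histograms ("density maps") of synapse and dendrite positions.
#
# The smoother is a second-order difference-penalty (Whittaker) smoother
# applied separably along rows then columns. Its penalty annihilates
# constants, so the all-ones vector is an eigenvector of (I + lambda D'D)
# with eigenvalue 1 and total mass is conserved exactly for any lambda.

# solve (I + lambda D2'D2) z = y for every column of M
whittaker_smooth <- function(M, lambda) {
  smooth_cols <- function(A) {
    n <- nrow(A)
    if (n < 3 || lambda == 0) return(A)
    D <- diff(diag(n), differences = 2)
    W <- diag(n) + lambda * crossprod(D)
    solve(W, A)
  }
  M <- smooth_cols(M)
  t(smooth_cols(t(M)))
}

# mass-preserving Gaussian kernel alternative (column-normalised operator)
gaussian_smooth <- function(M, lambda) {
  smooth_cols <- function(A) {
    n <- nrow(A)
    if (n < 2 || lambda == 0) return(A)
    s <- sqrt(lambda)
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-0.5 * (i - j)^2 / s^2))
    K <- sweep(K, 2, colSums(K), "/")   # each source bin redistributes mass 1
    K %*% A
  }
  M <- smooth_cols(M)
  t(smooth_cols(t(M)))
}

#' Smoothed 2D histogram of planar point positions
#'
#' Bins the x-y coordinates on a grid over the bounding box padded by one
#' bin, then applies a second-order Whittaker smoother with penalty
#' `lambda` separably along both axes. Smoothing conserves total mass:
#' the grid always sums to the number of points (to 1e-9 relative).
#' `lambda = 0` returns the raw histogram bit-exactly. The grid origin is
#' snapped to a bin multiple so maps of translated point sets are
#' translated maps.
#'
#' @param points two-column matrix/data.frame of x-y coordinates (um).
#' @param bin_size bin edge length (um), > 0.
#' @param lambda smoothing penalty, >= 0 (default 1, the minimum smoothing
#'   used for the published maps).
#' @param smoother "whittaker" (default) or "gaussian" (sensitivity check).
#' @return A `density_map`: `origin` (x, y of the lower-left grid corner),
#'   `bin_size`, `values` (matrix, rows = x bins, cols = y bins), `lambda`,
#'   `n_points`, `normalization`.
#' @export
density_map <- function(points, bin_size, lambda = 1,
                        smoother = c("whittaker", "gaussian")) {
  smoother <- match.arg(smoother)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (!nrow(pts)) stop("need at least one point")
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  origin <- c(floor(min(pts[, 1]) / bin_size) - 1,
              floor(min(pts[, 2]) / bin_size) - 1) * bin_size
  nx <- floor((max(pts[, 1]) - origin[1]) / bin_size) + 2L
  ny <- floor((max(pts[, 2]) - origin[2]) / bin_size) + 2L
  ix <- floor((pts[, 1] - origin[1]) / bin_size) + 1L
  iy <- floor((pts[, 2] - origin[2]) / bin_size) + 1L
  counts <- matrix(0, nx, ny)
  counts[] <- tabulate(ix + (iy - 1L) * nx, nbins = nx * ny)
  values <- counts
  if (lambda > 0) {
    values <- switch(smoother,
                     whittaker = whittaker_smooth(counts, lambda),
                     gaussian = gaussian_smooth(counts, lambda))
    # The penalized smoother conserves mass exactly but can ring below
    # zero next to sharp peaks. Clamp, then rescale so the map still sums
    # to the point count.
    if (any(values < 0)) {
      values[values < 0] <- 0
      values <- values * (nrow(pts) / sum(values))
    }
  }
  structure(list(origin = origin, bin_size = bin_size, values = values,
                 lambda = lambda, n_points = nrow(pts),
                 normalization = "none"),
            class = "density_map")
}

#' Normalize density maps to \[0, 1\]
#'
#' Independent normalization divides each map by its own maximum (used when
#' maps are displayed on their own color scales); joint normalization
#' divides all maps by the global maximum (used to show relative
#' contributions across maps). All-zero maps are left unchanged.
#'
#' @param maps list of `density_map` objects (or a single map).
#' @param mode "independent" or "joint".
#' @return List of rescaled maps.
#' @export
normalize_maps <- function(maps, mode = c("independent", "joint")) {
  mode <- match.arg(mode)
  if (inherits(maps, "density_map")) maps <- list(maps)
  if (!length(maps)) stop("need at least one map")
  maxima <- vapply(maps, function(m) max(m$values), numeric(1))
  global <- max(maxima)
  lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    div <- if (mode == "independent") maxima[i] else global
    if (div > 0) m$values <- m$values / div
    m$normalization <- mode
    m
  })
}

#' Default density-map bin size for a dendritic field
#'
#' Bin sizes scale with the dendritic-field diameter: diameter/15.8 for
#' synapse maps and diameter/24.3 for dendrite maps (a 153.1 um field gives
#' 9.7 and 6.3 um). Always overridable.
#'
#' @param role "synapse" or "dendrite".
#' @param field_diameter equivalent hull diameter in um, > 0.
#' @return Bin size in um.
#' @export
default_bin_size <- function(role = c("synapse", "dendrite"),
                             field_diameter) {
  role <- match.arg(role)
  if (!is.numeric(field_diameter) || field_diameter <= 0)
    stop("field_diameter must be > 0")
  field_diameter / switch(role, synapse = 15.8, dendrite = 24.3)
}

#' Write / read a density map as delimited text
#'
#' Three header lines (origin, bin size, lambda) followed by the
#' tab-separated grid, rows = x bins.
#'
#' @param map a `density_map`.
#' @param path output file.
#' @return `path` invisibly; `read_density_map` returns the map.
#' @export
write_density_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin %.17g %.17g", map$origin[1], map$origin[2]),
               sprintf("# bin_size %.17g", map$bin_size),
               sprintf("# lambda %.17g", map$lambda)), con)
  utils::write.table(map$values, con, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  hdr <- readLines(path, n = 3)
  num <- function(line) as.numeric(strsplit(line, " ")[[1]][-(1:2)])
  origin <- num(hdr[1])
  bin_size <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
  lambda <- as.numeric(strsplit(hdr[3], " ")[[1]][3])
  values <- as.matrix(utils::read.table(path, skip = 3, sep = "\t"))
  dimnames(values) <- NULL
  structure(list(origin = origin, bin_size = bin_size, values = values,
                 lambda = lambda, n_points = sum(values),
                 normalization = "none"),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d x %d bins of %.2f um, lambda = %g, %d points\n",
    nrow(x$values), ncol(x$values), x$bin_size, x$lambda,
    round(x$n_points)))
  invisible(x)
}
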