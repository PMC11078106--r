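# Dendritic-field morphometry: convex hulls, soma diameter, IPL depth.

#' Convex hull metrics of a 2D point set
#'
#' The dendritic-field diameter is reported as the equivalent circular
#' diameter of the convex hull, 2*sqrt(area/pi), because dendritic fields
#' can be asymmetric. The centroid is the area centroid of the hull polygon.
#'
#' @param points two-column matrix or data.frame of x-y coordinates (um).
#' @return A `hull_metrics` list: `vertices` (counter-clockwise matrix),
#'   `area` (um^2), `equivalent_diameter` (um), `centroid` (x, y).
#' @export
convex_hull_metrics <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  if (nrow(pts) < 3)
    stop("degenerate geometry: need at least 3 distinct points")
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  if (nrow(v) < 3)
    stop("degenerate geometry: points are collinear")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a_signed <- sum(cross) / 2
  if (abs(a_signed) < 1e-12)
    stop("degenerate geometry: points are collinear")
  if (a_signed < 0) {           # orient counter-clockwise
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    x <- v[, 1]; y <- v[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- x * yn - xn * y
    a_signed <- sum(cross) / 2
  }
  centroid <- c(sum((x + xn) * cross), sum((y + yn) * cross)) /
    (6 * a_signed)
  structure(list(vertices = unname(v), area = a_signed,
                 equivalent_diameter = 2 * sqrt(a_signed / pi),
                 centroid = unname(centroid)),
            class = "hull_metrics")
}

#' Convex hull of a cell's dendritic field
#'
#' Axon- and soma-tagged nodes are excluded: the field is the 2D polygon
#' bounding the dendritic annotations only.
#'
#' @param reconstruction a `neuron_reconstruction`.
#' @return A `hull_metrics`.
#' @export
dendritic_field_hull <- function(reconstruction) {
  dend <- reconstruction$nodes[reconstruction$nodes$tag == "dendrite", ]
  if (nrow(dend) < 3)
    stop("cell ", reconstruction$cell_id, ": fewer than 3 dendrite nodes")
  convex_hull_metrics(cbind(dend$x_um, dend$y_um))
}

#' Soma diameter of a reconstruction
#'
#' Twice the maximum disk radius among soma-tagged nodes (the widest
#' annotated soma profile).
#'
#' @param reconstruction a `neuron_reconstruction`.
#' @return Diameter in um.
#' @export
soma_diameter <- function(reconstruction) {
  soma <- reconstruction$nodes[reconstruction$nodes$tag == "soma", ]
  if (!nrow(soma))
    stop("cell ", reconstruction$cell_id, ": no soma-tagged node")
  2 * max(soma$radius_um)
}

#' IPL depth profile of a set of nodes
#'
#' Depth is 100 * (z - inl_ipl_z) / (ipl_gcl_z - inl_ipl_z) percent, so the
#' INL/IPL boundary is 0% and the IPL/GCL boundary 100%. The mean is the
#' arithmetic mean; the mode is the center of the most populated histogram
#' bin (bins anchored at 0, ties broken toward the shallower bin).
#'
#' @param nodes data.frame with a `z_um` column (or numeric z values).
#' @param ipl_boundaries list with `inl_ipl_z` and `ipl_gcl_z` (distinct).
#' @param bin_width mode histogram bin width in percent (default 1).
#' @return A `depth_profile` list: `depths`, `mean_depth`, `mode_depth`,
#'   `bin_width`.
#' @export
depth_profile <- function(nodes, ipl_boundaries, bin_width = 1) {
  z <- if (is.data.frame(nodes)) nodes$z_um else as.numeric(nodes)
  z0 <- ipl_boundaries$inl_ipl_z
  z1 <- ipl_boundaries$ipl_gcl_z
  if (!length(z)) stop("no nodes")
  if (z1 == z0) stop("coincident IPL boundaries")
  depths <- 100 * (z - z0) / (z1 - z0)
  bins <- floor(depths / bin_width)      # bin k covers [k*w, (k+1)*w)
  tab <- table(bins)
  best <- as.numeric(names(tab))[tab == max(tab)]
  mode_depth <- (min(best) + 0.5) * bin_width   # ties -> shallower bin
  structure(list(depths = depths, mean_depth = mean(depths),
                 mode_depth = mode_depth, bin_width = bin_width),
            class = "depth_profile")
}

#' Pooled-variance two-sample t test
#'
#' Two-sided Student's t test with pooled variance, as used to compare
#' soma diameters and mean stratification depths between cell classes.
#' When the pooled variance is zero: p = 1 if the means agree (by
#' convention), p = 0 otherwise.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t` and `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2")
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  res <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), p = res$p.value)
}

#' @export
print.hull_metrics <- function(x, ...) {
  cat(sprintf(
    "<hull_metrics> area %.1f um^2, equivalent diameter %.1f um, centroid (%.1f, %.1f)\n",
    x$area, x$equivalent_diameter, x$centroid[1], x$centroid[2]))
  invisible(x)
}
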