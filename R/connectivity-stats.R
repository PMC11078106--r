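# Connectivity statistics: amacrine/bipolar proportions, geometric run
# null, consecutive-run detection along dendrites, per-partner profiles,
# classification rates, Fisher's exact test, overlap analysis.

#' Per-synapse amacrine probability
#'
#' Either the observed fraction of conventional (amacrine) synapses in a
#' synapse table, or a/(a+b) from a stated amacrine:bipolar ratio.
#'
#' @param synapses synapse records with a `kind` column (ignored if `ratio`
#'   is given).
#' @param ratio optional length-2 numeric c(amacrine, bipolar), e.g.
#'   c(1.6, 1).
#' @return Probability p in \[0, 1\].
#' @export
amacrine_probability <- function(synapses = NULL, ratio = NULL) {
  if (!is.null(ratio)) {
    stopifnot(length(ratio) == 2, all(ratio >= 0))
    if (sum(ratio) == 0) stop("ratio has zero total")
    return(ratio[1] / sum(ratio))
  }
  if (is.null(synapses) || !nrow(synapses)) stop("zero total synapses")
  mean(synapses$kind == "conventional")
}

#' Geometric null probability of a run of amacrine synapses
#'
#' Probability of N consecutive amacrine synapses, uninterrupted by a
#' bipolar synapse, under independent draws: p^N.
#'
#' @param p per-synapse amacrine probability in \[0, 1\].
#' @param N run length, integer >= 0 (p^0 = 1).
#' @return p^N.
#' @export
run_probability <- function(p, N) {
  stopifnot(p >= 0, p <= 1, N >= 0, N == round(N))
  p^N
}

# root-to-leaf node paths of a reconstruction, with arc length per node
skeleton_paths <- function(reconstruction) {
  nodes <- reconstruction$nodes
  children <- split(nodes$node_id, nodes$parent_id)
  roots <- nodes$node_id[is.na(nodes$parent_id)]
  coords <- as.matrix(nodes[, c("x_um", "y_um", "z_um")])
  rownames(coords) <- nodes$node_id
  paths <- list()
  # iterative DFS carrying the path so far
  for (root in roots) {
    stack <- list(list(id = root, path = root, arc = 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      kids <- children[[top$id]]
      if (is.null(kids)) {
        paths[[length(paths) + 1]] <- list(nodes = top$path, arc = top$arc)
        next
      }
      for (kid in kids) {
        step <- sqrt(sum((coords[kid, ] - coords[top$id, ])^2))
        stack[[length(stack) + 1]] <-
          list(id = kid, path = c(top$path, kid),
               arc = c(top$arc, top$arc[length(top$arc)] + step))
      }
    }
  }
  paths
}

#' Maximal runs of consecutive amacrine synapses along dendrites
#'
#' Synapses are attached to their nearest skeleton node, ordered by
#' cumulative arc length along each root-to-leaf path, and maximal runs of
#' consecutive amacrine (conventional) synapses are reported per path.
#' Runs occurring identically on several paths that share a prefix are
#' reported once.
#'
#' @param reconstruction a `neuron_reconstruction`.
#' @param synapses synapse records onto that cell; attached to nodes first
#'   if no `node_id` column is present.
#' @return data.frame with `path_id`, `run_length`, and a `synapse_ids`
#'   list-column of the member synapses (empty when no amacrine synapses).
#' @export
find_amacrine_runs <- function(reconstruction, synapses) {
  empty <- data.frame(path_id = integer(0), run_length = integer(0))
  empty$synapse_ids <- list()
  if (!nrow(synapses)) return(empty)
  if (!"node_id" %in% names(synapses))
    synapses <- attach_synapses(reconstruction, synapses)
  if (anyNA(synapses$node_id) || any(!synapses$node_id %in%
                                     reconstruction$nodes$node_id))
    stop("synapse attached to no node of the reconstruction")
  paths <- skeleton_paths(reconstruction)
  recs <- list()
  seen <- character(0)
  for (pi in seq_along(paths)) {
    p <- paths[[pi]]
    on_path <- synapses[synapses$node_id %in% p$nodes, , drop = FALSE]
    if (!nrow(on_path)) next
    arc <- p$arc[match(on_path$node_id, p$nodes)]
    ord <- order(arc, on_path$synapse_id)
    on_path <- on_path[ord, , drop = FALSE]
    is_ama <- on_path$kind == "conventional"
    r <- rle(is_ama)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      ids <- on_path$synapse_id[starts[j]:ends[j]]
      key <- paste(sort(ids), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      recs[[length(recs) + 1]] <- list(path_id = pi,
                                       run_length = length(ids),
                                       synapse_ids = ids)
    }
  }
  if (!length(recs)) return(empty)
  out <- data.frame(path_id = vapply(recs, `[[`, integer(1), "path_id"),
                    run_length = vapply(recs, `[[`, integer(1),
                                        "run_length"))
  out$synapse_ids <- lapply(recs, `[[`, "synapse_ids")
  out[order(-out$run_length, out$path_id), , drop = FALSE]
}

#' Per-partner synapse profile
#'
#' Counts ribbon synapses per presynaptic bipolar cell, the totals by type,
#' the mean synapse load per partner, and the histogram of per-partner
#' counts by type.
#'
#' @param synapses ribbon synapse records with `pre_cell_id` and `pre_type`.
#' @return A `partner_profile`: `per_partner` (data.frame pre_cell_id /
#'   pre_type / n_synapses), `totals_by_type`, `n_partners`,
#'   `mean_synapses_per_partner`, `histogram` (table of count x type).
#' @export
partner_profile <- function(synapses) {
  syn <- synapses[synapses$kind == "ribbon", , drop = FALSE]
  if (!nrow(syn)) {
    return(structure(list(per_partner = data.frame(
      pre_cell_id = character(0), pre_type = character(0),
      n_synapses = integer(0)), totals_by_type = table(character(0)),
      n_partners = 0L, mean_synapses_per_partner = NaN,
      histogram = table(character(0))), class = "partner_profile"))
  }
  agg <- stats::aggregate(list(n_synapses = syn$synapse_id),
                          by = list(pre_cell_id = syn$pre_cell_id,
                                    pre_type = syn$pre_type),
                          FUN = length)
  agg <- agg[order(-agg$n_synapses, agg$pre_cell_id), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(per_partner = agg,
                 totals_by_type = table(syn$pre_type),
                 n_partners = nrow(agg),
                 mean_synapses_per_partner = nrow(syn) / nrow(agg),
                 histogram = table(agg$n_synapses, agg$pre_type)),
            class = "partner_profile")
}

#' Classification rate of ribbon synapses
#'
#' Share of ribbon synapses whose presynaptic bipolar cell could be typed.
#'
#' @param synapses ribbon synapse records with `pre_type` ("unclassified"
#'   marks an untyped presynaptic cell).
#' @return list with `n_classified`, `n_total`, `percent` (2 dp).
#' @export
classification_rate <- function(synapses) {
  syn <- synapses[synapses$kind == "ribbon", , drop = FALSE]
  if (!nrow(syn)) stop("zero ribbon synapses")
  n_classified <- sum(syn$pre_type != "unclassified")
  list(n_classified = n_classified, n_total = nrow(syn),
       percent = round(100 * n_classified / nrow(syn), 2))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact two-sided p by summing the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (the minimum-likelihood convention, as in
#' `stats::fisher.test`). The doubling rule (twice the smaller one-sided
#' tail, capped at 1) is available as an alternative.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @param method "min.likelihood" (default) or "doubling".
#' @return Two-sided p value.
#' @export
fisher_exact_2x2 <- function(tab, method = c("min.likelihood",
                                             "doubling")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0)
    stop("all-zero margin")
  a <- tab[1, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  if (method == "min.likelihood") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- stats::phyper(a, r1, r2, c1)
    upper <- stats::phyper(a - 1, r1, r2, c1, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
  }
  min(p, 1)
}

# boundary-inclusive membership of points in a convex hull polygon
points_in_hull <- function(points, hull, tol = 1e-9) {
  X <- as.matrix(points)[, 1:2, drop = FALSE]
  v <- hull$vertices                    # counter-clockwise
  n <- nrow(v)
  scale <- max(1, max(abs(v)))
  inside <- rep(TRUE, nrow(X))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- v[j, 1] - v[i, 1]; ey <- v[j, 2] - v[i, 2]
    cross <- ex * (X[, 2] - v[i, 2]) - ey * (X[, 1] - v[i, 1])
    inside <- inside & (cross >= -tol * scale)
  }
  inside
}

#' Overlap of synapses with a reference cell's dendritic field
#'
#' Classifies each test synapse by boundary-inclusive membership in the
#' reference cell's dendritic convex hull, measures member distances to the
#' hull's area centroid (the dendritic-field center), and counts shared
#' presynaptic partners by type when the reference cell's own synapses are
#' supplied.
#'
#' @param test_synapses synapse records (e.g. the smooth cell's ribbon
#'   synapses).
#' @param reference_cell a `neuron_reconstruction` (e.g. a parasol).
#' @param reference_synapses optional synapse records onto the reference
#'   cell, for the shared-partner count.
#' @return An `overlap_report`: `hull`, `member` (logical per test
#'   synapse), `distances` (members only, um), `n_member`, `n_total`,
#'   `shared_partners` (data.frame pre_cell_id / pre_type or NULL).
#' @export
overlap_analysis <- function(test_synapses, reference_cell,
                             reference_synapses = NULL) {
  hull <- dendritic_field_hull(reference_cell)
  member <- if (nrow(test_synapses))
    points_in_hull(cbind(test_synapses$x_um, test_synapses$y_um), hull)
  else logical(0)
  dx <- test_synapses$x_um[member] - hull$centroid[1]
  dy <- test_synapses$y_um[member] - hull$centroid[2]
  shared <- NULL
  if (!is.null(reference_synapses)) {
    pre_test <- unique(test_synapses$pre_cell_id[
      test_synapses$kind == "ribbon"])
    ref_rib <- reference_synapses[reference_synapses$kind == "ribbon", ,
                                  drop = FALSE]
    shared_ids <- intersect(pre_test, unique(ref_rib$pre_cell_id))
    shared <- unique(ref_rib[ref_rib$pre_cell_id %in% shared_ids,
                             c("pre_cell_id", "pre_type")])
    rownames(shared) <- NULL
  }
  structure(list(hull = hull, member = member,
                 distances = sqrt(dx^2 + dy^2),
                 n_member = sum(member), n_total = nrow(test_synapses),
                 shared_partners = shared),
            class = "overlap_report")
}

#' @export
print.partner_profile <- function(x, ...) {
  cat(sprintf(
    "<partner_profile> %d synapses from %d partners (mean %.2f per partner)\n",
    sum(x$per_partner$n_synapses), x$n_partners,
    x$mean_synapses_per_partner))
  invisible(x)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d of %d synapses inside the field\n",
              x$n_member, x$n_total))
  invisible(x)
}
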