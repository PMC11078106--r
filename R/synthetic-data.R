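# Synthetic reconstructions and synapse tables with known ground truth.
#
# The generator emulates the statistical structure of the real material:
# one large, sparse, radiate dendritic tree (~150 um across) vs small,
# dense, tortuous trees (~57 um), an amacrine:bipolar synapse ratio of
# ~1.6:1, and bipolar synapses drawn either homogeneously along the cable
# or from a planted K-component Gaussian intensity.

#' Skeleton generator configuration
#'
#' @param n_primary_dendrites number of primary dendrites leaving the soma.
#' @param field_radius maximum x-y distance of any node from the soma (um).
#' @param segment_length length of one growth segment (um).
#' @param branch_prob probability of bifurcating at each grown segment
#'   (applied only while the field is under-tiled; see `branch_spacing`).
#' @param branch_spacing target spacing between neighbouring branches (um).
#'   Branching is suppressed once a growth ring carries more tips than
#'   2 pi r / branch_spacing, so the tree tiles its field with roughly
#'   uniform areal cable density instead of multiplying tips
#'   exponentially.
#' @param soma_radius radius of the soma disk (um).
#' @param soma_radius_sd optional Gaussian jitter of the soma radius (um);
#'   0 (default) keeps the soma size deterministic.
#' @param stratification_z z of the dendritic stratum (um).
#' @param z_jitter_sd SD of per-node z jitter about the stratum (um).
#' @param angle_sd SD of the angular noise per segment (radians); small
#'   values give straight, radiate dendrites, large values tortuous ones.
#' @param radial_bias strength (0..1) of the outward tropism that keeps
#'   dendrites growing away from the soma rather than orbiting the field.
#' @param max_path_factor tips are retired once their path length exceeds
#'   `max_path_factor * field_radius` (safety against wandering growth).
#' @param dendrite_radius annotation-disk radius for dendrite nodes (um).
#' @param soma_center x-y position of the soma (um).
#' @param max_nodes growth cap.
#' @param seed integer RNG seed (mandatory; no global RNG state is used).
#' @return A `skeleton_config` list.
#' @export
skeleton_config <- function(n_primary_dendrites, field_radius,
                            segment_length, branch_prob, soma_radius,
                            stratification_z, soma_radius_sd = 0,
                            z_jitter_sd = 1,
                            angle_sd = 0.2, branch_spacing = 8,
                            radial_bias = 0.1, max_path_factor = 2,
                            dendrite_radius = 0.4,
                            soma_center = c(0, 0), max_nodes = 20000,
                            seed) {
  stopifnot(field_radius > 0, segment_length > 0,
            branch_prob >= 0, branch_prob <= 1,
            n_primary_dendrites >= 1, soma_radius > 0)
  if (segment_length > field_radius)
    stop("impossible geometry: segment_length exceeds field_radius")
  structure(list(n_primary_dendrites = as.integer(n_primary_dendrites),
                 field_radius = field_radius,
                 segment_length = segment_length,
                 branch_prob = branch_prob, soma_radius = soma_radius,
                 soma_radius_sd = soma_radius_sd,
                 stratification_z = stratification_z,
                 z_jitter_sd = z_jitter_sd, angle_sd = angle_sd,
                 branch_spacing = branch_spacing,
                 radial_bias = radial_bias,
                 max_path_factor = max_path_factor,
                 dendrite_radius = dendrite_radius,
                 soma_center = soma_center, max_nodes = max_nodes,
                 seed = as.integer(seed)),
            class = "skeleton_config")
}

#' Default skeleton configurations for the two ganglion-cell morphologies
#'
#' The smooth monostratified configuration grows a sparse radiate tree with
#' a ~153 um dendritic field stratifying at 63.2% of a 40 um IPL; the
#' parasol configuration a dense tortuous tree with a ~57 um field at
#' 64.6% depth. Soma radii give 14.5 and 14.9 um diameters respectively.
#'
#' @param seed integer RNG seed.
#' @param soma_center x-y soma position (um).
#' @return A `skeleton_config`.
#' @export
smooth_skeleton_config <- function(seed, soma_center = c(0, 0)) {
  skeleton_config(n_primary_dendrites = 8, field_radius = 76.5,
                  segment_length = 2, branch_prob = 0.20,
                  soma_radius = 7.25, stratification_z = 25.28,
                  z_jitter_sd = 1, angle_sd = 0.08, branch_spacing = 4,
                  soma_center = soma_center, seed = seed)
}

#' @rdname smooth_skeleton_config
#' @export
parasol_skeleton_config <- function(seed, soma_center = c(0, 0)) {
  skeleton_config(n_primary_dendrites = 2, field_radius = 28.5,
                  segment_length = 1.5, branch_prob = 0.40,
                  soma_radius = 7.45, stratification_z = 25.84,
                  z_jitter_sd = 1, angle_sd = 0.35, branch_spacing = 3.5,
                  soma_center = soma_center, seed = seed)
}

#' Grow a synthetic dendritic skeleton
#'
#' Discrete-segment growth: each active tip advances by `segment_length`
#' in its current direction plus Gaussian angular noise, bifurcates with
#' probability `branch_prob`, and terminates when the next step would leave
#' the dendritic field. The soma has exactly `n_primary_dendrites` children.
#' Deterministic given the config seed.
#'
#' @param config a [skeleton_config()].
#' @param cell_id id for the generated cell.
#' @param cell_type label for the generated cell.
#' @return A `neuron_reconstruction`.
#' @export
generate_skeleton <- function(config, cell_id = "cell_1",
                              cell_type = "RGC_smooth") {
  cfg <- config
  withr::with_seed(cfg$seed, {
    cx <- cfg$soma_center[1]; cy <- cfg$soma_center[2]
    xs <- cx; ys <- cy
    zs <- cfg$stratification_z
    radii <- cfg$soma_radius
    parents <- NA_integer_
    tags <- "soma"
    n_nodes <- 1L
    # active tips: node index + current direction
    tip_node <- integer(0); tip_angle <- numeric(0)
    base <- stats::runif(1, 0, 2 * pi)
    prim <- base + 2 * pi * (seq_len(cfg$n_primary_dendrites) - 1) /
      cfg$n_primary_dendrites
    add_node <- function(px, py, pangle, parent) {
      nx <- px + cfg$segment_length * cos(pangle)
      ny <- py + cfg$segment_length * sin(pangle)
      if (sqrt((nx - cx)^2 + (ny - cy)^2) > cfg$field_radius) return(NA)
      n_nodes <<- n_nodes + 1L
      xs[n_nodes] <<- nx; ys[n_nodes] <<- ny
      zs[n_nodes] <<- cfg$stratification_z +
        stats::rnorm(1, 0, cfg$z_jitter_sd)
      radii[n_nodes] <<- cfg$dendrite_radius
      parents[n_nodes] <<- parent
      tags[n_nodes] <<- "dendrite"
      n_nodes
    }
    for (a in prim) {
      id <- add_node(cx, cy, a, 1L)
      if (is.na(id)) stop("primary dendrite could not be placed")
      tip_node <- c(tip_node, id); tip_angle <- c(tip_angle, a)
    }
    max_rings <- ceiling(cfg$max_path_factor * cfg$field_radius /
                           cfg$segment_length)
    ring <- 0L
    while (length(tip_node) > 0 && n_nodes < cfg$max_nodes &&
           ring < max_rings) {
      ring <- ring + 1L
      # Self-avoiding, space-filling growth: each tip measures the arc
      # distance to its azimuthal neighbours; tips steer away from a
      # neighbour closer than branch_spacing and may branch only into a
      # gap wider than twice the spacing, so the field is tiled with
      # roughly uniform cable density.
      nt <- length(tip_node)
      az <- atan2(ys[tip_node] - cy, xs[tip_node] - cx)
      rr <- sqrt((xs[tip_node] - cx)^2 + (ys[tip_node] - cy)^2)
      ord <- order(az)
      gap_left <- gap_right <- rep(Inf, nt)
      if (nt > 1) {
        az_s <- az[ord]
        dgap <- diff(c(az_s, az_s[1] + 2 * pi))        # gap to the right
        arc <- dgap * mean(rr)
        gap_right[ord] <- arc
        gap_left[ord] <- c(arc[nt], arc[-nt])
      }
      new_node <- integer(0); new_angle <- numeric(0)
      for (k in seq_along(tip_node)) {
        i <- tip_node[k]
        ang <- tip_angle[k] + stats::rnorm(1, 0, cfg$angle_sd)
        # outward tropism: nudge the heading toward the radial direction
        radial <- atan2(ys[i] - cy, xs[i] - cx)
        dev <- atan2(sin(radial - ang), cos(radial - ang))
        ang <- ang + cfg$radial_bias * dev
        # repulsion: steer toward the wider side when crowded
        gl <- gap_left[k]; gr <- gap_right[k]
        if (min(gl, gr) < cfg$branch_spacing && is.finite(max(gl, gr)))
          ang <- ang + 0.25 * sign(gr - gl) *
            (1 - min(gl, gr) / cfg$branch_spacing)
        id <- add_node(xs[i], ys[i], ang, i)
        if (is.na(id)) next
        new_node <- c(new_node, id); new_angle <- c(new_angle, ang)
        wide <- max(gl, gr)
        if (wide > 2 * cfg$branch_spacing &&
            stats::runif(1) < cfg$branch_prob) {
          side <- if (gr >= gl) 1 else -1
          bang <- ang + side * stats::rnorm(1, 0.5, 0.15)
          bid <- add_node(xs[i], ys[i], bang, i)
          if (!is.na(bid)) {
            new_node <- c(new_node, bid); new_angle <- c(new_angle, bang)
          }
        }
        if (n_nodes >= cfg$max_nodes) break
      }
      tip_node <- new_node; tip_angle <- new_angle
    }
    # soma-size jitter is the final draw so the tree itself is unchanged
    # for a given seed whether or not jitter is requested
    if (cfg$soma_radius_sd > 0)
      radii[1] <- max(0.5, cfg$soma_radius +
                        stats::rnorm(1, 0, cfg$soma_radius_sd))
    nodes <- data.frame(
      cell_id = cell_id,
      node_id = as.character(seq_len(n_nodes)),
      parent_id = ifelse(is.na(parents), NA_character_,
                         as.character(parents)),
      x_um = xs, y_um = ys, z_um = zs, radius_um = radii, tag = tags,
      stringsAsFactors = FALSE)
    structure(list(cell_id = cell_id, cell_type = cell_type, nodes = nodes),
              class = "neuron_reconstruction")
  })
}

#' Synapse placement model
#'
#' @param n_synapses total synapses to place.
#' @param amacrine_fraction probability that a synapse is amacrine
#'   (conventional); the remainder are bipolar ribbon synapses.
#' @param bipolar_spatial "homogeneous" (uniform along the cable) or
#'   "mixture" (planted Gaussian intensity).
#' @param mixture_components data.frame with columns `weight`, `x`, `y`,
#'   `sd` (um); weights must sum to 1. Required when
#'   `bipolar_spatial = "mixture"`.
#' @param type_proportions named probabilities over presynaptic bipolar
#'   types (may include "unclassified"); must sum to 1.
#' @param mean_synapses_per_partner expected ribbon synapses contributed by
#'   one presynaptic bipolar cell; sets the partner pool size.
#' @param seed integer RNG seed.
#' @return A `synapse_model` list.
#' @export
synapse_model <- function(n_synapses, amacrine_fraction,
                          bipolar_spatial = c("homogeneous", "mixture"),
                          mixture_components = NULL,
                          type_proportions,
                          mean_synapses_per_partner = 1.8,
                          seed) {
  bipolar_spatial <- match.arg(bipolar_spatial)
  stopifnot(amacrine_fraction >= 0, amacrine_fraction <= 1,
            n_synapses >= 0)
  if (bipolar_spatial == "mixture") {
    if (is.null(mixture_components))
      stop("mixture_components required for bipolar_spatial = 'mixture'")
    mixture_components <- as.data.frame(mixture_components)
    stopifnot(all(c("weight", "x", "y", "sd") %in%
                    names(mixture_components)))
    if (abs(sum(mixture_components$weight) - 1) > 1e-8)
      stop("mixture weights must sum to 1")
  }
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("type_proportions must sum to 1")
  structure(list(n_synapses = as.integer(n_synapses),
                 amacrine_fraction = amacrine_fraction,
                 bipolar_spatial = bipolar_spatial,
                 mixture_components = mixture_components,
                 type_proportions = type_proportions,
                 mean_synapses_per_partner = mean_synapses_per_partner,
                 seed = as.integer(seed)),
            class = "synapse_model")
}

#' Planted four-hotspot mixture used by the default smooth-cell scene
#'
#' Four equal-weight components at (+-38, +-38) um with 8 um SD: well
#' separated (>= 60 um between centers) within a ~153 um dendritic field.
#'
#' @return data.frame of mixture components.
#' @export
planted_hotspots <- function() {
  data.frame(weight = rep(0.25, 4),
             x = c(-38, 38, -38, 38),
             y = c(-38, -38, 38, 38),
             sd = 8)
}

#' Default synapse models for the two ganglion-cell classes
#'
#' The smooth model plants four bipolar-input hotspots and uses the 1.6:1
#' amacrine:bipolar ratio (amacrine fraction 0.615); bipolar types are
#' dominated by DB5 with DB4 and giant contributions and ~7% unclassified.
#' The parasol model is spatially homogeneous with amacrine fraction 0.464
#' and DB4-dominated type proportions including ON midget input.
#'
#' @param seed integer RNG seed.
#' @return A `synapse_model`.
#' @export
smooth_synapse_model <- function(seed) {
  synapse_model(
    n_synapses = 327, amacrine_fraction = 0.615,
    bipolar_spatial = "mixture", mixture_components = planted_hotspots(),
    type_proportions = c(BC_DB5 = 0.52, BC_DB4 = 0.26, BC_giant = 0.15,
                         unclassified = 0.07),
    mean_synapses_per_partner = 1.8, seed = seed)
}

#' @rdname smooth_synapse_model
#' @export
parasol_synapse_model <- function(seed) {
  synapse_model(
    n_synapses = 347, amacrine_fraction = 0.464,
    bipolar_spatial = "homogeneous",
    type_proportions = c(BC_DB4 = 0.4885, BC_ON_midget = 0.25,
                         BC_DB5 = 0.18, BC_giant = 0.05, BC_DB6 = 0.01,
                         unclassified = 0.0215),
    mean_synapses_per_partner = 4.6, seed = seed)
}

# intensity of the planted mixture at x-y positions
mixture_intensity <- function(comp, x, y) {
  out <- numeric(length(x))
  for (j in seq_len(nrow(comp))) {
    out <- out + comp$weight[j] *
      exp(-0.5 * ((x - comp$x[j])^2 + (y - comp$y[j])^2) / comp$sd[j]^2)
  }
  out
}

# Partner pool: spatially coherent presynaptic cells. Terminal centers sit
# on (jittered) dendrite positions; synapses later pick a pool member of
# their type with probability falling off with distance, emulating the
# limited reach of one axon terminal.
build_partner_pool <- function(dend_xy, expected_by_type,
                               mean_per_partner, prefix = "bc") {
  pool <- list()
  for (t in names(expected_by_type)) {
    if (t == "unclassified") next
    n_t <- max(1L, round(expected_by_type[[t]] / mean_per_partner[[t]]))
    idx <- sample.int(nrow(dend_xy), n_t, replace = TRUE)
    pool[[t]] <- data.frame(
      pre_cell_id = paste0(prefix, "_", tolower(sub("^BC_", "", t)), "_",
                           seq_len(n_t)),
      x = dend_xy[idx, 1] + stats::rnorm(n_t, 0, 3),
      y = dend_xy[idx, 2] + stats::rnorm(n_t, 0, 3),
      stringsAsFactors = FALSE)
  }
  pool
}

# expected classified-ribbon count per type under a synapse model
expected_ribbons <- function(model) {
  out <- model$n_synapses * (1 - model$amacrine_fraction) *
    model$type_proportions
  out[names(out) != "unclassified"]
}

#' Place synapses on a skeleton
#'
#' Each synapse is independently amacrine with probability
#' `amacrine_fraction` (kind "conventional"), otherwise a bipolar ribbon
#' synapse. Bipolar synapses are located at dendrite nodes drawn with
#' probability proportional to the planted mixture intensity at the node
#' (uniform along the cable when homogeneous); amacrine synapses are
#' uniform along the cable. Presynaptic bipolar types follow
#' `type_proportions`; each classified ribbon synapse is assigned to the
#' nearest member of a spatially coherent partner pool of its type.
#'
#' @param skeleton a `neuron_reconstruction` with at least one dendrite node.
#' @param model a [synapse_model()].
#' @param partner_pool optional pool shared across cells (see
#'   [generate_paired_scene()]); built from the skeleton when NULL.
#' @param id_prefix prefix for synapse ids.
#' @return data.frame of synapse records.
#' @export
place_synapses <- function(skeleton, model, partner_pool = NULL,
                           id_prefix = NULL) {
  dend <- skeleton$nodes[skeleton$nodes$tag == "dendrite", , drop = FALSE]
  if (!nrow(dend)) stop("skeleton has no dendrite nodes")
  if (is.null(id_prefix)) id_prefix <- paste0("syn_", skeleton$cell_id)
  withr::with_seed(model$seed, {
    n <- model$n_synapses
    is_ama <- stats::runif(n) < model$amacrine_fraction
    n_bip <- sum(!is_ama)
    # node index per synapse
    node_idx <- integer(n)
    if (any(is_ama))
      node_idx[is_ama] <- sample.int(nrow(dend), sum(is_ama),
                                     replace = TRUE)
    if (n_bip > 0) {
      if (model$bipolar_spatial == "homogeneous") {
        node_idx[!is_ama] <- sample.int(nrow(dend), n_bip, replace = TRUE)
      } else {
        w <- mixture_intensity(model$mixture_components,
                               dend$x_um, dend$y_um)
        if (max(w) < 1e-12) {
          warning("planted mixture has negligible intensity on the ",
                  "skeleton; falling back to uniform placement")
          w <- rep(1, nrow(dend))
        }
        node_idx[!is_ama] <- sample.int(nrow(dend), n_bip, replace = TRUE,
                                        prob = w)
      }
    }
    kind <- ifelse(is_ama, "conventional", "ribbon")
    pre_type <- character(n)
    pre_type[is_ama] <- "amacrine"
    if (n_bip > 0)
      pre_type[!is_ama] <- sample(names(model$type_proportions), n_bip,
                                  replace = TRUE,
                                  prob = model$type_proportions)
    if (is.null(partner_pool)) {
      exp_t <- expected_ribbons(model)
      partner_pool <- build_partner_pool(
        cbind(dend$x_um, dend$y_um), exp_t,
        stats::setNames(rep(model$mean_synapses_per_partner,
                            length(exp_t)), names(exp_t)),
        prefix = paste0("bc_", skeleton$cell_id))
    }
    pre_cell <- character(n)
    # amacrine partner ids: pooled at ~3 synapses per amacrine cell
    if (any(is_ama)) {
      n_ama_cells <- max(1L, round(sum(is_ama) / 3))
      pre_cell[is_ama] <- paste0("ama_", skeleton$cell_id, "_",
                                 sample.int(n_ama_cells, sum(is_ama),
                                            replace = TRUE))
    }
    kern2 <- 2 * 12^2        # 12 um reach of one axon terminal
    unk <- 0L
    for (i in which(!is_ama)) {
      t <- pre_type[i]
      if (t == "unclassified" || is.null(partner_pool[[t]])) {
        unk <- unk + 1L
        pre_cell[i] <- paste0("bc_unk_", skeleton$cell_id, "_", unk)
      } else {
        p <- partner_pool[[t]]
        d2 <- (p$x - dend$x_um[node_idx[i]])^2 +
          (p$y - dend$y_um[node_idx[i]])^2
        w <- exp(-d2 / kern2) + 1e-12
        j <- if (nrow(p) == 1) 1L else
          sample.int(nrow(p), 1, prob = w)
        pre_cell[i] <- p$pre_cell_id[j]
      }
    }
    data.frame(synapse_id = sprintf("%s_%04d", id_prefix, seq_len(n)),
               pre_cell_id = pre_cell,
               post_cell_id = skeleton$cell_id,
               kind = kind,
               x_um = dend$x_um[node_idx],
               y_um = dend$y_um[node_idx],
               z_um = dend$z_um[node_idx],
               pre_type = pre_type,
               stringsAsFactors = FALSE)
  })
}

#' Generate a paired scene: one smooth cell plus parasols inside its field
#'
#' Builds one large sparse cell and one or more small dense cells sharing
#' the same stratum, places synapses on each from a shared presynaptic
#' partner pool, and records the planted ground truth (mixture components,
#' seeds, soma positions) as an attribute that [write_dataset()] emits as
#' `truth.json`.
#'
#' @param smooth_config [skeleton_config()] for the smooth cell.
#' @param parasol_configs list of [skeleton_config()]s; each `soma_center`
#'   must lie inside the smooth cell's field.
#' @param model [synapse_model()] for the smooth cell.
#' @param parasol_models optional list of models, one per parasol; defaults
#'   to [parasol_synapse_model()] with seeds derived from `model$seed`.
#' @return A validated `scene_dataset` with a `truth` attribute.
#' @export
generate_paired_scene <- function(smooth_config, parasol_configs, model,
                                  parasol_models = NULL) {
  np <- length(parasol_configs)
  for (pc in parasol_configs) {
    d <- sqrt(sum((pc$soma_center - smooth_config$soma_center)^2))
    if (d > smooth_config$field_radius)
      stop("parasol soma at (", pc$soma_center[1], ", ", pc$soma_center[2],
           ") lies outside the smooth cell's field")
  }
  if (is.null(parasol_models))
    parasol_models <- lapply(seq_len(np), function(i)
      parasol_synapse_model(seed = (model$seed + 1000L + i) %%
                              .Machine$integer.max))
  smooth <- generate_skeleton(smooth_config, cell_id = "smooth_1",
                              cell_type = "RGC_smooth")
  parasols <- lapply(seq_len(np), function(i)
    generate_skeleton(parasol_configs[[i]],
                      cell_id = paste0("parasol_", i),
                      cell_type = "RGC_parasol"))
  # shared partner pool over the whole field so cells can share partners;
  # pool sizes reflect the expected classified ribbons of every cell
  all_dend <- do.call(rbind, lapply(c(list(smooth), parasols), function(r) {
    nd <- r$nodes[r$nodes$tag == "dendrite", c("x_um", "y_um")]
    as.matrix(nd)
  }))
  models <- c(list(model), parasol_models)
  expected <- list()
  mean_pp <- list()
  for (m in models) {
    for (t in names(expected_ribbons(m))) {
      e <- expected_ribbons(m)[[t]]
      expected[[t]] <- (expected[[t]] %||% 0) + e
      # weight each model's partner load by its expected contribution
      mean_pp[[t]] <- c(mean_pp[[t]], rep(m$mean_synapses_per_partner,
                                          round(e)))
    }
  }
  mean_pp <- lapply(mean_pp, mean)
  pool <- withr::with_seed((model$seed + 77L) %% .Machine$integer.max,
                           build_partner_pool(all_dend, expected, mean_pp,
                                              prefix = "bc"))
  syn <- list(place_synapses(smooth, model, partner_pool = pool))
  for (i in seq_len(np))
    syn[[i + 1]] <- place_synapses(parasols[[i]], parasol_models[[i]],
                                   partner_pool = pool)
  cells <- data.frame(
    cell_id = c("smooth_1", paste0("parasol_", seq_len(np))),
    cell_type = c("RGC_smooth", rep("RGC_parasol", np)),
    stringsAsFactors = FALSE)
  nodes <- do.call(rbind, lapply(c(list(smooth), parasols),
                                 function(r) r$nodes))
  ds <- new_dataset(cells, nodes, do.call(rbind, syn),
                    ipl = list(inl_ipl_z = 0, ipl_gcl_z = 40))
  truth <- list(
    mixture_components = model$mixture_components,
    bipolar_spatial = model$bipolar_spatial,
    amacrine_fraction = model$amacrine_fraction,
    type_proportions = as.list(model$type_proportions),
    parasol_soma_centers = lapply(parasol_configs,
                                  function(pc) pc$soma_center),
    seeds = list(smooth_skeleton = smooth_config$seed,
                 synapses = model$seed))
  attr(ds, "truth") <- truth
  ds
}
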