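# Independent oracles and small fixtures shared across test files.

# Brute-force Calinski-Harabasz index, written directly from the printed
# definition with explicit loops (independent of the package's vectorized
# implementation).
ch_brute <- function(X, labels) {
  X <- as.matrix(X)
  N <- nrow(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  g <- colMeans(X)
  between <- 0
  within <- 0
  for (k in ks) {
    pts <- X[labels == k, , drop = FALSE]
    ck <- colMeans(pts)
    between <- between + nrow(pts) * sum((ck - g)^2)
    for (i in seq_len(nrow(pts)))
      within <- within + sum((pts[i, ] - ck)^2)
  }
  (between / (K - 1)) / (within / (N - K))
}

# Exhaustive two-sided Fisher p for a 2x2 table: enumerate every table with
# the observed margins, hypergeometric probabilities from choose() products.
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) /
    choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Best assignment of K fitted means to K planted centers: the smallest
# achievable maximum distance over all permutations.
match_max_dist <- function(means, centers) {
  K <- nrow(centers)
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), ,
                 drop = FALSE]
  min(apply(perms, 1, function(p)
    max(sqrt(rowSums((means[p, , drop = FALSE] - centers)^2)))))
}

# Planted four-hotspot oracle scene: 126 bipolar synapses drawn from the
# default planted mixture on a fresh smooth-type skeleton.
planted_scene <- function(seed, n_synapses = 126) {
  sk <- generate_skeleton(smooth_skeleton_config(seed))
  m <- synapse_model(
    n_synapses = n_synapses, amacrine_fraction = 0,
    bipolar_spatial = "mixture",
    mixture_components = planted_hotspots(),
    type_proportions = c(BC_DB5 = 0.55, BC_DB4 = 0.30, BC_giant = 0.15),
    seed = seed + 500L)
  syn <- place_synapses(sk, m)
  list(skeleton = sk, synapses = syn,
       points = cbind(syn$x_um, syn$y_um),
       centers = as.matrix(planted_hotspots()[, c("x", "y")]))
}

# Hand-built cell whose dendrites sit at the corners of the (0,0)-(10,10)
# square; soma in the middle.
square_cell <- function(cell_id = "sq") {
  nodes <- data.frame(
    cell_id = cell_id,
    node_id = as.character(1:5),
    parent_id = c(NA, "1", "1", "1", "1"),
    x_um = c(5, 0, 10, 10, 0),
    y_um = c(5, 0, 0, 10, 10),
    z_um = 0,
    radius_um = c(5, rep(0.5, 4)),
    tag = c("soma", rep("dendrite", 4)),
    stringsAsFactors = FALSE)
  structure(list(cell_id = cell_id, cell_type = "RGC_parasol",
                 nodes = nodes),
            class = "neuron_reconstruction")
}

# Unbranched chain cell along +x: soma at the origin, n dendrite nodes at
# x = 1..n. Useful for run-length tests where arc order is known.
chain_cell <- function(n, cell_id = "chain") {
  nodes <- data.frame(
    cell_id = cell_id,
    node_id = as.character(seq_len(n + 1)),
    parent_id = c(NA, as.character(seq_len(n))),
    x_um = c(0, seq_len(n)),
    y_um = 0, z_um = 0,
    radius_um = c(5, rep(0.5, n)),
    tag = c("soma", rep("dendrite", n)),
    stringsAsFactors = FALSE)
  structure(list(cell_id = cell_id, cell_type = "RGC_smooth",
                 nodes = nodes),
            class = "neuron_reconstruction")
}

# Synapse table placed exactly on given nodes of a reconstruction.
synapses_on_nodes <- function(rec, node_ids, kinds,
                              pre_types = NULL, pre_cells = NULL) {
  idx <- match(node_ids, rec$nodes$node_id)
  n <- length(node_ids)
  if (is.null(pre_types))
    pre_types <- ifelse(kinds == "conventional", "amacrine", "BC_DB5")
  if (is.null(pre_cells)) pre_cells <- paste0("pre_", seq_len(n))
  data.frame(
    synapse_id = sprintf("s%03d", seq_len(n)),
    pre_cell_id = pre_cells,
    post_cell_id = rec$cell_id,
    kind = kinds,
    x_um = rec$nodes$x_um[idx],
    y_um = rec$nodes$y_um[idx],
    z_um = rec$nodes$z_um[idx],
    pre_type = pre_types,
    stringsAsFactors = FALSE)
}
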