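# Domain model: annotation-disk skeletons, synapse tables, and dataset I/O.

#' Recognised cell type labels
#'
#' Cell types appearing in reconstructions and synapse tables. Bipolar types
#' carry the `BC_` prefix; presynaptic bipolar cells make ribbon synapses,
#' amacrine cells make conventional synapses.
#'
#' @export
CELL_TYPES <- c("RGC_smooth", "RGC_parasol",
                "BC_DB4", "BC_DB5", "BC_DB6", "BC_giant", "BC_ON_midget",
                "amacrine", "unclassified")

#' @rdname CELL_TYPES
#' @export
BIPOLAR_TYPES <- c("BC_DB4", "BC_DB5", "BC_DB6", "BC_giant", "BC_ON_midget")

NODE_COLS <- c("cell_id", "node_id", "parent_id",
               "x_um", "y_um", "z_um", "radius_um", "tag")
SYNAPSE_COLS <- c("synapse_id", "pre_cell_id", "post_cell_id", "kind",
                  "x_um", "y_um", "z_um", "pre_type")

#' Assemble a dataset of reconstructions and synapses
#'
#' A dataset bundles the cell table, the annotation-node table, the synapse
#' table, and the inner plexiform layer (IPL) boundary planes. Coordinates
#' are in micrometres; the INL/IPL boundary defines 0% depth and the
#' IPL/GCL boundary 100%.
#'
#' @param cells data.frame with columns `cell_id`, `cell_type`.
#' @param nodes data.frame with columns `cell_id`, `node_id`, `parent_id`
#'   (`NA` at roots), `x_um`, `y_um`, `z_um`, `radius_um`, `tag`
#'   (one of soma/dendrite/axon).
#' @param synapses data.frame with columns `synapse_id`, `pre_cell_id`,
#'   `post_cell_id`, `kind` (ribbon/conventional), `x_um`, `y_um`, `z_um`,
#'   `pre_type`.
#' @param ipl list with numeric `inl_ipl_z` and `ipl_gcl_z`.
#' @param validate validate invariants (default TRUE).
#' @return An object of class `scene_dataset`.
#' @export
new_dataset <- function(cells, nodes, synapses, ipl, validate = TRUE) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(synapses) || nrow(as.data.frame(synapses)) == 0) {
    synapses <- empty_synapse_table()
  } else {
    synapses <- as.data.frame(synapses, stringsAsFactors = FALSE)
  }
  for (col in c("cell_id", "node_id", "parent_id"))
    nodes[[col]] <- as.character(nodes[[col]])
  cells$cell_id <- as.character(cells$cell_id)
  for (col in c("synapse_id", "pre_cell_id", "post_cell_id"))
    synapses[[col]] <- as.character(synapses[[col]])
  ds <- structure(list(cells = cells[, c("cell_id", "cell_type")],
                       nodes = nodes[, NODE_COLS],
                       synapses = synapses[, SYNAPSE_COLS],
                       ipl = list(inl_ipl_z = as.numeric(ipl$inl_ipl_z),
                                  ipl_gcl_z = as.numeric(ipl$ipl_gcl_z))),
                  class = "scene_dataset")
  if (validate) validate_dataset(ds)
  ds
}

empty_synapse_table <- function() {
  data.frame(synapse_id = character(), pre_cell_id = character(),
             post_cell_id = character(), kind = character(),
             x_um = numeric(), y_um = numeric(), z_um = numeric(),
             pre_type = character(), stringsAsFactors = FALSE)
}

#' Validate a dataset against the schema invariants
#'
#' Checks disk radii, parent references, acyclicity of the skeleton forest,
#' presence of a soma node per cell, synapse cross-references, and the
#' ribbon/conventional vs presynaptic-type consistency rule.
#'
#' @param dataset a `scene_dataset`.
#' @return `dataset`, invisibly; errors describe the first violation found.
#' @export
validate_dataset <- function(dataset) {
  nodes <- dataset$nodes
  cells <- dataset$cells
  syn <- dataset$synapses

  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell_id in cells table")
  bad_type <- setdiff(unique(cells$cell_type), CELL_TYPES)
  if (length(bad_type))
    stop("unknown cell_type: ", paste(bad_type, collapse = ", "))
  if (nrow(nodes)) {
    if (any(!is.finite(nodes$x_um) | !is.finite(nodes$y_um) |
            !is.finite(nodes$z_um)))
      stop("non-finite node coordinates")
    if (any(nodes$radius_um <= 0))
      stop("node radius_um must be > 0")
    if (any(!nodes$tag %in% c("soma", "dendrite", "axon")))
      stop("node tag must be one of soma/dendrite/axon")
    unknown_cells <- setdiff(unique(nodes$cell_id), cells$cell_id)
    if (length(unknown_cells))
      stop("nodes reference unknown cell_id: ",
           paste(unknown_cells, collapse = ", "))
    for (cid in unique(nodes$cell_id)) {
      cn <- nodes[nodes$cell_id == cid, ]
      if (anyDuplicated(cn$node_id))
        stop("duplicate node_id within cell ", cid)
      if (!any(cn$tag == "soma"))
        stop("cell ", cid, " has no soma-tagged node")
      has_parent <- !is.na(cn$parent_id)
      if (any(has_parent & !cn$parent_id %in% cn$node_id))
        stop("cell ", cid, ": parent_id not found within the same cell")
      check_acyclic(cn, cid)
    }
  }
  if (nrow(syn)) {
    if (any(!is.finite(syn$x_um) | !is.finite(syn$y_um) |
            !is.finite(syn$z_um)))
      stop("non-finite synapse coordinates")
    if (anyDuplicated(syn$synapse_id))
      stop("duplicate synapse_id")
    if (any(!syn$kind %in% c("ribbon", "conventional")))
      stop("synapse kind must be ribbon or conventional")
    bad_pt <- setdiff(unique(syn$pre_type), CELL_TYPES)
    if (length(bad_pt))
      stop("unknown pre_type: ", paste(bad_pt, collapse = ", "))
    unresolved <- setdiff(unique(syn$post_cell_id), cells$cell_id)
    if (length(unresolved))
      stop("synapses reference unknown post_cell_id: ",
           paste(unresolved, collapse = ", "))
    # ribbon <=> bipolar presynaptic type, whenever the type is known
    is_bip <- syn$pre_type %in% BIPOLAR_TYPES
    if (any(is_bip & syn$kind != "ribbon"))
      stop("bipolar presynaptic type with non-ribbon kind")
    if (any(syn$pre_type == "amacrine" & syn$kind != "conventional"))
      stop("amacrine presynaptic type with non-conventional kind")
  }
  invisible(dataset)
}

# Follow parent links; a walk longer than the node count means a cycle.
check_acyclic <- function(cell_nodes, cid) {
  parent <- cell_nodes$parent_id
  names(parent) <- cell_nodes$node_id
  n <- length(parent)
  for (start in cell_nodes$node_id) {
    cur <- start
    steps <- 0L
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cell ", cid, ": cycle in parent links")
    }
  }
  invisible(TRUE)
}

#' Read a dataset from a directory of CSV/JSON files
#'
#' Expects `cells.csv`, `nodes.csv`, `synapses.csv` and `ipl.json` as written
#' by [write_dataset()]. An empty synapse file is valid. Malformed rows and
#' unresolved cross-references raise errors naming the offending file or ids.
#'
#' @param dir directory containing the files.
#' @return A validated `scene_dataset`.
#' @export
load_dataset <- function(dir) {
  need <- c("cells.csv", "nodes.csv", "synapses.csv", "ipl.json")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing dataset files in ", dir, ": ",
         paste(missing, collapse = ", "))
  read1 <- function(p, what) {
    out <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = "character",
                                    fileEncoding = "UTF-8"),
                    error = function(e) stop("malformed ", what, " (", p,
                                             "): ", conditionMessage(e)))
    out
  }
  cells <- read1(paths[1], "cells.csv")
  nodes <- read1(paths[2], "nodes.csv")
  syn <- read1(paths[3], "synapses.csv")
  for (col in c("x_um", "y_um", "z_um", "radius_um")) {
    v <- suppressWarnings(as.numeric(nodes[[col]]))
    if (nrow(nodes) && anyNA(v))
      stop("malformed nodes.csv: non-numeric ", col, " at line ",
           which(is.na(v))[1] + 1L)
    nodes[[col]] <- v
  }
  nodes$parent_id[nodes$parent_id == ""] <- NA_character_
  for (col in c("x_um", "y_um", "z_um")) {
    v <- suppressWarnings(as.numeric(syn[[col]]))
    if (nrow(syn) && anyNA(v))
      stop("malformed synapses.csv: non-numeric ", col, " at line ",
           which(is.na(v))[1] + 1L)
    syn[[col]] <- v
  }
  ipl <- jsonlite::fromJSON(paths[4])
  if (nrow(syn) == 0) syn <- empty_synapse_table()
  new_dataset(cells, nodes, syn, ipl)
}

#' Write a dataset to a directory
#'
#' Writes `cells.csv`, `nodes.csv`, `synapses.csv` (fixed column order,
#' UTF-8) and `ipl.json`. If the dataset carries planted ground truth (see
#' [generate_paired_scene()]) a `truth.json` sidecar is written too.
#' `load_dataset(write_dataset(d))` reproduces `d` field for field.
#'
#' @param dataset a `scene_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  validate_dataset(dataset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8", quote = TRUE)
  }
  nodes <- dataset$nodes
  # full precision so the round trip is exact to numeric print precision
  for (col in c("x_um", "y_um", "z_um", "radius_um"))
    nodes[[col]] <- formatC(nodes[[col]], digits = 17, format = "g")
  syn <- dataset$synapses
  for (col in c("x_um", "y_um", "z_um"))
    syn[[col]] <- formatC(syn[[col]], digits = 17, format = "g")
  w(dataset$cells, "cells.csv")
  w(nodes, "nodes.csv")
  w(syn, "synapses.csv")
  jsonlite::write_json(dataset$ipl, file.path(dir, "ipl.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- attr(dataset, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export reconstructions in SWC format
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent), one file per
#' cell, parent -1 at roots. Type codes: 1 soma, 2 axon, 3 dendrite.
#'
#' @param dataset a `scene_dataset`.
#' @param dir output directory.
#' @return Paths of the files written, invisibly.
#' @export
write_swc <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  type_code <- c(soma = 1L, axon = 2L, dendrite = 3L)
  paths <- character(0)
  for (cid in unique(dataset$nodes$cell_id)) {
    cn <- dataset$nodes[dataset$nodes$cell_id == cid, ]
    idx <- seq_len(nrow(cn))
    names(idx) <- cn$node_id
    parent <- ifelse(is.na(cn$parent_id), -1L, idx[cn$parent_id])
    swc <- data.frame(id = idx, type = type_code[cn$tag],
                      x = cn$x_um, y = cn$y_um, z = cn$z_um,
                      r = cn$radius_um, parent = as.integer(parent))
    p <- file.path(dir, paste0(cid, ".swc"))
    utils::write.table(swc, p, row.names = FALSE, col.names = FALSE,
                       quote = FALSE, sep = " ")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Filter the synapse table of one postsynaptic cell
#'
#' Filters are conjunctive; rows are returned in stable `synapse_id` order.
#'
#' @param dataset a `scene_dataset`.
#' @param post_cell_id cell whose input synapses are wanted.
#' @param kind optional filter: "ribbon" or "conventional".
#' @param pre_type optional presynaptic type filter.
#' @return data.frame of synapse records.
#' @export
subset_synapses <- function(dataset, post_cell_id, kind = NULL,
                            pre_type = NULL) {
  if (!post_cell_id %in% dataset$cells$cell_id)
    stop("unknown cell id: ", post_cell_id)
  syn <- dataset$synapses
  keep <- syn$post_cell_id == post_cell_id
  if (!is.null(kind)) keep <- keep & syn$kind == kind
  if (!is.null(pre_type)) keep <- keep & syn$pre_type == pre_type
  out <- syn[keep, , drop = FALSE]
  out[order(out$synapse_id), , drop = FALSE]
}

#' Extract one cell's reconstruction
#'
#' @param dataset a `scene_dataset`.
#' @param cell_id the cell to extract.
#' @return A `neuron_reconstruction`: list with `cell_id`, `cell_type`, and
#'   the cell's `nodes` table.
#' @export
get_reconstruction <- function(dataset, cell_id) {
  i <- match(cell_id, dataset$cells$cell_id)
  if (is.na(i)) stop("unknown cell id: ", cell_id)
  structure(list(cell_id = cell_id,
                 cell_type = dataset$cells$cell_type[i],
                 nodes = dataset$nodes[dataset$nodes$cell_id == cell_id, ,
                                       drop = FALSE]),
            class = "neuron_reconstruction")
}

#' Attach synapses to their nearest skeleton node
#'
#' Each synapse is assigned the node of the postsynaptic reconstruction
#' nearest in 3D Euclidean distance; ties go to the lower `node_id`
#' (character comparison after numeric where possible).
#'
#' @param reconstruction a `neuron_reconstruction`.
#' @param synapses synapse records for that cell.
#' @return `synapses` with an added `node_id` column.
#' @export
attach_synapses <- function(reconstruction, synapses) {
  nodes <- reconstruction$nodes
  if (!nrow(nodes)) stop("reconstruction has no nodes")
  if (!nrow(synapses)) {
    synapses$node_id <- character(0)
    return(synapses)
  }
  # order nodes so the first minimum is the lower node_id
  ord <- order_node_ids(nodes$node_id)
  nodes <- nodes[ord, , drop = FALSE]
  nx <- nodes$x_um; ny <- nodes$y_um; nz <- nodes$z_um
  node_for <- character(nrow(synapses))
  for (i in seq_len(nrow(synapses))) {
    d2 <- (nx - synapses$x_um[i])^2 + (ny - synapses$y_um[i])^2 +
      (nz - synapses$z_um[i])^2
    node_for[i] <- nodes$node_id[which.min(d2)]
  }
  synapses$node_id <- node_for
  synapses
}

# numeric-aware ordering of node ids ("2" < "10" when all numeric)
order_node_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids)
}

#' @export
print.scene_dataset <- function(x, ...) {
  cat("<scene_dataset> ", nrow(x$cells), " cells, ", nrow(x$nodes),
      " nodes, ", nrow(x$synapses), " synapses\n", sep = "")
  invisible(x)
}

#' @export
print.neuron_reconstruction <- function(x, ...) {
  cat("<neuron_reconstruction> ", x$cell_id, " (", x$cell_type, "), ",
      nrow(x$nodes), " nodes\n", sep = "")
  invisible(x)
}
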