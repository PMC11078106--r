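test_that("write/load round trip reproduces the dataset field for field", {
  ds <- generate_paired_scene(
    smooth_skeleton_config(21),
    list(parasol_skeleton_config(22, c(-30, 5))),
    smooth_synapse_model(23))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- load_dataset(dir)
  expect_equal(ds2$cells, ds$cells)
  expect_equal(ds2$nodes, ds$nodes, tolerance = 1e-12)
  expect_equal(ds2$synapses, ds$synapses, tolerance = 1e-12)
  expect_equal(ds2$ipl, ds$ipl)
  # planted truth is emitted as a sidecar
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("unicode cell labels survive the round trip", {
  cells <- data.frame(cell_id = "célula_β", cell_type = "RGC_smooth")
  nodes <- data.frame(cell_id = "célula_β", node_id = "1",
                      parent_id = NA_character_, x_um = 0, y_um = 0,
                      z_um = 1, radius_um = 5, tag = "soma")
  ds <- new_dataset(cells, nodes, NULL,
                    ipl = list(inl_ipl_z = 0, ipl_gcl_z = 40))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_equal(load_dataset(dir)$cells$cell_id, "célula_β")
})

test_that("an empty synapse table is valid and loads back empty", {
  cells <- data.frame(cell_id = "c1", cell_type = "RGC_parasol")
  nodes <- data.frame(cell_id = "c1", node_id = "1",
                      parent_id = NA_character_, x_um = 0, y_um = 0,
                      z_um = 0, radius_um = 4, tag = "soma")
  ds <- new_dataset(cells, nodes, NULL,
                    ipl = list(inl_ipl_z = 0, ipl_gcl_z = 40))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_identical(nrow(load_dataset(dir)$synapses), 0L)
})

test_that("validation reports unresolved synapse references and bad nodes", {
  cells <- data.frame(cell_id = "c1", cell_type = "RGC_smooth")
  nodes <- data.frame(cell_id = "c1", node_id = "1",
                      parent_id = NA_character_, x_um = 0, y_um = 0,
                      z_um = 0, radius_um = 4, tag = "soma")
  syn <- data.frame(synapse_id = "s1", pre_cell_id = "b1",
                    post_cell_id = "ghost", kind = "ribbon",
                    x_um = 0, y_um = 0, z_um = 0, pre_type = "BC_DB5")
  expect_error(
    new_dataset(cells, nodes, syn, list(inl_ipl_z = 0, ipl_gcl_z = 40)),
    "ghost")

  bad_radius <- transform(nodes, radius_um = -1)
  expect_error(
    new_dataset(cells, bad_radius, NULL,
                list(inl_ipl_z = 0, ipl_gcl_z = 40)),
    "radius")

  no_soma <- transform(nodes, tag = "dendrite")
  expect_error(
    new_dataset(cells, no_soma, NULL,
                list(inl_ipl_z = 0, ipl_gcl_z = 40)),
    "soma")

  cyclic <- rbind(nodes,
                  data.frame(cell_id = "c1", node_id = "2",
                             parent_id = "3", x_um = 1, y_um = 0, z_um = 0,
                             radius_um = 1, tag = "dendrite"),
                  data.frame(cell_id = "c1", node_id = "3",
                             parent_id = "2", x_um = 2, y_um = 0, z_um = 0,
                             radius_um = 1, tag = "dendrite"))
  expect_error(
    new_dataset(cells, cyclic, NULL,
                list(inl_ipl_z = 0, ipl_gcl_z = 40)),
    "cycle")

  # ribbon kind must match a bipolar presynaptic type when typed
  bad_kind <- data.frame(synapse_id = "s1", pre_cell_id = "a1",
                         post_cell_id = "c1", kind = "ribbon",
                         x_um = 0, y_um = 0, z_um = 0,
                         pre_type = "amacrine")
  expect_error(
    new_dataset(cells, nodes, bad_kind,
                list(inl_ipl_z = 0, ipl_gcl_z = 40)),
    "amacrine")
})

test_that("subset_synapses filters conjunctively with stable order", {
  rec <- chain_cell(6)
  syn <- synapses_on_nodes(
    rec, node_ids = as.character(2:7),
    kinds = c("ribbon", "conventional", "ribbon", "ribbon",
              "conventional", "ribbon"),
    pre_types = c("BC_DB5", "amacrine", "BC_DB4", "BC_giant",
                  "amacrine", "BC_DB5"))
  syn$node_id <- NULL
  cells <- data.frame(cell_id = "chain", cell_type = "RGC_smooth")
  ds <- new_dataset(cells, rec$nodes, syn,
                    list(inl_ipl_z = 0, ipl_gcl_z = 40))

  rib <- subset_synapses(ds, "chain", kind = "ribbon")
  expect_true(all(rib$kind == "ribbon"))
  expect_identical(nrow(rib), 4L)
  expect_identical(rib$synapse_id, sort(rib$synapse_id))

  expect_identical(
    nrow(subset_synapses(ds, "chain", pre_type = "BC_ON_midget")), 0L)
  expect_identical(nrow(subset_synapses(ds, "chain")), 6L)
  expect_error(subset_synapses(ds, "nope"), "unknown cell id")

  # counts are conserved by any disjoint partition
  by_kind <- vapply(c("ribbon", "conventional"), function(k)
    nrow(subset_synapses(ds, "chain", kind = k)), integer(1))
  expect_identical(sum(by_kind), nrow(ds$synapses))
  by_type <- vapply(unique(syn$pre_type), function(t)
    nrow(subset_synapses(ds, "chain", pre_type = t)), integer(1))
  expect_identical(sum(by_type), nrow(ds$synapses))
})

test_that("SWC export follows the 7-column convention", {
  rec <- square_cell()
  cells <- data.frame(cell_id = "sq", cell_type = "RGC_parasol")
  ds <- new_dataset(cells, rec$nodes, NULL,
                    list(inl_ipl_z = 0, ipl_gcl_z = 40))
  dir <- withr::local_tempdir()
  write_swc(ds, dir)
  swc <- utils::read.table(file.path(dir, "sq.swc"))
  expect_identical(nrow(swc), nrow(rec$nodes))
  expect_identical(ncol(swc), 7L)
  expect_identical(swc[[7]][1], -1L)          # root parent
  expect_identical(swc[[2]], c(1L, 3L, 3L, 3L, 3L))  # soma 1, dendrite 3
})

test_that("synapses attach to the nearest node, ties to the lower id", {
  rec <- chain_cell(4)
  syn <- data.frame(synapse_id = c("a", "b"), pre_cell_id = "p",
                    post_cell_id = "chain", kind = "conventional",
                    x_um = c(2.2, 2.5), y_um = 0, z_um = 0,
                    pre_type = "amacrine")
  att <- attach_synapses(rec, syn)
  expect_identical(att$node_id[1], "3")   # x = 2.2 nearest to node at x=2
  expect_identical(att$node_id[2], "3")   # tie between x=2 and x=3 -> "3"
})
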