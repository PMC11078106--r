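test_that("skeleton growth honours the config contract", {
  cfg <- skeleton_config(n_primary_dendrites = 4, field_radius = 75,
                         segment_length = 2, branch_prob = 0.2,
                         soma_radius = 6, stratification_z = 25, seed = 7)
  sk <- generate_skeleton(cfg)
  soma_id <- sk$nodes$node_id[sk$nodes$tag == "soma"]
  expect_length(soma_id, 1L)
  expect_identical(sum(sk$nodes$parent_id %in% soma_id), 4L)

  # all nodes stay within the field radius of the soma
  r <- sqrt(sk$nodes$x_um^2 + sk$nodes$y_um^2)
  expect_true(all(r <= 75 + 1e-9))

  # same seed, same table; different seed, different table
  expect_identical(generate_skeleton(cfg)$nodes, sk$nodes)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(generate_skeleton(cfg2)$nodes, sk$nodes))
})

test_that("impossible geometry is rejected", {
  expect_error(
    skeleton_config(n_primary_dendrites = 4, field_radius = 5,
                    segment_length = 10, branch_prob = 0.1,
                    soma_radius = 5, stratification_z = 25, seed = 1),
    "impossible geometry")
})

test_that("generated reconstructions satisfy the dataset invariants", {
  for (s in c(3, 14)) {
    sk <- generate_skeleton(smooth_skeleton_config(s))
    syn <- place_synapses(sk, smooth_synapse_model(s + 1))
    ds <- new_dataset(
      data.frame(cell_id = sk$cell_id, cell_type = sk$cell_type),
      sk$nodes, syn, list(inl_ipl_z = 0, ipl_gcl_z = 40))
    expect_s3_class(ds, "scene_dataset")
  }
})

test_that("amacrine_fraction = 1 places no ribbon synapses", {
  sk <- generate_skeleton(parasol_skeleton_config(5))
  m <- synapse_model(n_synapses = 50, amacrine_fraction = 1,
                     type_proportions = c(BC_DB4 = 1), seed = 6)
  syn <- place_synapses(sk, m)
  expect_identical(sum(syn$kind == "ribbon"), 0L)
  expect_identical(nrow(syn), 50L)
})

test_that("the amacrine fraction obeys the binomial law at n = 10^4", {
  sk <- generate_skeleton(smooth_skeleton_config(9))
  p <- 0.615; n <- 10000
  m <- synapse_model(n_synapses = n, amacrine_fraction = p,
                     bipolar_spatial = "mixture",
                     mixture_components = planted_hotspots(),
                     type_proportions = c(BC_DB5 = 0.55, BC_DB4 = 0.30,
                                          BC_giant = 0.15),
                     seed = 10)
  syn <- place_synapses(sk, m)
  expect_lt(abs(mean(syn$kind == "conventional") - p),
            3 * sqrt(p * (1 - p) / n))
})

test_that("planted tight clusters capture >= 95% of bipolar synapses", {
  sc <- planted_scene(31, n_synapses = 500)
  d_min <- apply(sc$points, 1, function(pt)
    min(sqrt(rowSums(sweep(sc$centers, 2, pt)^2))))
  expect_gte(mean(d_min <= 3 * 8), 0.95)
})

test_that("a mixture centred off the skeleton warns and falls back", {
  sk <- generate_skeleton(parasol_skeleton_config(4))
  far <- data.frame(weight = 1, x = 5000, y = 5000, sd = 2)
  m <- synapse_model(n_synapses = 20, amacrine_fraction = 0,
                     bipolar_spatial = "mixture",
                     mixture_components = far,
                     type_proportions = c(BC_DB4 = 1), seed = 2)
  expect_warning(syn <- place_synapses(sk, m), "negligible intensity")
  expect_identical(nrow(syn), 20L)
})

test_that("model constructors validate their probability inputs", {
  expect_error(synapse_model(10, amacrine_fraction = 0.5,
                             type_proportions = c(BC_DB4 = 0.7),
                             seed = 1),
               "sum to 1")
  bad_mix <- data.frame(weight = c(0.5, 0.2), x = 0, y = 0, sd = 1)
  expect_error(synapse_model(10, amacrine_fraction = 0.5,
                             bipolar_spatial = "mixture",
                             mixture_components = bad_mix,
                             type_proportions = c(BC_DB4 = 1), seed = 1),
               "weights")
})

test_that("paired scenes bundle all cells with ground truth", {
  sc <- generate_paired_scene(
    smooth_skeleton_config(41),
    list(parasol_skeleton_config(42, c(-40, 0)),
         parasol_skeleton_config(43, c(0, 0)),
         parasol_skeleton_config(44, c(40, 0))),
    smooth_synapse_model(45))
  expect_identical(nrow(sc$cells), 4L)
  expect_setequal(unique(sc$synapses$post_cell_id),
                  c("smooth_1", "parasol_1", "parasol_2", "parasol_3"))

  truth <- attr(sc, "truth")
  expect_equal(truth$mixture_components, planted_hotspots())
  expect_equal(truth$amacrine_fraction, 0.615)

  # determinism of the whole scene
  sc2 <- generate_paired_scene(
    smooth_skeleton_config(41),
    list(parasol_skeleton_config(42, c(-40, 0)),
         parasol_skeleton_config(43, c(0, 0)),
         parasol_skeleton_config(44, c(40, 0))),
    smooth_synapse_model(45))
  expect_identical(sc$nodes, sc2$nodes)
  expect_identical(sc$synapses, sc2$synapses)
})

test_that("parasol somas outside the smooth field are rejected", {
  expect_error(
    generate_paired_scene(
      smooth_skeleton_config(1),
      list(parasol_skeleton_config(2, c(200, 0))),
      smooth_synapse_model(3)),
    "outside")
})
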