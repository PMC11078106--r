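test_that("amacrine probability from counts or a stated ratio", {
  expect_equal(amacrine_probability(ratio = c(1.6, 1)), 1.6 / 2.6)
  expect_equal(amacrine_probability(ratio = c(160, 100)), 160 / 260)

  syn <- data.frame(kind = c(rep("conventional", 160), rep("ribbon", 100)))
  expect_equal(amacrine_probability(syn), 160 / 260)
  all_ama <- data.frame(kind = rep("conventional", 7))
  expect_equal(amacrine_probability(all_ama), 1)

  expect_error(amacrine_probability(ratio = c(0, 0)), "zero total")
  expect_error(amacrine_probability(data.frame(kind = character(0))),
               "zero total")
})

test_that("the geometric run null matches p^N", {
  p <- 1.6 / 2.6
  expect_equal(run_probability(p, 0), 1)
  expect_equal(run_probability(p, 5), p^5)
  expect_equal(run_probability(0.5, 3), 0.125)
  expect_error(run_probability(1.2, 3))
  expect_error(run_probability(0.5, 2.5))
})

test_that("the run null agrees with Monte-Carlo window simulation", {
  p <- 0.6; N <- 5; reps <- 1e5
  hits <- withr::with_seed(77, {
    draws <- matrix(runif(reps * N) < p, ncol = N)
    mean(rowSums(draws) == N)
  })
  se <- sqrt(p^N * (1 - p^N) / reps)
  expect_lt(abs(hits - p^N), 3 * se)
})

test_that("maximal amacrine runs are found along an unbranched path", {
  rec <- chain_cell(4)
  syn <- synapses_on_nodes(rec, as.character(2:5),
                           kinds = c("conventional", "conventional",
                                     "ribbon", "conventional"))
  runs <- find_amacrine_runs(rec, syn)
  expect_setequal(runs$run_length, c(2L, 1L))

  sole <- chain_cell(13)
  syn13 <- synapses_on_nodes(sole, as.character(2:14),
                             kinds = rep("conventional", 13))
  runs13 <- find_amacrine_runs(sole, syn13)
  expect_identical(nrow(runs13), 1L)
  expect_identical(runs13$run_length, 13L)

  no_ama <- synapses_on_nodes(rec, as.character(2:3),
                              kinds = rep("ribbon", 2))
  expect_identical(nrow(find_amacrine_runs(rec, no_ama)), 0L)
})

test_that("runs on a shared prefix are deduplicated across branches", {
  # Y-shaped tree: soma 1 -> 2 -> 3, then 3 -> 4a and 3 -> 4b
  nodes <- data.frame(
    cell_id = "y", node_id = c("1", "2", "3", "4", "5"),
    parent_id = c(NA, "1", "2", "3", "3"),
    x_um = c(0, 1, 2, 3, 3), y_um = c(0, 0, 0, 1, -1), z_um = 0,
    radius_um = c(5, rep(0.5, 4)),
    tag = c("soma", rep("dendrite", 4)), stringsAsFactors = FALSE)
  rec <- structure(list(cell_id = "y", cell_type = "RGC_smooth",
                        nodes = nodes),
                   class = "neuron_reconstruction")
  # amacrine run on the shared prefix (nodes 2, 3), ribbon on both leaves
  syn <- synapses_on_nodes(rec, c("2", "3", "4", "5"),
                           kinds = c("conventional", "conventional",
                                     "ribbon", "ribbon"))
  runs <- find_amacrine_runs(rec, syn)
  expect_identical(nrow(runs), 1L)    # one run, not one per leaf path
  expect_identical(runs$run_length, 2L)

  # per-path amacrine counts equal the summed run lengths
  sc <- planted_scene(6, n_synapses = 60)
  mixed <- place_synapses(sc$skeleton, smooth_synapse_model(61))
  att <- attach_synapses(sc$skeleton, mixed)
  runs2 <- find_amacrine_runs(sc$skeleton, att)
  # every amacrine synapse belongs to at least one maximal run
  total_in_runs <- length(unique(unlist(runs2$synapse_ids)))
  expect_identical(total_in_runs, sum(att$kind == "conventional"))
})

test_that("partner profiles count synapses per presynaptic cell", {
  syn <- data.frame(
    synapse_id = sprintf("s%02d", 1:4),
    pre_cell_id = c("b1", "b1", "b1", "b2"),
    post_cell_id = "c", kind = "ribbon",
    x_um = 0, y_um = 0, z_um = 0,
    pre_type = c("BC_DB5", "BC_DB5", "BC_DB5", "BC_DB4"))
  pp <- partner_profile(syn)
  expect_identical(pp$n_partners, 2L)
  expect_equal(pp$mean_synapses_per_partner, 2)
  expect_identical(unname(pp$histogram["1", "BC_DB4"]), 1L)
  expect_identical(unname(pp$histogram["3", "BC_DB5"]), 1L)

  # totals conserved under the type partition
  expect_identical(sum(pp$totals_by_type), nrow(syn))

  single <- data.frame(synapse_id = sprintf("s%02d", 1:33),
                       pre_cell_id = "b9", post_cell_id = "c",
                       kind = "ribbon", x_um = 0, y_um = 0, z_um = 0,
                       pre_type = "BC_DB4")
  pp33 <- partner_profile(single)
  expect_identical(max(pp33$per_partner$n_synapses), 33L)
})

test_that("classification rates match the printed convention", {
  syn <- data.frame(synapse_id = as.character(1:10),
                    kind = "ribbon",
                    pre_type = rep("unclassified", 10))
  expect_equal(classification_rate(syn)$percent, 0)
  expect_error(classification_rate(syn[0, ]), "zero ribbon")
})

test_that("Fisher's exact test matches enumeration and the stock test", {
  t1 <- rbind(c(3, 1), c(1, 3))
  expect_equal(fisher_exact_2x2(t1), 34 / 70)
  expect_equal(fisher_exact_2x2(t1), fisher_enum(t1))

  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10))

  for (s in 1:20) {
    tab <- withr::with_seed(s, matrix(rpois(4, 6), 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  }

  # doubling rule: twice the smaller tail, capped at 1
  expect_equal(fisher_exact_2x2(t1, method = "doubling"),
               min(1, 2 * min(phyper(3, 4, 4, 4),
                              phyper(2, 4, 4, 4, lower.tail = FALSE))))
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("overlap analysis classifies membership boundary-inclusively", {
  ref <- square_cell()
  syn <- data.frame(
    synapse_id = c("in", "vertex", "out"),
    pre_cell_id = c("b1", "b2", "b3"),
    post_cell_id = "other", kind = "ribbon",
    x_um = c(5, 10, 20), y_um = c(5, 10, 5), z_um = 0,
    pre_type = "BC_DB5")
  rep <- overlap_analysis(syn, ref)
  expect_identical(rep$member, c(TRUE, TRUE, FALSE))
  expect_equal(rep$distances[1], 0)          # centroid of the square
  expect_identical(rep$n_member, 2L)

  # shared partners require the reference cell's synapse table
  ref_syn <- data.frame(
    synapse_id = c("r1", "r2"), pre_cell_id = c("b1", "b9"),
    post_cell_id = "sq", kind = "ribbon",
    x_um = 1, y_um = 1, z_um = 0, pre_type = c("BC_DB5", "BC_DB4"))
  rep2 <- overlap_analysis(syn, ref, ref_syn)
  expect_identical(rep2$shared_partners$pre_cell_id, "b1")
})
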