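test_that("generation is deterministic under a seed", {
  p <- generator_params(seed = 99)
  m1 <- generate_sme_map(p)
  m2 <- generate_sme_map(p)
  expect_true(map_identical(m1, m2, compare_origins = TRUE))
  pan1 <- generate_panel(generator_params(seed = 7, n_smes = 3))
  pan2 <- generate_panel(generator_params(seed = 7, n_smes = 3))
  for (i in 1:3)
    expect_true(map_identical(pan1$maps[[i]], pan2$maps[[i]],
                              compare_origins = TRUE))
  expect_identical(pan1$truth$true_thesaurus$entries,
                   pan2$truth$true_thesaurus$entries)
})

test_that("maps have the exact edge count, contain the focal concept, and are weakly connected", {
  set.seed(17)
  p <- generator_params()
  for (rep in 1:5) {
    m <- generate_sme_map(p, focal = "the problem")
    expect_equal(n_edges(m), p$edges_per_map)
    expect_true("the problem" %in% m$concepts$id)
    comp <- igraph::components(as_igraph(m), mode = "weak")
    expect_equal(comp$no, 1L)
    expect_false(any(m$edges$src == m$edges$dst))
    expect_false(anyDuplicated(paste(m$edges$src, m$edges$dst)) > 0)
  }
})

test_that("back-edges are the only source of cycles", {
  set.seed(23)
  p0 <- generator_params(p_backedge = 0)
  for (rep in 1:5)
    expect_false(census(generate_sme_map(p0))$has_cycles)
  p1 <- generator_params(p_backedge = 0.15)
  for (rep in 1:5)
    expect_true(census(generate_sme_map(p1))$has_cycles)
})

test_that("infeasible parameter combinations fail before generation", {
  expect_error(generator_params(p_negative = 1.2), "in \\[0, 1\\]")
  expect_error(generator_params(edges_per_map = 10), "at least")
  expect_error(generator_params(n_concept_pool = 50), "pool too small")
  expect_error(generator_params(target_diameter = 2), ">= 4")
})

test_that("panel ground truth is consistent: membership union equals the pooled map", {
  pan <- generate_panel(generator_params(seed = 31, n_smes = 6))
  union_keys <- sort(unique(unlist(lapply(pan$truth$per_map_membership,
    function(e) paste0(norm_label(e$src), ">", norm_label(e$dst), ":", e$sign)))))
  expect_equal(union_keys, edge_keys(pan$truth$pooled_map))
})

test_that("aggregation with the true thesaurus reconstructs the pooled graph exactly", {
  pan <- generate_panel(generator_params(seed = 43, n_smes = 8))
  agg <- aggregate_maps(pan$maps, pan$truth$true_thesaurus, map_id = "pooled")
  expect_true(map_identical(agg$map, pan$truth$pooled_map,
                            compare_origins = TRUE))
  expect_equal(agg$report$n_sign_conflicts, 0L)
})

test_that("alias_rate drives lexical variation: 0 needs no thesaurus, 1 splits every shared term", {
  pan0 <- generate_panel(generator_params(seed = 5, n_smes = 4,
                                          alias_rate = 0))
  expect_length(pan0$truth$true_thesaurus, 0L)
  agg_plain <- aggregate_maps(pan0$maps)
  expect_true(map_identical(agg_plain$map, pan0$truth$pooled_map,
                            compare_origins = TRUE))

  pan1 <- generate_panel(generator_params(seed = 5, n_smes = 4,
                                          alias_rate = 1))
  no_th <- aggregate_maps(pan1$maps)$map
  expect_gt(n_concepts(no_th), n_concepts(pan1$truth$pooled_map))
  with_th <- aggregate_maps(pan1$maps, pan1$truth$true_thesaurus)$map
  expect_true(map_identical(with_th, pan1$truth$pooled_map))
})

test_that("injected sign conflicts surface in the merge report", {
  pan <- generate_panel(generator_params(seed = 77, n_smes = 10,
                                         conflict_rate = 0.2))
  agg <- aggregate_maps(pan$maps, pan$truth$true_thesaurus)
  expect_gt(agg$report$n_sign_conflicts, 0L)
})
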