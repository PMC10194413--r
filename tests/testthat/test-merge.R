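th_racism <- thesaurus(c("structural racism", "racial injustice"),
                       c("racism", "racism"))

test_that("canonicalization unites variant concepts and keeps their names as aliases", {
  m <- mk_map("structural racism +poverty", "racial injustice +crime")
  out <- canonicalize(m, th_racism)
  expect_equal(n_concepts(out), 3L)
  i <- match("racism", out$concepts$id)
  expect_false(is.na(i))
  expect_setequal(out$concepts$aliases[[i]],
                  c("structural racism", "racial injustice"))
  expect_setequal(edge_keys(out), c("racism>poverty:1", "racism>crime:1"))
})

test_that("canonicalization is idempotent", {
  m <- mk_map("structural racism +poverty", "poverty +racial injustice")
  once <- canonicalize(m, th_racism)
  twice <- canonicalize(once, th_racism)
  expect_true(map_identical(once, twice, compare_origins = TRUE))
})

test_that("edges collapsing to self-loops are dropped and recorded", {
  m <- mk_map("structural racism +racial injustice", "poverty +crime")
  out <- canonicalize(m, th_racism)
  rep <- attr(out, "canonicalize_report")
  expect_equal(nrow(rep$collapsed_self_loops), 1L)
  expect_equal(rep$collapsed_self_loops$canonical, "racism")
  expect_equal(n_edges(out), 1L)
  expect_true("racism" %in% out$concepts$id)  # the united concept remains
})

test_that("aggregation merges provenance under the majority policy", {
  m1 <- causal_map("m1"); m1 <- add_edge(m1, "A", "B", +1)
  m2 <- causal_map("m2"); m2 <- add_edge(m2, "A", "B", +1)
  agg <- aggregate_maps(list(m1, m2))
  expect_equal(edges_df(agg$map)$n_pos, 2L)
  expect_equal(n_edges(agg$map), 1L)

  m3 <- causal_map("m3"); m3 <- add_edge(m3, "A", "B", -1)
  m4 <- causal_map("m4"); m4 <- add_edge(m4, "A", "B", +1)
  agg <- aggregate_maps(list(m1, m3, m4))
  e <- edges_df(agg$map)
  expect_equal(e$polarity, 1L)
  expect_equal(agg$report$n_sign_conflicts, 1L)

  expect_error(aggregate_maps(list()), "non-empty")
})

test_that("single-map aggregation equals canonicalization and [M, M] doubles provenance", {
  m <- mk_map("structural racism -poverty", "poverty +crime", map_id = "solo")
  expect_true(map_identical(aggregate_maps(list(m), th_racism)$map,
                            canonicalize(m, th_racism),
                            compare_origins = TRUE))
  dup <- aggregate_maps(list(m, m), th_racism)$map
  can <- canonicalize(m, th_racism)
  expect_setequal(paste0(dup$edges$src, ">", dup$edges$dst),
                  paste0(can$edges$src, ">", can$edges$dst))
  i <- match(paste0(can$edges$src, ">", can$edges$dst),
             paste0(dup$edges$src, ">", dup$edges$dst))
  expect_equal(dup$edges$n_pos[i], 2L * can$edges$n_pos)
  expect_equal(dup$edges$n_neg[i], 2L * can$edges$n_neg)
  expect_equal(dup$edges$polarity[i], can$edges$polarity)
})

test_that("aggregation is invariant to panel order", {
  set.seed(404)
  pan <- generate_panel(generator_params(n_smes = 5))
  a <- aggregate_maps(pan$maps, pan$truth$true_thesaurus)$map
  b <- aggregate_maps(rev(pan$maps), pan$truth$true_thesaurus)$map
  p <- sample(length(pan$maps))
  c_ <- aggregate_maps(pan$maps[p], pan$truth$true_thesaurus)$map
  expect_true(map_identical(a, b, compare_origins = TRUE))
  expect_true(map_identical(a, c_, compare_origins = TRUE))
})

test_that("merge report counts terms that appeared under several names", {
  m1 <- mk_map("structural racism +poverty", map_id = "m1")
  m2 <- mk_map("racial injustice +poverty", map_id = "m2")
  agg <- aggregate_maps(list(m1, m2), th_racism)
  expect_equal(agg$report$n_maps, 2L)
  expect_equal(agg$report$n_terms_resolved, 1L)  # racism, seen as 2 forms
  expect_equal(as.integer(agg$report$variants_per_term[["racism"]]), 2L)
})

test_that("alias suggestion ranks word-permuted labels high and never proposes identical ones", {
  m1 <- mk_map("family financial stress +poverty", map_id = "m1")
  m2 <- mk_map("financial stress (family) +poverty", map_id = "m2")
  sug <- suggest_aliases(list(m1, m2), similarity_floor = 0.8)
  expect_gte(nrow(sug), 1L)
  expect_setequal(unlist(sug[1, c("label1", "label2")]),
                  c("family financial stress", "financial stress (family)"))
  expect_equal(sug$similarity[1], 1)
  # identical labels are already unified by normalization -> no pairs
  m3 <- mk_map("poverty +crime", map_id = "m3")
  m4 <- mk_map("Poverty +crime", map_id = "m4")
  sug <- suggest_aliases(list(m3, m4), similarity_floor = 0.95)
  expect_false(any(sug$label1 == "poverty" & sug$label2 == "Poverty"))
  # disjoint vocabularies at a high floor -> empty
  m5 <- mk_map("aaaa +bbbb", map_id = "m5")
  m6 <- mk_map("qqqq +zzzz", map_id = "m6")
  expect_equal(nrow(suggest_aliases(list(m5, m6), 0.8)), 0L)
  expect_error(suggest_aliases(list(m5)), "at least two")
})
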