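test_that("the plan lists endpoints for review and degree-1/1 skippables", {
  m <- mk_map("A +B", "B +C")
  plan <- propose_plan(m)
  expect_equal(plan$endpoints_for_review$sources, "A")
  expect_equal(plan$endpoints_for_review$receivers, "C")
  expect_equal(plan$skippable, "B")
  expect_length(plan$to_remove, 0L)

  # in-degree 2 disqualifies
  m2 <- mk_map("A +B", "C +B", "B +D")
  expect_length(propose_plan(m2)$skippable, 0L)

  # protected and focal transmitters are not offered
  m3 <- mk_map("A +B", "B +C", focal = "B")
  expect_length(propose_plan(m3)$skippable, 0L)
  m4 <- set_protected(mk_map("A +B", "B +C"), "B")
  expect_length(propose_plan(m4)$skippable, 0L)
})

test_that("pruning removes endpoints with their incident edges and refuses the rest", {
  m <- mk_map("A +B", "B +C")
  out <- prune_endpoints(m, "A")
  expect_equal(edge_keys(out), "b>c:1")
  expect_equal(unname(classify_nodes(out)["B"]), "source")

  hub <- mk_map("a +R", "b +R", "c +R")
  out <- prune_endpoints(hub, "R")
  expect_equal(n_edges(out), 0L)
  expect_equal(n_concepts(out), 3L)

  expect_error(prune_endpoints(m, "B"), "not a source or receiver")
  expect_error(prune_endpoints(m, "nope"), "unknown")
  expect_error(prune_endpoints(set_protected(m, "A"), "A"), "protected")
  expect_error(prune_endpoints(mk_map("A +B", focal = "A"), "A"), "protected")
})

test_that("iterative pruning reports newly exposed endpoints without removing them", {
  m <- mk_map("A +B", "B +C", "C +D")
  out <- prune_endpoints(m, "A", iterative = TRUE)
  expect_equal(attr(out, "newly_exposed"), "B")
  expect_equal(n_concepts(out), 3L)
})

test_that("pruning matches brute-force set subtraction on random maps", {
  set.seed(505)
  for (rep in 1:15) {
    m <- rand_map(sample(4:9, 1), runif(1, 0.15, 0.4))
    roles <- classify_nodes(m)
    ends <- names(roles)[roles %in% c("source", "receiver")]
    if (length(ends) == 0L) next
    pick <- sample(ends, min(length(ends), 2L))
    out <- prune_endpoints(m, pick)
    ids <- norm_label(pick)
    expect_equal(n_concepts(out), n_concepts(m) - length(pick))
    expect_equal(n_edges(out),
                 n_edges(m) - sum(m$edges$src %in% ids | m$edges$dst %in% ids))
    expect_setequal(out$concepts$id, setdiff(m$concepts$id, ids))
  }
})

test_that("contraction multiplies signs along the chain", {
  expect_equal(edge_keys(contract_chains(mk_map("A +B", "B -C"), "B")),
               "a>c:-1")
  expect_equal(edge_keys(contract_chains(mk_map("A -B", "B -C"), "B")),
               "a>c:1")
  # transitive contraction of two approved skippables
  m <- mk_map("A +B", "B +C", "C -D")
  out <- contract_chains(m, c("B", "C"))
  expect_equal(edge_keys(out), "a>d:-1")
  expect_equal(attr(out, "contract_report")$status, c("contracted", "contracted"))
})

test_that("contraction refuses self-loop closure, conflicted edges and wrong degrees", {
  # 2-node feedback loop stays intact
  loop <- mk_map("A +B", "B +A")
  out <- contract_chains(loop, "B")
  expect_equal(n_concepts(out), 2L)
  expect_equal(attr(out, "contract_report")$status, "skipped-self-loop")

  m <- causal_map()
  m <- add_edge(m, "A", "B", +1, origin = "m1")
  m <- add_edge(m, "A", "B", -1, origin = "m2")
  m <- add_edge(m, "B", "C", +1, origin = "m1")
  out <- contract_chains(m, "B")
  expect_equal(attr(out, "contract_report")$status, "skipped-conflicted")

  m2 <- mk_map("A +B", "C +B", "B +D")
  out <- contract_chains(m2, "B")
  expect_equal(attr(out, "contract_report")$status, "skipped-degree")
  expect_equal(n_concepts(out), 4L)
})

test_that("merging a contracted edge into an opposite-signed edge flags a conflict", {
  m <- mk_map("A +B", "B +C", "A -C")
  out <- contract_chains(m, "B")
  e <- edges_df(out)
  expect_equal(nrow(e), 1L)
  expect_true(e$conflicted)
  # same-signed merge stays clean
  m2 <- mk_map("A +B", "B +C", "A +C")
  e2 <- edges_df(contract_chains(m2, "B"))
  expect_false(e2$conflicted)
  expect_equal(e2$polarity, 1L)
})

test_that("contraction preserves path-sign products and never creates reachability", {
  set.seed(606)
  for (rep in 1:25) {
    m <- rand_map(sample(4:8, 1), runif(1, 0.15, 0.4))
    plan <- propose_plan(m)
    if (length(plan$skippable) == 0L) next
    out <- contract_chains(m, plan$skippable)
    done <- attr(out, "contract_report")
    k <- sum(done$status == "contracted")
    merged <- n_edges(out) != n_edges(m) - k
    ids <- out$concepts$id
    g_old <- igraph::distances(as_igraph(m), mode = "out")
    g_new <- igraph::distances(as_igraph(out), mode = "out")
    for (u in ids) for (v in ids) {
      if (u == v) next
      # no new reachability
      if (is.finite(g_new[u, v])) expect_true(is.finite(g_old[u, v]))
      # sign multisets agree unless a contracted edge was merged into an
      # existing parallel edge (which collapses the multiset by design)
      if (!merged) {
        expect_equal(oracle_path_signs(out, u, v), oracle_path_signs(m, u, v),
                     label = sprintf("paths %s->%s rep %d", u, v, rep))
      }
    }
    # degrees of non-neighbours of contracted nodes are untouched
    con <- done$label[done$status == "contracted"]
    nbr <- unique(c(m$edges$src[m$edges$dst %in% con],
                    m$edges$dst[m$edges$src %in% con]))
    untouched <- setdiff(ids, c(nbr, con))
    if (length(untouched) > 0L) {
      d_old <- degree_stats(m)$degree
      d_new <- degree_stats(out)$degree
      labs <- m$concepts$label[match(untouched, m$concepts$id)]
      expect_equal(d_new[labs], d_old[labs])
    }
  }
})
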