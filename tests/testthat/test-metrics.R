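test_that("a chain classifies as source -> transmitter -> receiver", {
  m <- mk_map("A +B", "B +C")
  expect_equal(unname(classify_nodes(m)[c("A", "B", "C")]),
               c("source", "transmitter", "receiver"))
})

test_that("density is m / (n (n-1)) with its edge cases", {
  m <- mk_map("A +B")
  expect_equal(map_density(m), 0.5)
  expect_error(map_density(causal_map()), "undefined")
  expect_error(map_density(add_concept(causal_map(), "A")), "undefined")
  # complete digraph on 3 nodes
  k3 <- causal_map()
  for (a in c("A", "B", "C")) for (b in c("A", "B", "C"))
    if (a != b) k3 <- add_edge(k3, a, b, +1)
  expect_equal(map_density(k3), 1)
})

test_that("degree statistics use total degree with lexicographic tie reporting", {
  m <- mk_map("A +B")
  ds <- degree_stats(m)
  expect_equal(ds$avg_degree, 1)
  expect_equal(ds$max_degree, 1L)
  expect_equal(ds$max_degree_concepts, c("A", "B"))
  star <- mk_map("H +a", "H +b", "H +c", "H +d", "H +e")
  ds <- degree_stats(star)
  expect_equal(ds$max_degree, 5L)
  expect_equal(ds$max_degree_concepts, "H")
  expect_equal(ds$avg_degree, 2 * 5 / 6)
})

test_that("diameter is the longest finite shortest path; disconnection is ignored", {
  chain4 <- mk_map("A +B", "B +C", "C +D", "D +E")
  expect_equal(map_diameter(chain4), 4L)
  two <- mk_map("A +B", "B +C", "C +D", "x +y", "y +z")
  # components of diameter 3 and 2 -> 3
  expect_equal(map_diameter(two), 3L)
  expect_error(map_diameter(causal_map()), "undefined")
  # undirected mode sees paths against edge direction
  v <- mk_map("A +C", "B +C")
  expect_equal(map_diameter(v, "undirected"), 2L)
})

test_that("cycle census signs loops as reinforcing or balancing", {
  m <- mk_map("A +B", "B -A")
  cc <- cycle_census(m)
  expect_true(cc$has_cycles)
  expect_equal(nrow(cc$cycles), 1L)
  expect_equal(cc$cycles$sign, -1L)
  expect_equal(cc$cycles$type, "balancing")

  dag <- mk_map("A +B", "A +C", "B +D", "C +D")
  cc <- cycle_census(dag)
  expect_false(cc$has_cycles)
  expect_equal(nrow(cc$cycles), 0L)

  # two negatives multiply to a reinforcing loop
  m3 <- mk_map("A -B", "B +C", "C -A")
  cc <- cycle_census(m3)
  expect_equal(cc$cycles$sign, 1L)
  expect_equal(cc$cycles$type, "reinforcing")
})

test_that("cycle enumeration respects length and count caps", {
  k5 <- causal_map()
  labs <- paste0("v", 1:5)
  for (a in labs) for (b in labs) if (a != b) k5 <- add_edge(k5, a, b, +1)
  full <- cycle_census(k5, max_len = 5L)
  short <- cycle_census(k5, max_len = 2L)
  expect_true(all(short$cycles$length == 2L))
  expect_equal(nrow(short$cycles), choose(5, 2))
  expect_gt(nrow(full$cycles), nrow(short$cycles))
  capped <- cycle_census(k5, max_len = 5L, max_cycles = 3L)
  expect_true(capped$truncated)
  expect_equal(nrow(capped$cycles), 3L)
  expect_true(capped$has_cycles)
})

test_that("diameter, roles and signed cycle sets match brute force on small digraphs", {
  set.seed(303)
  for (rep in 1:40) {
    m <- rand_map(sample(3:8, 1), runif(1, 0.1, 0.5))
    if (n_edges(m) == 0L) next
    expect_equal(classify_nodes(m), oracle_roles(m))
    expect_equal(map_diameter(m), oracle_diameter(m))
    expect_equal(map_diameter(m, "undirected"),
                 oracle_diameter(m, "undirected"))
    cc <- cycle_census(m, max_len = 8L)
    expect_equal(census_cycle_keys(m, cc), oracle_cycles(m))
  }
})

test_that("structural QC flags missing loops, short chains, parameter overload and density", {
  star <- mk_map("H +a", "H +b", "H +c", "H +d")
  f <- validate_map(star)
  expect_true(all(c("cycles", "diameter") %in% f$criterion))
  # one long chain: diameter passes, cycles still fire
  chain <- mk_map("A +B", "B +C", "C +D", "D +E", "E +F")
  f <- validate_map(chain)
  expect_true("cycles" %in% f$criterion)
  expect_false("diameter" %in% f$criterion)
  # dense two-node loop trips the density ceiling and nothing about cycles
  loop <- mk_map("A +B", "B +A")
  f <- validate_map(loop)
  expect_true("density" %in% f$criterion)
  expect_false("cycles" %in% f$criterion)
})

test_that("the census partitions nodes and computes degree concentration", {
  m <- mk_map("A +B", "B +C", "C -A", "B +D")
  cen <- census(m)
  expect_equal(cen$n_sources + cen$n_receivers + cen$n_transmitters +
                 cen$n_isolated, cen$n_nodes)
  expect_equal(cen$avg_degree, 2 * cen$n_edges / cen$n_nodes)
  expect_equal(cen$degree_concentration, cen$max_degree / cen$n_edges)
  expect_true(cen$has_cycles)

  empty4 <- Reduce(add_concept, paste0("c", 1:4), causal_map())
  cen <- census(empty4)
  expect_equal(cen$n_isolated, 4L)
  expect_true(is.na(cen$diameter))
  expect_equal(cen$n_edges, 0L)

  # a map with max degree 15 out of 85 edges concentrates 15/85 of links
  expect_equal(round(15 / 85, 3), 0.176)
})
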