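mk_edges <- function(a, b, s) data.frame(node_a = a, node_b = b, score = s,
                                         stringsAsFactors = FALSE)

test_that("graph construction canonicalizes, thresholds and keeps isolates", {
  g <- build_graph(mk_edges(character(), character(), numeric()),
                   node_universe = sprintf("N%d", 1:5))
  expect_equal(igraph::vcount(g$graph), 5)
  expect_equal(nrow(g$edges), 0)

  # duplicate unordered pair collapses
  g2 <- build_graph(mk_edges(c("A", "B"), c("B", "A"), c(0.9, 0.8)),
                    node_universe = c("A", "B"))
  expect_equal(nrow(g2$edges), 1)

  # threshold is inclusive at >= 0.4
  g3 <- build_graph(mk_edges(c("A", "A", "B"), c("B", "C", "C"),
                             c(0.39, 0.40, 0.41)),
                    node_universe = c("A", "B", "C"))
  expect_equal(nrow(g3$edges), 2)

  # foreign endpoints dropped with a warning
  expect_warning(
    g4 <- build_graph(mk_edges("A", "Z", 0.9), node_universe = c("A", "B")),
    "outside")
  expect_equal(nrow(g4$edges), 0)

  # idempotence: rebuilding from retained edges changes nothing
  g5 <- build_graph(g3$edges, c("A", "B", "C"))
  expect_equal(g5$edges, g3$edges)
})

test_that("component summary: main component, orphans, partition", {
  g <- build_graph(mk_edges(c("A", "B", "X"), c("B", "C", "Y"),
                            c(0.9, 0.9, 0.9)),
                   node_universe = c("A", "B", "C", "X", "Y", "Z"))
  cs <- component_summary(g)
  expect_equal(cs$main_component_ids, c("A", "B", "C"))
  # orphans are all universe nodes outside the largest component,
  # including the X-Y doubleton and the isolated Z
  expect_equal(cs$orphan_ids, c("X", "Y", "Z"))
  expect_equal(sum(cs$sizes), 6)
  expect_equal(cs$main_fraction, 0.5)
  # complete graph: a single component, no orphans
  cg <- build_graph(mk_edges(c("A", "A", "B"), c("B", "C", "C"), 0.9),
                    node_universe = c("A", "B", "C"))
  expect_equal(component_summary(cg)$n_orphans, 0)
  # single node, no edges: main component of size 1
  s1 <- component_summary(build_graph(mk_edges(character(), character(),
                                               numeric()), "solo"))
  expect_equal(s1$main_size, 1)
  expect_equal(s1$n_orphans, 0)
})

test_that("components agree with an independent union-find on random graphs", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    ne <- sample(0:(2 * n), 1)
    ea <- sample(nodes, ne, replace = TRUE)
    eb <- sample(nodes, ne, replace = TRUE)
    keep <- ea != eb
    g <- build_graph(mk_edges(ea[keep], eb[keep],
                              runif(sum(keep), 0.4, 1)), nodes)
    cs <- component_summary(g)
    comp <- oracle_components(nodes, g$edges$node_a, g$edges$node_b)
    sizes <- sort(unname(vapply(comp, length, 1L)), decreasing = TRUE)
    expect_equal(cs$sizes, sizes)
    expect_equal(cs$main_size, max(sizes))
    # partition property
    expect_equal(sum(cs$sizes), n)
    expect_setequal(c(cs$main_component_ids, cs$orphan_ids), nodes)
  }
})

test_that("simulated networks carry their planted component structure", {
  nodes <- sprintf("L%03d", 1:100)
  net <- simulate_network(nodes, main_fraction = 0.9, n_orphans = 10,
                          seed = 17)
  g <- build_graph(net$edges, nodes)
  cs <- component_summary(g)
  expect_equal(cs$main_size, 90)
  expect_equal(cs$n_orphans, 10)
  expect_setequal(cs$main_component_ids, net$truth$main_component_ids)
  expect_setequal(cs$orphan_ids, net$truth$orphan_ids)
  # planted orphans appear in no edge
  expect_length(intersect(net$truth$orphan_ids,
                          c(net$edges$node_a, net$edges$node_b)), 0)
  # main_fraction = 1: no orphans at all
  net2 <- simulate_network(nodes, main_fraction = 1, seed = 17)
  expect_equal(component_summary(build_graph(net2$edges, nodes))$n_orphans, 0)
  # infeasible orphan count
  expect_error(simulate_network(nodes, 0.9, n_orphans = 99), "infeasible")
})

test_that("neighborhood extraction is an induced ball around the seed", {
  # chain A-B-C-D
  g <- build_graph(mk_edges(c("A", "B", "C"), c("B", "C", "D"), 0.9),
                   node_universe = c("A", "B", "C", "D"))
  expect_equal(extract_neighborhood(g, "A", 0)$node_universe, "A")
  nb <- extract_neighborhood(g, "A", 2)
  expect_equal(nb$node_universe, c("A", "B", "C"))
  expect_error(extract_neighborhood(g, "Q", 1), "not in the node universe")
  # star graph: radius 1 from the hub covers everything
  star <- build_graph(mk_edges(rep("H", 4), sprintf("S%d", 1:4), 0.9),
                      node_universe = c("H", sprintf("S%d", 1:4)))
  expect_length(extract_neighborhood(star, "H", 1)$node_universe, 5)
})

test_that("uncharacterized proteins are flagged and partitioned", {
  ann <- data.frame(id = c("A", "B", "C", "X", "Z"),
                    description = c("kinase", "", "unknown", "ligase", NA),
                    stringsAsFactors = FALSE)
  g <- build_graph(mk_edges(c("A", "B"), c("B", "C"), 0.9),
                   node_universe = c("A", "B", "C", "X", "Z"))
  cs <- component_summary(g)
  fl <- flag_uncharacterized(c("A", "B", "C", "X", "Z"), ann, cs)
  expect_setequal(fl$id, c("B", "C", "Z"))
  expect_equal(fl$membership[fl$id == "Z"], "orphan")
  expect_equal(sort(fl$membership[fl$id %in% c("B", "C")]), c("main", "main"))
  # everything annotated: nothing flagged
  ann2 <- data.frame(id = "A", description = "kinase")
  expect_equal(nrow(flag_uncharacterized("A", ann2)), 0)
  expect_equal(nrow(flag_uncharacterized(character(), ann2)), 0)
})
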