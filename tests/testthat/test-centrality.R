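test_that("closed forms: path, star, complete graph", {
  # path a-b-c: b mediates the single a-c pair
  p3 <- makeProjected(c("a", "b"), c("b", "c"), c(1L, 1L))
  v <- centralityValues(betweennessCentrality(p3))
  expect_equal(v, c(a = 0, b = 1, c = 0))

  # star K_{1,4}: center mediates all C(4,2) = 6 leaf pairs, leaves 0
  star <- makeProjected(rep("ctr", 4), paste0("leaf", 1:4), rep(1L, 4))
  vs <- centralityValues(betweennessCentrality(star))
  expect_equal(vs[["ctr"]], 6)
  expect_true(all(vs[names(vs) != "ctr"] == 0))
  # normalized: 6 / ((5-1)(5-2)/2) = 1
  vn <- centralityValues(betweennessCentrality(star, normalized = TRUE))
  expect_equal(vn[["ctr"]], 1)

  # complete graphs: every pair adjacent, all betweenness 0
  for (n in 3:6) {
    pairs <- t(combn(sprintf("k%d", 1:n), 2))
    kn <- makeProjected(pairs[, 1], pairs[, 2], rep(1L, nrow(pairs)))
    expect_true(all(centralityValues(betweennessCentrality(kn)) == 0))
  }
})

test_that("Brandes output matches exhaustive shortest-path enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    net <- randomProjected(n, p = 0.35, wmax = 5, seed = seed + 100)
    for (mode in c("unweighted", "invweight")) {
      got <- centralityValues(betweennessCentrality(net, mode = mode))
      want <- oracleBetweenness(net, mode = mode)
      expect_equal(got, want, tolerance = 1e-9)
    }
    gotn <- centralityValues(
      betweennessCentrality(net, normalized = TRUE))
    expect_equal(gotn, oracleBetweenness(net, normalized = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("unweighted mode agrees with an independent library implementation", {
  net <- randomProjected(15, p = 0.25, seed = 7)
  got <- centralityValues(betweennessCentrality(net))
  ig <- igraph::graph_from_data_frame(
    edgeTable(net)[, c("gene1", "gene2")], directed = FALSE,
    vertices = nodeIds(net))
  want <- igraph::betweenness(ig, weights = NA)
  expect_equal(got[names(want)], want, tolerance = 1e-9)
})

test_that("all-equal weights make the two modes coincide", {
  net <- randomProjected(10, p = 0.4, wmax = 1, seed = 21)
  ed <- edgeTable(net)
  same <- makeProjected(ed$gene1, ed$gene2, rep(3L, nrow(ed)),
                        nodes = nodeIds(net))
  expect_equal(centralityValues(betweennessCentrality(same, "unweighted")),
               centralityValues(betweennessCentrality(same, "invweight")),
               tolerance = 1e-9)
})

test_that("relabeling nodes permutes the centrality table identically", {
  net <- randomProjected(9, p = 0.4, seed = 13)
  ed <- edgeTable(net)
  relabel <- setNames(sprintf("x%02d", seq_along(nodeIds(net))), nodeIds(net))
  net2 <- makeProjected(relabel[ed$gene1], relabel[ed$gene2], ed$weight,
                        nodes = sort(unname(relabel), method = "radix"))
  v1 <- centralityValues(betweennessCentrality(net, "invweight"))
  v2 <- centralityValues(betweennessCentrality(net2, "invweight"))
  expect_equal(unname(v2[relabel[names(v1)]]), unname(v1), tolerance = 1e-12)
})

test_that("leaves and isolated nodes score zero, within the theoretical bound", {
  net <- randomProjected(11, p = 0.3, seed = 31)
  v <- centralityValues(betweennessCentrality(net))
  ed <- edgeTable(net)
  deg <- table(factor(c(ed$gene1, ed$gene2), levels = nodeIds(net)))
  expect_true(all(v[deg <= 1] == 0))
  n <- length(nodeIds(net))
  expect_true(all(v <= (n - 1) * (n - 2) / 2 + 1e-12))

  # degenerate networks: empty and single-node tables
  single <- makeProjected(character(0), character(0), integer(0), nodes = "A")
  expect_equal(centralityValues(betweennessCentrality(single)), c(A = 0))
})

test_that("rankByCentrality is deterministic with lexicographic tie-breaks", {
  ct <- new("CentralityTable", values = c(A = 3, B = 1, C = 3),
            mode = "unweighted", normalized = FALSE)
  top2 <- rankByCentrality(ct, 2)
  expect_identical(top2$gene_id, c("A", "C"))
  expect_identical(top2$betweenness, c(3, 3))

  star <- makeProjected(rep("ctr", 4), paste0("leaf", 1:4), rep(1L, 4))
  expect_identical(
    rankByCentrality(betweennessCentrality(star), 1)$gene_id, "ctr")

  expect_message(all5 <- rankByCentrality(ct, 10), "returning all")
  expect_equal(nrow(all5), 3L)
  expect_error(rankByCentrality(ct, 0), "positive")
})
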