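test_that("frequency histograms bin degrees from zero and conserve totals", {
  deg <- data.frame(node_id = c("a", "b", "c", "d"),
                    degree = c(1L, 1L, 2L, 5L), node_class = "gene")
  h <- frequencyHistogram(deg, 2)
  expect_identical(h$lower, c(0L, 2L, 4L))
  expect_identical(h$upper, c(2L, 4L, 6L))
  expect_identical(h$count, c(2L, 1L, 1L))
  expect_identical(attr(h, "binSize"), 2L)
  expect_identical(attr(h, "nodeClass"), "gene")

  # bin size 1 is the exact degree spectrum
  h1 <- frequencyHistogram(deg, 1)
  expect_identical(h1$count, c(0L, 2L, 1L, 0L, 0L, 1L))

  expect_error(frequencyHistogram(deg, 0), "positive")

  # tally oracle + conservation across bin sizes on a seeded fixture
  net <- buildBipartite(generateAdjacency(25, 50, p = 0.12, seed = 6))
  for (tbl in list(geneDegrees(net), mirnaDegrees(net))) {
    for (bs in c(1, 2, 5, 50)) {
      h <- frequencyHistogram(tbl, bs)
      expect_equal(sum(h$count), nrow(tbl))
      for (k in seq_len(nrow(h)))
        expect_equal(h$count[k],
                     sum(tbl$degree >= h$lower[k] & tbl$degree < h$upper[k]))
    }
  }
})

test_that("gene strength sums incident shared-miRNA weights", {
  tri <- makeProjected(c("A", "A", "B"), c("B", "C", "C"), c(2L, 3L, 4L),
                       nodes = c("A", "B", "C", "LONER"))
  s <- geneStrength(tri)
  expect_identical(s, c(A = 5L, B = 6L, C = 7L, LONER = 0L))

  syn <- generateAdjacency(20, 40, p = 0.15, seed = 9)
  proj <- projectToGenes(buildBipartite(syn))
  ed <- edgeTable(proj)
  want <- vapply(nodeIds(proj), function(g)
    as.integer(sum(ed$weight[ed$gene1 == g | ed$gene2 == g])), integer(1))
  expect_identical(geneStrength(proj), want)
})

test_that("topGenesByShared ranks by strength with nested prefixes", {
  tri <- makeProjected(c("A", "A", "B"), c("B", "C", "C"), c(2L, 3L, 4L))
  expect_identical(topGenesByShared(tri, 1), "C")

  syn <- generateAdjacency(18, 36, p = 0.2, seed = 12)
  proj <- projectToGenes(buildBipartite(syn))
  s <- geneStrength(proj)
  want <- names(s)[order(-s, names(s), method = "radix")]
  expect_identical(topGenesByShared(proj, 3), want[1:3])     # sort oracle
  for (k in 1:6)                                             # prefix nesting
    expect_true(all(topGenesByShared(proj, k) %in%
                    topGenesByShared(proj, k + 1)))
  expect_message(topGenesByShared(proj, 999), "returning all")

  # degree ranking alternative counts co-targeted partners, not weight
  ed <- edgeTable(tri)
  expect_setequal(topGenesByShared(tri, 3, rankBy = "degree"),
                  c("A", "B", "C"))
})

test_that("subsetAdjacency filters records and commutes with projection", {
  il <- InteractionList(c("A", "B"), c("m1", "m1"))
  expect_identical(interactions(subsetAdjacency(il, "A"))$gene_id, "A")
  expect_identical(interactions(subsetAdjacency(il, c("A", "B"))),
                   interactions(il))
  expect_error(subsetAdjacency(il, "ZZZ"), "empty subset")
  expect_error(subsetAdjacency(il, character(0)), "non-empty")

  # commutation: project(build(subset(list))) == induced(project(build(list)))
  for (seed in 1:8) {
    syn <- generateAdjacency(15, 30, p = 0.15, seed = seed)
    full <- projectToGenes(buildBipartite(syn))
    set.seed(seed)
    pick <- sample(nodeIds(full), 5)
    via_list <- projectToGenes(
      buildBipartite(subsetAdjacency(syn, pick)))
    via_graph <- inducedSubnetwork(full, pick)
    expect_identical(edgeTable(via_list), edgeTable(via_graph))
    expect_setequal(nodeIds(via_graph), pick)
  }
})

test_that("inducedSubnetwork keeps weights and validates gene names", {
  net <- makeProjected(c("A", "A", "B"), c("B", "C", "C"), c(2L, 3L, 4L),
                       nodes = c("A", "B", "C", "D"))
  expect_identical(edgeTable(inducedSubnetwork(net, nodeIds(net))),
                   edgeTable(net))
  two <- inducedSubnetwork(net, c("A", "D"))   # non-adjacent pair
  expect_identical(nodeIds(two), c("A", "D"))
  expect_equal(nEdges(two), 0L)
  expect_error(inducedSubnetwork(net, "nope"), "nope")
})

test_that("styleGraph maps weight to width/alpha and betweenness to size", {
  net <- makeProjected(c("A", "B"), c("B", "C"), c(100L, 50L))
  ct <- betweennessCentrality(net)
  sg <- styleGraph(net, ct, edgeScale = 0.03)
  ed <- edgeTable(sg)
  expect_equal(sg@edgeWidth[ed$weight == 100L], 3.0)
  expect_equal(max(sg@edgeAlpha), 1.0)                 # max-weight edge opaque
  expect_equal(sg@edgeAlpha[which(ed$weight == 50L)], 0.5)

  # vertex size: affine in betweenness, midpoint when degenerate
  expect_equal(unname(sg@vertexSize[c("A", "C")]), c(5, 5))
  expect_equal(unname(sg@vertexSize["B"]), 30)
  flat <- new("CentralityTable",
              values = setNames(rep(2, 3), nodeIds(net)),
              mode = "unweighted", normalized = FALSE)
  sflat <- styleGraph(net, flat, vmin = 5, vmax = 30)
  expect_true(all(sflat@vertexSize == 17.5))

  # scale equivariance
  sg2 <- styleGraph(net, ct, edgeScale = 0.06)
  expect_equal(sg2@edgeWidth, 2 * sg@edgeWidth)
  expect_error(styleGraph(net, ct, edgeScale = 0), "positive")
  expect_error(styleGraph(inducedSubnetwork(net, c("A", "B")), flat),
               NA)  # subset centrality table covering a superset is fine
})
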