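# Independent oracles and fixture builders. Everything here is deliberately
# naive (hash-set intersections, Floyd-Warshall + pruned path enumeration)
# and shares no code path with the package implementation.

# Brute-force single-mode projection: pairwise miRNA-set intersection
# counts over the unique records. Returns canonical (gene1 < gene2, sorted)
# edge data.frame.
oracleProjection <- function(gene_id, mirna_id) {
  key <- paste(gene_id, mirna_id, sep = "\r")
  keep <- !duplicated(key)
  gene_id <- gene_id[keep]; mirna_id <- mirna_id[keep]
  genes <- sort(unique(gene_id), method = "radix")
  sets <- split(mirna_id, gene_id)
  g1 <- character(0); g2 <- character(0); w <- integer(0)
  if (length(genes) >= 2) {
    for (i in seq_len(length(genes) - 1)) {
      for (j in seq(i + 1, length(genes))) {
        shared <- length(intersect(sets[[genes[i]]], sets[[genes[j]]]))
        if (shared > 0) {
          g1 <- c(g1, genes[i]); g2 <- c(g2, genes[j]); w <- c(w, shared)
        }
      }
    }
  }
  ord <- order(g1, g2, method = "radix")
  data.frame(gene1 = g1[ord], gene2 = g2[ord], weight = as.integer(w[ord]),
             stringsAsFactors = FALSE)
}

# Exhaustive betweenness: Floyd-Warshall all-pairs distances, then for each
# unordered pair enumerate every shortest path by distance-pruned DFS and
# tally pass-throughs.
oracleBetweenness <- function(net, mode = "unweighted", normalized = FALSE,
                              tol = 1e-9) {
  nodes <- nodeIds(net)
  n <- length(nodes)
  ed <- edgeTable(net)
  len <- matrix(Inf, n, n)
  diag(len) <- 0
  if (nrow(ed)) {
    i <- match(ed$gene1, nodes); j <- match(ed$gene2, nodes)
    l <- if (mode == "invweight") 1 / ed$weight else rep(1, nrow(ed))
    len[cbind(i, j)] <- l; len[cbind(j, i)] <- l
  }
  d <- len
  for (k in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n))
    if (d[a, k] + d[k, b] < d[a, b]) d[a, b] <- d[a, k] + d[k, b]
  bc <- stats::setNames(numeric(n), nodes)
  if (n < 3) return(if (normalized) bc else bc)
  enumerate <- function(s, t) {
    # all shortest s->t paths: extend only along edges staying on a
    # shortest path (d[s,v] + len[v,w] + d[w,t] == d[s,t] within tol)
    paths <- list()
    recurse <- function(v, acc) {
      if (v == t) { paths[[length(paths) + 1L]] <<- acc; return(invisible()) }
      for (w in seq_len(n)) {
        if (is.finite(len[v, w]) && w != v &&
            abs((d[s, v] + len[v, w] + d[w, t]) - d[s, t]) <=
              tol * max(1, d[s, t])) {
          recurse(w, c(acc, w))
        }
      }
    }
    recurse(s, integer(0))
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[s, t])) next
      paths <- enumerate(s, t)
      sigma <- length(paths)
      if (sigma == 0) next
      through <- table(unlist(lapply(paths, function(p) p[-length(p)])))
      for (v in names(through))
        bc[as.integer(v)] <- bc[as.integer(v)] + through[[v]] / sigma
    }
  }
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    if (denom > 0) bc <- bc / denom
  }
  bc
}

# Build a ProjectedNetwork through the public CSV reader.
makeProjected <- function(gene1, gene2, weight, nodes = NULL) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeLines(c("gene1,gene2,weight",
               if (length(gene1)) sprintf("%s,%s,%d", pmin(gene1, gene2),
                                          pmax(gene1, gene2),
                                          as.integer(weight))), f)
  readEdgeList(f, nodes = nodes)
}

# Random weighted graph on n nodes (letters), each edge present with prob p,
# integer weights in 1..wmax.
randomProjected <- function(n, p = 0.35, wmax = 5, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  g1 <- character(0); g2 <- character(0); w <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (runif(1) < p) {
        g1 <- c(g1, nodes[i]); g2 <- c(g2, nodes[j])
        w <- c(w, sample.int(wmax, 1))
      }
    }
  }
  makeProjected(g1, g2, w, nodes = nodes)
}

# Write an InteractionList to a temp CSV (with header) and return the path.
writeAdjacency <- function(il, path = tempfile(fileext = ".csv")) {
  rec <- interactions(il)
  writeLines(c("gene,mirna",
               if (nrow(rec)) sprintf("%s,%s", rec$gene_id, rec$mirna_id)),
             path)
  path
}

expect_projection_matches_oracle <- function(il) {
  rec <- interactions(il)
  net <- suppressMessages(buildBipartite(il))
  proj <- projectToGenes(net)
  oracle <- oracleProjection(rec$gene_id, rec$mirna_id)
  got <- edgeTable(proj)
  got <- got[order(got$gene1, got$gene2, method = "radix"), , drop = FALSE]
  rownames(got) <- NULL
  expect_identical(got, oracle)
  # combinatorial identity: each miRNA of degree d contributes choose(d,2)
  md <- mirnaDegrees(net)
  expect_identical(totalSharedInteractions(proj),
                   as.integer(sum(choose(md$degree, 2))))
  invisible(proj)
}
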