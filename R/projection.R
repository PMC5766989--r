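#' Single-mode projection onto the gene set
#'
#' Collapses the bipartite gene-miRNA network onto its gene class: two
#' genes are connected iff at least one miRNA targets both, and the edge
#' weight is the number of such shared targeting miRNAs. Every miRNA of
#' degree d contributes d(d-1)/2 shared-pair counts, so total edge weight
#' equals the sum of choose(deg(m), 2) over miRNAs. Computed as the sparse
#' cross-product of the biadjacency matrix with the diagonal (each gene's
#' self-intersection) discarded. Genes sharing no miRNA with any other gene
#' remain as isolated nodes unless \code{dropIsolated} is set, so the node
#' count matches the bipartite gene count.
#'
#' @param net a \linkS4class{BipartiteNetwork}.
#' @param dropIsolated drop genes with no projected edge (for plotting).
#' @return A \linkS4class{ProjectedNetwork}.
#' @examples
#' net <- buildBipartite(InteractionList(c("A", "B"), c("m1", "m1")))
#' projectToGenes(net)  # single edge A-B, weight 1
#' @export
projectToGenes <- function(net, dropIsolated = FALSE) {
  stopifnot(is(net, "BipartiteNetwork"))
  genes <- net@genes
  mirnas <- net@mirnas
  ed <- net@edges
  B <- Matrix::sparseMatrix(
    i = match(ed$gene_id, genes),
    j = match(ed$mirna_id, mirnas),
    x = 1,
    dims = c(length(genes), length(mirnas)))
  P <- Matrix::tcrossprod(B)              # genes x genes shared-miRNA counts
  P <- Matrix::triu(P, k = 1)             # discard diagonal + lower mirror
  tp <- methods::as(methods::as(P, "generalMatrix"), "TsparseMatrix")
  nz <- tp@x > 0
  g1 <- genes[tp@i[nz] + 1L]
  g2 <- genes[tp@j[nz] + 1L]
  w <- tp@x[nz]
  nodes <- genes
  if (dropIsolated) nodes <- nodes[nodes %in% c(g1, g2)]
  .newProjected(nodes, g1, g2, w)
}

#' Total shared miRNA-gene target interactions
#'
#' Sum of all projected edge weights: each unit is one (miRNA, gene pair)
#' co-targeting event.
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @return Non-negative integer.
#' @export
totalSharedInteractions <- function(net) {
  stopifnot(is(net, "ProjectedNetwork"))
  as.integer(sum(net@edges$weight))
}

#' Shared-miRNA count for one gene pair
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @param g1,g2 distinct gene ids present in the network.
#' @return The edge weight, or 0 when the pair shares no miRNA.
#' @export
edgeWeight <- function(net, g1, g2) {
  stopifnot(is(net, "ProjectedNetwork"))
  for (g in c(g1, g2))
    if (!g %in% net@nodes) stop("unknown gene: '", g, "'")
  if (g1 == g2) stop("edgeWeight requires two distinct genes, got '", g1, "' twice")
  hit <- match(.pairKey(g1, g2), .pairKey(net@edges$gene1, net@edges$gene2))
  if (is.na(hit)) 0L else as.integer(net@edges$weight[hit])
}

#' Induced gene subnetwork
#'
#' Restricts a projected network to a gene subset: nodes become exactly
#' \code{genes}, and the surviving edges (both endpoints selected) keep
#' their weights. Equivalent to subsetting the adjacency list to those
#' genes and re-running build + project, since pairwise shared-miRNA counts
#' do not depend on which other genes are present.
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @param genes character vector, subset of the node set.
#' @return A \linkS4class{ProjectedNetwork} over \code{genes}.
#' @export
inducedSubnetwork <- function(net, genes) {
  stopifnot(is(net, "ProjectedNetwork"))
  genes <- unique(genes)
  missing <- setdiff(genes, net@nodes)
  if (length(missing)) stop("unknown gene: '", missing[1], "'")
  ed <- net@edges
  keep <- ed$gene1 %in% genes & ed$gene2 %in% genes
  nodes <- net@nodes[net@nodes %in% genes]
  .newProjected(nodes, ed$gene1[keep], ed$gene2[keep], ed$weight[keep])
}
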