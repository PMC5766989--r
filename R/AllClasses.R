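#' @import methods
#' @importFrom stats setNames
NULL

## C-locale (byte-order) sorting so ranked and written output is
## locale-independent.
.csort <- function(x) x[order(x, method = "radix")]
.corder <- function(...) order(..., method = "radix")

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' InteractionList: an ordered gene-miRNA adjacency list
#'
#' Holds one row per gene-miRNA targeting link, in input order, possibly
#' with duplicate pairs (deduplication is an explicit, logged step; see
#' \code{\link{deduplicate}}).
#'
#' @slot records data.frame with character columns \code{gene_id} and
#'   \code{mirna_id}; identifiers are whitespace-trimmed and non-empty, and
#'   no single row may use the same token for both columns.
#' @slot provenance free-text source label (e.g. the input file path).
#'
#' @seealso \code{\link{readAdjacencyList}}, \code{\link{buildBipartite}}
#' @export
setClass("InteractionList",
  representation(records = "data.frame", provenance = "character"),
  prototype(records = data.frame(gene_id = character(), mirna_id = character(),
                                 stringsAsFactors = FALSE),
            provenance = ""))

setValidity("InteractionList", function(object) {
  rec <- object@records
  if (!all(c("gene_id", "mirna_id") %in% names(rec)))
    return("records must have columns 'gene_id' and 'mirna_id'")
  if (!is.character(rec$gene_id) || !is.character(rec$mirna_id))
    return("gene_id and mirna_id must be character")
  if (any(rec$gene_id != trimws(rec$gene_id)) ||
      any(rec$mirna_id != trimws(rec$mirna_id)))
    return("identifiers must be whitespace-trimmed")
  if (any(!nzchar(rec$gene_id)) || any(!nzchar(rec$mirna_id)))
    return("identifiers must be non-empty")
  bad <- which(rec$gene_id == rec$mirna_id)
  if (length(bad))
    return(sprintf("record %d: gene_id and mirna_id are identical ('%s')",
                   bad[1], rec$gene_id[bad[1]]))
  if (length(object@provenance) != 1L)
    return("provenance must be a single string")
  TRUE
})

#' Construct an InteractionList
#'
#' @param gene_id,mirna_id character vectors of equal length; surrounding
#'   whitespace is trimmed.
#' @param provenance free-text source label.
#' @return An \linkS4class{InteractionList}.
#' @examples
#' InteractionList(c("CCND1", "MYC"), c("hsa-miR-16-5p", "hsa-miR-16-5p"))
#' @export
InteractionList <- function(gene_id = character(), mirna_id = character(),
                            provenance = "") {
  stopifnot(length(gene_id) == length(mirna_id))
  new("InteractionList",
      records = data.frame(gene_id = trimws(as.character(gene_id)),
                           mirna_id = trimws(as.character(mirna_id)),
                           stringsAsFactors = FALSE),
      provenance = as.character(provenance))
}

#' BipartiteNetwork: a validated two-class gene-miRNA graph
#'
#' Node classes are disjoint, every edge joins a gene to a miRNA, edges are
#' unique, and every node has degree >= 1 (genes without any validated
#' targeting interaction never enter the graph). Node sets keep
#' first-appearance order so downstream output is deterministic for a fixed
#' input.
#'
#' @slot genes character vector of gene symbols, first-appearance order.
#' @slot mirnas character vector of miRNA identifiers, first-appearance order.
#' @slot edges data.frame with columns \code{gene_id}, \code{mirna_id}; one
#'   row per unique targeting link.
#' @seealso \code{\link{buildBipartite}}, \code{\link{projectToGenes}}
#' @export
setClass("BipartiteNetwork",
  representation(genes = "character", mirnas = "character",
                 edges = "data.frame"))

setValidity("BipartiteNetwork", function(object) {
  ed <- object@edges
  if (!all(c("gene_id", "mirna_id") %in% names(ed)))
    return("edges must have columns 'gene_id' and 'mirna_id'")
  if (anyDuplicated(object@genes)) return("duplicate gene ids")
  if (anyDuplicated(object@mirnas)) return("duplicate miRNA ids")
  clash <- intersect(object@genes, object@mirnas)
  if (length(clash))
    return(sprintf("identifier '%s' appears in both node classes", clash[1]))
  if (!all(ed$gene_id %in% object@genes))
    return("edge with gene endpoint outside the gene set")
  if (!all(ed$mirna_id %in% object@mirnas))
    return("edge with miRNA endpoint outside the miRNA set")
  if (anyDuplicated(paste(ed$gene_id, ed$mirna_id, sep = "\r")))
    return("duplicate edges")
  if (!all(object@genes %in% ed$gene_id) || !all(object@mirnas %in% ed$mirna_id))
    return("isolated node (degree 0) present")
  TRUE
})

#' ProjectedNetwork: gene-only co-targeting graph
#'
#' Single-mode projection of a \linkS4class{BipartiteNetwork} onto its gene
#' set. Each undirected edge carries a positive integer weight: the number
#' of distinct miRNAs targeting both endpoint genes. Genes sharing no miRNA
#' with any other gene stay in the node set as isolated nodes, so the node
#' count matches the bipartite gene count.
#'
#' @slot nodes character vector of gene symbols, first-appearance order of
#'   the source bipartite network.
#' @slot edges data.frame with columns \code{gene1}, \code{gene2},
#'   \code{weight}; within a row \code{gene1 < gene2} (byte order) and rows
#'   are sorted by (\code{gene1}, \code{gene2}).
#' @seealso \code{\link{projectToGenes}}, \code{\link{betweennessCentrality}}
#' @export
setClass("ProjectedNetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("ProjectedNetwork", function(object) {
  ed <- object@edges
  if (!all(c("gene1", "gene2", "weight") %in% names(ed)))
    return("edges must have columns 'gene1', 'gene2', 'weight'")
  if (anyDuplicated(object@nodes)) return("duplicate node ids")
  if (nrow(ed)) {
    if (!all(ed$gene1 %in% object@nodes) || !all(ed$gene2 %in% object@nodes))
      return("edge endpoint outside the node set")
    if (any(ed$gene1 == ed$gene2)) return("self-loop present")
    # canonical within-row order keeps each unordered pair representable once
    swapped <- .corder(ed$gene1, ed$gene2)
    if (any(ed$gene2 < ed$gene1)) return("gene1 must precede gene2 (byte order)")
    if (anyDuplicated(.pairKey(ed$gene1, ed$gene2)))
      return("duplicate edge for an unordered gene pair")
    if (any(ed$weight < 1) || any(ed$weight != round(ed$weight)))
      return("weights must be positive integers")
  }
  TRUE
})

#' CentralityTable: per-gene betweenness values
#'
#' @slot values named numeric vector, one betweenness value per node of the
#'   projected network it was computed from.
#' @slot mode \code{"unweighted"} (all edges length 1) or \code{"invweight"}
#'   (edge length 1/weight, so heavily co-targeted pairs are close).
#' @slot normalized logical; if TRUE values were divided by (n-1)(n-2)/2.
#' @seealso \code{\link{betweennessCentrality}}, \code{\link{rankByCentrality}}
#' @export
setClass("CentralityTable",
  representation(values = "numeric", mode = "character",
                 normalized = "logical"))

setValidity("CentralityTable", function(object) {
  if (length(object@values) && is.null(names(object@values)))
    return("values must be named by gene id")
  if (any(object@values < 0)) return("betweenness values must be >= 0")
  if (!object@mode %in% c("unweighted", "invweight"))
    return("mode must be 'unweighted' or 'invweight'")
  TRUE
})

#' StyledGraph: a projected network plus plot attributes
#'
#' Carries the vertex and edge aesthetics used for graph plots and GraphML
#' export: vertex size is an affine rescale of betweenness centrality, edge
#' width is weight times a scale factor (default 0.03), and edge alpha is
#' weight normalized by the maximum weight, capped at 1.
#'
#' @slot base the underlying \linkS4class{ProjectedNetwork}.
#' @slot vertexSize named numeric, one positive size per node.
#' @slot edgeWidth numeric, one positive width per edge row of \code{base}.
#' @slot edgeAlpha numeric in (0, 1], one per edge row of \code{base}.
#' @slot edgeScale the width scale factor applied.
#' @slot betweenness named numeric, the centrality values the sizes encode.
#' @seealso \code{\link{styleGraph}}, \code{\link{writeGraphML}}
#' @export
setClass("StyledGraph",
  representation(base = "ProjectedNetwork", vertexSize = "numeric",
                 edgeWidth = "numeric", edgeAlpha = "numeric",
                 edgeScale = "numeric", betweenness = "numeric"))

setValidity("StyledGraph", function(object) {
  n <- length(object@base@nodes)
  m <- nrow(object@base@edges)
  if (length(object@vertexSize) != n ||
      !setequal(names(object@vertexSize), object@base@nodes))
    return("vertexSize must cover exactly the node set")
  if (any(object@vertexSize <= 0)) return("vertex sizes must be positive")
  if (length(object@edgeWidth) != m) return("one edgeWidth per edge required")
  if (length(object@edgeAlpha) != m) return("one edgeAlpha per edge required")
  if (m && (any(object@edgeWidth <= 0))) return("edge widths must be positive")
  if (m && (any(object@edgeAlpha <= 0) || any(object@edgeAlpha > 1)))
    return("edge alpha must lie in (0, 1]")
  if (length(object@edgeScale) != 1L || object@edgeScale <= 0)
    return("edgeScale must be a single positive number")
  TRUE
})
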