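#' Remove duplicate gene-miRNA pairs
#'
#' Keeps the first occurrence of each (gene, miRNA) pair, preserving the
#' original relative order, and reports how many redundant rows (multiple
#' experimental validations of a single pair) were dropped.
#'
#' @param x an \linkS4class{InteractionList}.
#' @return A deduplicated \linkS4class{InteractionList}. Idempotent.
#' @examples
#' il <- InteractionList(c("A", "A", "B"), c("m1", "m1", "m1"))
#' nInteractions(deduplicate(il))  # 2
#' @export
setGeneric("deduplicate", function(x) standardGeneric("deduplicate"))

#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname accessors
#' @export
setGeneric("nInteractions", function(x) standardGeneric("nInteractions"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("centralityValues", function(x) standardGeneric("centralityValues"))

#' @rdname accessors
#' @export
setGeneric("centralityMode", function(x) standardGeneric("centralityMode"))

#' Export a network as GraphML
#'
#' Writes a GraphML 1.0 document readable by standard GraphML parsers. Nodes
#' carry \code{id} (and, for styled graphs, \code{betweenness} and
#' \code{vertex_size}); edges carry \code{weight} (and, for styled graphs,
#' \code{width} and \code{alpha}).
#'
#' @param g a \linkS4class{ProjectedNetwork} or \linkS4class{StyledGraph}.
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
setGeneric("writeGraphML", function(g, path) standardGeneric("writeGraphML"))
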