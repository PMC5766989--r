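#' Accessors for cernaNet classes
#'
#' Small read-only accessors; user code should never reach into slots.
#'
#' \describe{
#'   \item{\code{interactions(x)}}{data.frame of (gene_id, mirna_id) records.}
#'   \item{\code{nInteractions(x)}}{number of records.}
#'   \item{\code{provenance(x)}}{source label of an interaction list.}
#'   \item{\code{geneIds(x)}, \code{mirnaIds(x)}}{node identifiers of a
#'     bipartite network (first-appearance order).}
#'   \item{\code{nodeIds(x)}}{gene identifiers of a projected network.}
#'   \item{\code{edgeTable(x)}}{edge data.frame of a bipartite or projected
#'     network.}
#'   \item{\code{nEdges(x)}}{edge count.}
#'   \item{\code{centralityValues(x)}, \code{centralityMode(x)}}{named
#'     betweenness vector and the distance mode it was computed under.}
#' }
#'
#' @param x a cernaNet object.
#' @name accessors
#' @aliases interactions nInteractions provenance geneIds mirnaIds edgeTable
#'   nodeIds nEdges centralityValues centralityMode
NULL

#' @rdname accessors
setMethod("interactions", "InteractionList", function(x) x@records)

#' @rdname accessors
setMethod("nInteractions", "InteractionList", function(x) nrow(x@records))

#' @rdname accessors
setMethod("provenance", "InteractionList", function(x) x@provenance)

#' @rdname accessors
setMethod("geneIds", "BipartiteNetwork", function(x) x@genes)

#' @rdname accessors
setMethod("mirnaIds", "BipartiteNetwork", function(x) x@mirnas)

#' @rdname accessors
setMethod("edgeTable", "BipartiteNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("nEdges", "BipartiteNetwork", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("nodeIds", "ProjectedNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("edgeTable", "ProjectedNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("nEdges", "ProjectedNetwork", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("centralityValues", "CentralityTable", function(x) x@values)

#' @rdname accessors
setMethod("centralityMode", "CentralityTable", function(x) x@mode)

#' @rdname accessors
setMethod("nodeIds", "StyledGraph", function(x) x@base@nodes)

#' @rdname accessors
setMethod("edgeTable", "StyledGraph", function(x) x@base@edges)

#' Coerce a CentralityTable to a data.frame
#'
#' @param x a \linkS4class{CentralityTable}.
#' @param ... ignored.
#' @return data.frame with columns \code{gene_id}, \code{betweenness}.
#' @export
as.data.frame.CentralityTable <- function(x, ...) {
  data.frame(gene_id = names(x@values), betweenness = unname(x@values),
             stringsAsFactors = FALSE)
}

setMethod("show", "InteractionList", function(object) {
  cat(sprintf("InteractionList: %d records, %d genes, %d miRNAs\n",
              nrow(object@records), length(unique(object@records$gene_id)),
              length(unique(object@records$mirna_id))))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat(sprintf("BipartiteNetwork: %d genes, %d miRNAs, %d edges\n",
              length(object@genes), length(object@mirnas),
              nrow(object@edges)))
})

setMethod("show", "ProjectedNetwork", function(object) {
  w <- object@edges$weight
  cat(sprintf(
    "ProjectedNetwork: %d genes, %d edges, %d total shared interactions\n",
    length(object@nodes), nrow(object@edges), sum(w)))
})

setMethod("show", "CentralityTable", function(object) {
  cat(sprintf("CentralityTable: %d genes, mode=%s, normalized=%s\n",
              length(object@values), object@mode, object@normalized))
  if (length(object@values)) {
    top <- utils::head(sort(object@values, decreasing = TRUE), 3L)
    cat("  top:", paste(sprintf("%s=%.4g", names(top), top),
                        collapse = ", "), "\n")
  }
})

setMethod("show", "StyledGraph", function(object) {
  cat(sprintf("StyledGraph: %d nodes, %d edges, edgeScale=%g\n",
              length(object@base@nodes), nrow(object@base@edges),
              object@edgeScale))
})
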