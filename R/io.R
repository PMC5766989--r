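#' Read a gene-miRNA adjacency list
#'
#' Parses a two-column, comma-delimited adjacency list of experimentally
#' validated gene-miRNA targeting interactions (column 1 = gene symbol,
#' column 2 = miRNA identifier, e.g. the miRWalk-derived lists this tool was
#' designed around). Reading is lossless: duplicate pairs are kept and
#' removed only by the explicit \code{\link{deduplicate}} step. Identifiers
#' are trimmed of surrounding whitespace but never case-folded (miRNA names
#' are case-sensitive by convention).
#'
#' Header presence is never auto-detected; state it explicitly via
#' \code{hasHeader}.
#'
#' @param path path to the CSV file.
#' @param hasHeader logical; does the first line hold column names?
#'   Default TRUE.
#' @param swapColumns logical; set TRUE for files in (miRNA, gene) order.
#' @return An \linkS4class{InteractionList} with records in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("gene,mirna", "CCND1,hsa-miR-16-5p", "MYC,hsa-miR-16-5p"), f)
#' readAdjacencyList(f)
#' @export
readAdjacencyList <- function(path, hasHeader = TRUE, swapColumns = FALSE) {
  if (!file.exists(path))
    stop("cannot read adjacency list: no such file: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"",
                            blank.lines.skip = FALSE)
  first <- if (hasHeader) 2L else 1L
  data_lines <- seq_along(nf)[seq_along(nf) >= first]
  data_lines <- data_lines[!is.na(nf[data_lines])]  # NA: quoted continuation
  bad <- data_lines[nf[data_lines] != 2L]
  if (length(bad))
    stop(sprintf("malformed adjacency list '%s': line %d has %d field(s), expected 2",
                 path, bad[1], nf[bad[1]]))
  df <- tryCatch(
    utils::read.csv(path, header = hasHeader, colClasses = "character",
                    blank.lines.skip = TRUE, strip.white = TRUE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0L)
    stop("no interaction records in '", path, "'")
  if (swapColumns) df <- df[, 2:1]
  il <- InteractionList(df[[1]], df[[2]], provenance = path)
  message(sprintf("read %d interaction records from '%s'", nrow(df), path))
  il
}

#' @rdname deduplicate
setMethod("deduplicate", "InteractionList", function(x) {
  rec <- x@records
  keep <- !duplicated(paste(rec$gene_id, rec$mirna_id, sep = "\r"))
  removed <- sum(!keep)
  if (removed)
    message(sprintf("deduplicate: removed %d redundant record(s), %d kept",
                    removed, sum(keep)))
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("InteractionList", records = out, provenance = x@provenance)
})

#' Write a projected network as a CSV edge list
#'
#' One line per edge, \code{gene1,gene2,weight}, with \code{gene1 < gene2}
#' byte-lexicographically within each line and lines sorted the same way.
#' An empty network yields a header-only file. Round-trips losslessly
#' through \code{\link{readEdgeList}}.
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "ProjectedNetwork"))
  ed <- net@edges
  lines <- "gene1,gene2,weight"
  if (nrow(ed)) {
    ord <- .corder(ed$gene1, ed$gene2)
    lines <- c(lines, sprintf("%s,%s,%d", ed$gene1[ord], ed$gene2[ord],
                              as.integer(ed$weight[ord])))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write edge list to: ", path)
  invisible(path)
}

#' Read a CSV edge list written by writeEdgeList
#'
#' @param path path to a \code{gene1,gene2,weight} CSV.
#' @param nodes optional character vector of node ids; defaults to the
#'   genes present in the edges (isolated nodes are not representable in an
#'   edge list, so pass \code{nodes} to restore them).
#' @return A \linkS4class{ProjectedNetwork}.
#' @export
readEdgeList <- function(path, nodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses =
                          c("character", "character", "integer"))
  if (is.null(nodes))
    nodes <- .csort(unique(c(df$gene1, df$gene2)))
  .newProjected(nodes, df$gene1, df$gene2, df$weight)
}

## canonicalize edges (alpha order within pair, sorted rows) and validate
.newProjected <- function(nodes, g1, g2, w) {
  a <- pmin(g1, g2); b <- pmax(g1, g2)
  ord <- .corder(a, b)
  new("ProjectedNetwork", nodes = nodes,
      edges = data.frame(gene1 = a[ord], gene2 = b[ord],
                         weight = as.integer(w[ord]),
                         stringsAsFactors = FALSE))
}

.asIgraph <- function(g) {
  if (is(g, "StyledGraph")) {
    base <- g@base
    ig <- .asIgraph(base)
    igraph::V(ig)$betweenness <- unname(g@betweenness[base@nodes])
    igraph::V(ig)$vertex_size <- unname(g@vertexSize[base@nodes])
    if (nrow(base@edges)) {
      igraph::E(ig)$width <- g@edgeWidth
      igraph::E(ig)$alpha <- g@edgeAlpha
    }
    return(ig)
  }
  stopifnot(is(g, "ProjectedNetwork"))
  ed <- g@edges
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = ed$gene1, to = ed$gene2, weight = ed$weight),
    directed = FALSE,
    vertices = data.frame(name = g@nodes, stringsAsFactors = FALSE))
  igraph::V(ig)$id <- g@nodes
  ig
}

#' @rdname writeGraphML
setMethod("writeGraphML", "ProjectedNetwork", function(g, path) {
  .writeGraphMLImpl(g, path)
})

#' @rdname writeGraphML
setMethod("writeGraphML", "StyledGraph", function(g, path) {
  .writeGraphMLImpl(g, path)
})

.writeGraphMLImpl <- function(g, path) {
  ig <- .asIgraph(g)
  ok <- tryCatch({
    igraph::write_graph(ig, file = path, format = "graphml")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write GraphML to: ", path)
  invisible(path)
}

#' Path to a locally supplied reference adjacency list, if any
#'
#' The published miRWalk-derived adjacency list (3414 interactions over 196
#' genes and 657 miRNAs) is not redistributed with this package. If a copy
#' is available, point option \code{cernaNet.reference} at it, or drop it at
#' \code{inst/extdata/reference_adjacency.csv} before installing; the
#' full-pipeline reproduction checks then run against it.
#'
#' @return The file path, or \code{NA_character_} when no copy is available.
#' @export
referenceAdjacencyPath <- function() {
  opt <- getOption("cernaNet.reference", NULL)
  if (!is.null(opt) && file.exists(opt)) return(opt)
  p <- system.file("extdata", "reference_adjacency.csv", package = "cernaNet")
  if (nzchar(p) && file.exists(p)) p else NA_character_
}
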