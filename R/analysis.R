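#' Degree frequency histogram
#'
#' Bins a degree table into contiguous left-closed, right-open intervals
#' [i*binSize, (i+1)*binSize) starting at 0, trimming trailing empty bins.
#' Counts always sum to the number of nodes of that class. Bin size 2 for
#' targets-per-miRNA and 5 for targeting-miRNAs-per-gene reproduce the
#' standard summary views of these networks.
#'
#' @param degrees a degree table from \code{\link{geneDegrees}} or
#'   \code{\link{mirnaDegrees}} (columns \code{node_id}, \code{degree},
#'   \code{node_class}).
#' @param binSize positive integer bin width.
#' @return data.frame with columns \code{lower} (inclusive), \code{upper}
#'   (exclusive), \code{count}; attributes \code{binSize} and
#'   \code{nodeClass}.
#' @examples
#' deg <- data.frame(node_id = letters[1:4], degree = c(1, 1, 2, 5),
#'                   node_class = "gene")
#' frequencyHistogram(deg, 2)  # counts 2, 1, 1
#' @export
frequencyHistogram <- function(degrees, binSize) {
  if (!is.numeric(binSize) || length(binSize) != 1L || binSize < 1 ||
      binSize != round(binSize))
    stop("binSize must be a positive integer")
  d <- degrees$degree
  stopifnot(is.numeric(d), all(d >= 0))
  nbin <- max(1L, max(c(0L, d)) %/% as.integer(binSize) + 1L)
  idx <- d %/% as.integer(binSize) + 1L
  counts <- tabulate(idx, nbins = nbin)
  while (length(counts) > 1L && counts[length(counts)] == 0L)
    counts <- counts[-length(counts)]
  out <- data.frame(lower = (seq_along(counts) - 1L) * as.integer(binSize),
                    upper = seq_along(counts) * as.integer(binSize),
                    count = counts)
  attr(out, "binSize") <- as.integer(binSize)
  attr(out, "nodeClass") <- if (length(unique(degrees$node_class)) == 1L)
    degrees$node_class[1] else NA_character_
  out
}

#' Gene strength: total shared targeting interactions per gene
#'
#' Strength of a gene is the sum of the weights of its incident projected
#' edges, i.e. its total count of shared targeting-miRNA interactions with
#' all other genes. Isolated genes have strength 0.
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @return Named integer vector over all nodes, in node order.
#' @export
geneStrength <- function(net) {
  stopifnot(is(net, "ProjectedNetwork"))
  s <- setNames(integer(length(net@nodes)), net@nodes)
  ed <- net@edges
  if (nrow(ed)) {
    t1 <- tapply(ed$weight, factor(ed$gene1, levels = net@nodes), sum)
    t2 <- tapply(ed$weight, factor(ed$gene2, levels = net@nodes), sum)
    t1[is.na(t1)] <- 0; t2[is.na(t2)] <- 0
    s[] <- as.integer(t1 + t2)
  }
  s
}

#' Top-k genes by shared targeting miRNAs
#'
#' Ranks genes by strength (total shared targeting-miRNA interactions) or,
#' alternatively, by bipartite-style degree in the projection (number of
#' co-targeted partner genes). Ties break by byte-order gene id, so output
#' is reproducible. In real targeting networks the strength ranking tends
#' to coincide with the most-targeted genes — the co-targeting hubs this
#' extraction is designed to surface as candidate ceRNA modules.
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @param k positive integer.
#' @param rankBy \code{"strength"} (default) or \code{"degree"}.
#' @return Character vector of gene ids, highest-ranked first.
#' @export
topGenesByShared <- function(net, k, rankBy = c("strength", "degree")) {
  stopifnot(is(net, "ProjectedNetwork"))
  rankBy <- match.arg(rankBy)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer")
  score <- if (rankBy == "strength") geneStrength(net) else {
    deg <- setNames(integer(length(net@nodes)), net@nodes)
    tab <- table(factor(c(net@edges$gene1, net@edges$gene2),
                        levels = net@nodes))
    deg[] <- as.integer(tab)
    deg
  }
  if (k > length(score)) {
    message(sprintf("topGenesByShared: k=%d exceeds %d genes; returning all",
                    as.integer(k), length(score)))
    k <- length(score)
  }
  ord <- order(-score, names(score), method = "radix")
  names(score)[ord][seq_len(k)]
}

#' Subset an adjacency list to selected genes
#'
#' Keeps the records whose gene belongs to \code{genes}, preserving order.
#' Re-running build + project on the result yields the subnetwork whose
#' edge weights are the shared-miRNA counts among the selected genes —
#' identical to \code{\link{inducedSubnetwork}} on the full projection.
#'
#' @param x an \linkS4class{InteractionList}.
#' @param genes non-empty character vector of gene ids to keep.
#' @return An \linkS4class{InteractionList}.
#' @export
subsetAdjacency <- function(x, genes) {
  stopifnot(is(x, "InteractionList"))
  if (!length(genes)) stop("genes must be non-empty")
  keep <- x@records$gene_id %in% genes
  if (!any(keep)) stop("empty subset: no record matches the selected genes")
  out <- x@records[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("InteractionList", records = out, provenance = x@provenance)
}

#' Attach plot styling to a projected network
#'
#' Edge width is weight times \code{edgeScale} (default 0.03, a factor that
#' tames the 'hairball' at typical shared-miRNA counts; tune it per
#' network). Edge alpha is weight over the maximum weight, capped at 1, so
#' the strongest co-targeting tie is fully opaque. Vertex size is an affine
#' rescale of betweenness centrality into [\code{vmin}, \code{vmax}]; when
#' every gene has equal betweenness all vertices get the midpoint size.
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @param cent a \linkS4class{CentralityTable} covering all nodes of
#'   \code{net}.
#' @param edgeScale positive width factor.
#' @param vmin,vmax vertex size bounds (plot units).
#' @return A \linkS4class{StyledGraph}.
#' @export
styleGraph <- function(net, cent, edgeScale = 0.03, vmin = 5, vmax = 30) {
  stopifnot(is(net, "ProjectedNetwork"), is(cent, "CentralityTable"))
  if (!is.numeric(edgeScale) || length(edgeScale) != 1L || edgeScale <= 0)
    stop("edgeScale must be a single positive number")
  stopifnot(vmin > 0, vmax >= vmin)
  v <- cent@values
  missing <- setdiff(net@nodes, names(v))
  if (length(missing))
    stop("centrality table does not cover gene '", missing[1], "'")
  b <- v[net@nodes]
  rng <- range(b)
  size <- if (diff(rng) == 0) rep((vmin + vmax) / 2, length(b))
          else vmin + (b - rng[1]) / diff(rng) * (vmax - vmin)
  ed <- net@edges
  width <- ed$weight * edgeScale
  alpha <- if (nrow(ed)) pmin(1, ed$weight / max(ed$weight)) else numeric(0)
  new("StyledGraph", base = net,
      vertexSize = setNames(as.numeric(size), net@nodes),
      edgeWidth = as.numeric(width), edgeAlpha = as.numeric(alpha),
      edgeScale = edgeScale, betweenness = setNames(unname(b), net@nodes))
}
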