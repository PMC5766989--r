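#' Build a validated bipartite gene-miRNA network
#'
#' Turns a (deduplicated) adjacency list into a two-class affiliation
#' network: genes interact only with miRNAs. Node sets are exactly the
#' identifiers appearing in the records, in first-appearance order. The
#' operation deduplicates defensively and notes when it had to. An
#' identifier appearing in both columns (across any rows) is a hard error,
#' since it usually indicates a swapped-column file.
#'
#' @param x an \linkS4class{InteractionList}.
#' @return A \linkS4class{BipartiteNetwork}.
#' @examples
#' il <- InteractionList(c("A", "B", "A"), c("m1", "m1", "m2"))
#' buildBipartite(il)  # 2 genes, 2 miRNAs, 3 edges
#' @export
buildBipartite <- function(x) {
  stopifnot(is(x, "InteractionList"))
  rec <- x@records
  keep <- !duplicated(paste(rec$gene_id, rec$mirna_id, sep = "\r"))
  if (any(!keep)) {
    message(sprintf("buildBipartite: input not deduplicated; dropped %d duplicate record(s)",
                    sum(!keep)))
    rec <- rec[keep, , drop = FALSE]
  }
  genes <- unique(rec$gene_id)
  mirnas <- unique(rec$mirna_id)
  clash <- intersect(genes, mirnas)
  if (length(clash))
    stop("identifier '", clash[1],
         "' appears both as a gene and as a miRNA (class collision; ",
         "check column order)")
  rownames(rec) <- NULL
  new("BipartiteNetwork", genes = genes, mirnas = mirnas, edges = rec)
}

.degreeTable <- function(ids, counts, class) {
  data.frame(node_id = ids,
             degree = as.integer(counts),
             node_class = class,
             stringsAsFactors = FALSE)
}

#' Node degrees of a bipartite network
#'
#' \code{geneDegrees} counts, per gene, the distinct miRNAs targeting it;
#' \code{mirnaDegrees} counts, per miRNA, its distinct mRNA target genes.
#' Both satisfy the handshake identity: each class's degrees sum to the
#' edge count.
#'
#' @param net a \linkS4class{BipartiteNetwork}.
#' @return data.frame with columns \code{node_id}, \code{degree},
#'   \code{node_class}, in the network's node order.
#' @examples
#' net <- buildBipartite(InteractionList(c("A", "A", "B"), c("m1", "m2", "m1")))
#' geneDegrees(net)   # A: 2, B: 1
#' mirnaDegrees(net)  # m1: 2, m2: 1
#' @export
geneDegrees <- function(net) {
  stopifnot(is(net, "BipartiteNetwork"))
  tab <- table(factor(net@edges$gene_id, levels = net@genes))
  .degreeTable(net@genes, as.vector(tab), "gene")
}

#' @rdname geneDegrees
#' @export
mirnaDegrees <- function(net) {
  stopifnot(is(net, "BipartiteNetwork"))
  tab <- table(factor(net@edges$mirna_id, levels = net@mirnas))
  .degreeTable(net@mirnas, as.vector(tab), "mirna")
}
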