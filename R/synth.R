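#' Generate a synthetic gene-miRNA adjacency list
#'
#' Seeded generator of many-to-many targeting interactions for testing
#' every stage of the pipeline without external data. Two models:
#' \describe{
#'   \item{\code{"uniform"}}{each of the nGenes x nMirnas possible links is
#'     included independently with probability \code{p}.}
#'   \item{\code{"planted-motif"}}{the uniform background plus a complete
#'     block in which the first \code{motifMirnas} miRNAs each target all
#'     of the first \code{motifGenes} genes. Every motif gene pair then
#'     shares at least \code{motifMirnas} miRNAs, so with a block well
#'     above the background co-targeting level the motif genes dominate
#'     the shared-miRNA ranking — a synthetic co-regulation module for
#'     end-to-end recovery tests.}
#' }
#' Records are emitted in gene-major grid order, contain no duplicates, and
#' are byte-identical for a fixed seed. Gene ids are \code{G0001...};
#' miRNA ids are \code{hsa-miR-synth-1...}. The global RNG state is left
#' untouched.
#'
#' @param nGenes,nMirnas positive integers.
#' @param model \code{"uniform"} or \code{"planted-motif"}.
#' @param p background edge probability in (0, 1].
#' @param motifGenes,motifMirnas planted block dimensions
#'   (motif model only; must not exceed nGenes / nMirnas).
#' @param seed integer seed.
#' @return An \linkS4class{InteractionList}.
#' @examples
#' il <- generateAdjacency(10, 20, p = 0.2, seed = 1)
#' buildBipartite(il)
#' @export
generateAdjacency <- function(nGenes, nMirnas,
                              model = c("uniform", "planted-motif"),
                              p = 0.1, motifGenes = 5, motifMirnas = 40,
                              seed = 1) {
  model <- match.arg(model)
  stopifnot(nGenes >= 1, nMirnas >= 1, p > 0 || model == "planted-motif",
            p <= 1, p >= 0)
  if (model == "planted-motif")
    stopifnot(motifGenes >= 1, motifMirnas >= 1,
              motifGenes <= nGenes, motifMirnas <= nMirnas)
  genes <- sprintf("G%04d", seq_len(nGenes))
  mirnas <- sprintf("hsa-miR-synth-%d", seq_len(nMirnas))
  gi <- rep(seq_len(nGenes), each = nMirnas)
  mi <- rep(seq_len(nMirnas), times = nGenes)
  include <- .withSeed(seed, stats::runif(length(gi)) < p)
  if (model == "planted-motif")
    include <- include | (gi <= motifGenes & mi <= motifMirnas)
  InteractionList(genes[gi][include], mirnas[mi][include],
                  provenance = sprintf("synthetic:%s:seed=%d", model, seed))
}

## run expr under a temporary RNG state; restores (or removes) .Random.seed
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
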