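#' Betweenness centrality of a projected co-targeting network
#'
#' For every gene v, sums over unordered source-target pairs s != t (both
#' different from v) the fraction of shortest s-t paths passing through v.
#' Pairs in different components contribute 0. Implemented with Brandes'
#' single-source accumulation: breadth-first search per source in
#' \code{"unweighted"} mode, Dijkstra in \code{"invweight"} mode, where each
#' edge has length 1/weight so that heavily co-targeted gene pairs are
#' topologically close. Normalization divides by (n-1)(n-2)/2 with n the
#' node count of the whole network.
#'
#' The default is unweighted shortest paths; the inverse-weight mode is the
#' semantically coherent weighted alternative (a raw weight used as a
#' distance would make strong co-targeting ties long, which is backwards).
#'
#' @param net a \linkS4class{ProjectedNetwork}.
#' @param mode \code{"unweighted"} or \code{"invweight"}.
#' @param normalized divide by the number of possible mediated pairs.
#' @return A \linkS4class{CentralityTable} covering every node.
#' @examples
#' net <- projectToGenes(buildBipartite(
#'   InteractionList(c("a", "b", "b", "c"), c("m1", "m1", "m2", "m2"))))
#' centralityValues(betweennessCentrality(net))  # b mediates the a-c pair
#' @export
betweennessCentrality <- function(net, mode = c("unweighted", "invweight"),
                                  normalized = FALSE) {
  stopifnot(is(net, "ProjectedNetwork"))
  mode <- match.arg(mode)
  nodes <- net@nodes
  n <- length(nodes)
  bc <- setNames(numeric(n), nodes)
  if (n >= 3L && nrow(net@edges) > 0L) {
    i1 <- match(net@edges$gene1, nodes)
    i2 <- match(net@edges$gene2, nodes)
    len <- if (mode == "invweight") 1 / net@edges$weight else rep(1, length(i1))
    adj <- vector("list", n)       # adjacency: neighbor index + edge length
    for (k in seq_along(i1)) {
      adj[[i1[k]]] <- rbind(adj[[i1[k]]], c(i2[k], len[k]))
      adj[[i2[k]]] <- rbind(adj[[i2[k]]], c(i1[k], len[k]))
    }
    raw <- if (mode == "unweighted") .brandesBFS(adj, n)
           else .brandesDijkstra(adj, n)
    bc[] <- raw / 2                # undirected: each unordered pair once
  }
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    if (denom > 0) bc <- bc / denom
  }
  new("CentralityTable", values = bc, mode = mode, normalized = normalized)
}

.brandesBFS <- function(adj, n) {
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s); head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

## Dijkstra variant; shortest-path ties detected within a small relative
## tolerance since inverse-weight lengths are floating sums.
.brandesDijkstra <- function(adj, n, tol = 1e-10) {
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(Inf, n); dist[s] <- 0
    done <- logical(n)
    preds <- vector("list", n)
    order_visited <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      order_visited <- c(order_visited, v)
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]
        if (done[w]) next
        d2 <- dist[v] + nb[r, 2]
        eps <- tol * max(1, abs(d2),
                         if (is.finite(dist[w])) abs(dist[w]) else 0)
        if (d2 < dist[w] - eps) {
          dist[w] <- d2
          sigma[w] <- sigma[v]
          preds[[w]] <- c(v)
        } else if (abs(d2 - dist[w]) <= eps) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

#' Top-k genes by betweenness
#'
#' Deterministic ranking: descending betweenness, ties broken by byte-order
#' gene id. Asking for more genes than exist returns all of them, with a
#' note.
#'
#' @param table a \linkS4class{CentralityTable}.
#' @param k positive integer.
#' @return data.frame with columns \code{gene_id}, \code{betweenness},
#'   highest first.
#' @export
rankByCentrality <- function(table, k) {
  stopifnot(is(table, "CentralityTable"))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer")
  v <- table@values
  if (k > length(v)) {
    message(sprintf("rankByCentrality: k=%d exceeds %d genes; returning all",
                    as.integer(k), length(v)))
    k <- length(v)
  }
  ord <- order(-v, names(v), method = "radix")[seq_len(k)]
  data.frame(gene_id = names(v)[ord], betweenness = unname(v[ord]),
             stringsAsFactors = FALSE)
}
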