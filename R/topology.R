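# Network topology statistics and native Markov clustering.

#' Topology statistics of a network
#'
#' Unweighted statistics on the simple graph: protein and interaction counts,
#' average degree, connected components, diameter and characteristic path
#' length on the largest component, Freeman degree centralization
#' `sum(deg_max - deg_i) / ((N-1)(N-2))`, and a log-log least-squares
#' power-law fit of the degree distribution (Pearson correlation of
#' log-frequency with log-degree, and the regression R squared).
#'
#' @param pfin a `pfin`.
#' @return list of class `topology_report`.
#' @export
topology_stats <- function(pfin) {
  if (length(pfin$nodes) == 0L) stop("empty network")
  g <- pfin_to_igraph(pfin, weighted = FALSE)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)

  comps <- igraph::components(g)
  largest <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))

  if (igraph::vcount(largest) > 1) {
    diam <- igraph::diameter(largest, weights = NA)
    cpl <- igraph::mean_distance(largest, weights = NA)
  } else {
    diam <- NA_real_; cpl <- NA_real_
  }

  centralization <- if (n > 2) {
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  } else NA_real_

  # degree distribution on log-log scale, degrees with non-zero frequency
  tab <- table(deg[deg > 0])
  if (length(tab) >= 3) {
    x <- log(as.numeric(names(tab))); y <- log(as.numeric(tab))
    fit <- stats::lm(y ~ x)
    pl_cor <- abs(stats::cor(x, y))
    pl_r2 <- summary(fit)$r.squared
  } else {
    pl_cor <- NA_real_; pl_r2 <- NA_real_
  }

  structure(
    list(proteins = n, interactions = m,
         average_degree = 2 * m / n,
         connected_components = comps$no,
         diameter = diam,
         characteristic_path_length = cpl,
         centralization = centralization,
         power_law_correlation = pl_cor,
         power_law_r2 = pl_r2),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology\n")
  cat(sprintf("  proteins: %d  interactions: %d  average degree: %.1f\n",
              x$proteins, x$interactions, x$average_degree))
  cat(sprintf("  connected components: %d  diameter: %s  path length: %s\n",
              x$connected_components,
              format(x$diameter), format(round(x$characteristic_path_length, 2))))
  cat(sprintf("  centralization: %.2f  power-law cor: %.2f  R2: %.2f\n",
              x$centralization, x$power_law_correlation, x$power_law_r2))
  invisible(x)
}

#' Markov clustering (MCL) of a network
#'
#' Native MCL on the column-stochastic transition matrix built from edge
#' weights (or the unweighted adjacency): repeated expansion (matrix square)
#' and inflation (entry-wise power, column renormalisation) with pruning of
#' small entries, until convergence. Clusters are the connected components of
#' the limit matrix's support; every node lands in exactly one cluster.
#'
#' @param pfin a `pfin`.
#' @param inflation inflation exponent, `> 1` (default 2.0, MCL's default).
#' @param weighted use edge weights as similarities (default TRUE).
#' @param max_iter iteration cap (default 100).
#' @param prune entries below this are zeroed after inflation (default 1e-5).
#' @param tol convergence: max absolute entry change (default 1e-6).
#' @param self_loops add self-loops with each node's maximum incident weight
#'   (standard MCL regularisation; default TRUE).
#' @return named integer vector: node -> cluster id (1 = largest cluster).
#' @export
mcl_cluster <- function(pfin, inflation = 2.0, weighted = TRUE,
                        max_iter = 100, prune = 1e-5, tol = 1e-6,
                        self_loops = TRUE) {
  stopifnot(inflation > 1)
  nodes <- pfin$nodes
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- if (weighted) pfin$edges$weight else rep(1, nrow(pfin$edges))
  ia <- match(pfin$edges$a, nodes); ib <- match(pfin$edges$b, nodes)
  M[cbind(ia, ib)] <- w
  M[cbind(ib, ia)] <- w
  if (self_loops) diag(M) <- pmax(apply(M, 1, max), .Machine$double.eps)

  normalize <- function(A) sweep(A, 2, pmax(colSums(A), .Machine$double.eps), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M              # expansion
    M2 <- M2^inflation         # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) {
      M <- M2; converged <- TRUE; break
    }
    M <- M2
  }
  if (!converged) warning("MCL did not converge in ", max_iter,
                          " iterations; interpreting current matrix")

  support <- (M > 0) | (t(M) > 0)
  gs <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  memb <- igraph::components(gs)$membership
  # relabel so cluster 1 is the largest
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(memb)])
  stats::setNames(out, nodes)
}
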