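# Evidence integration. Each pair's evidence scores are combined with the
# rank-decay weighted sum
#
#   WS = sum_{i=1..n} L_i / D^(i-1),   L_1 >= ... >= L_n,  D >= 1.
#
# D = 1 is a plain sum (equal weight regardless of rank); as D grows the
# weight concentrates on the single best line of evidence (WS -> L_1).

#' Rank-decay weighted sum of evidence scores
#'
#' @param scores numeric vector of positive confidence scores (any order).
#' @param D decay parameter, `>= 1`.
#' @return the weighted sum.
#' @examples
#' edge_ws(c(3, 2, 1), D = 1)   # 6
#' edge_ws(c(3, 2, 1), D = 2)   # 3 + 1 + 0.25
#' @export
edge_ws <- function(scores, D = 1) {
  if (length(scores) == 0L) stop("empty score list")
  if (D < 1) stop("D must be >= 1")
  s <- sort(scores, decreasing = TRUE)
  sum(s / D^(seq_along(s) - 1))
}

#' Attach finalised scores to evidence datasets
#'
#' Joins a finalised score table onto its evidence datasets, dropping
#' datasets that were discarded during scoring.
#'
#' @param datasets list of `evidence_dataset` objects.
#' @param scores finalised score data.frame ([finalize_scores()] /
#'   [ssnet_score()]`$scores`).
#' @return list of scored datasets (each an `evidence_dataset` with a
#'   `score` field).
#' @export
scored_datasets <- function(datasets, scores) {
  nm <- vapply(datasets, `[[`, character(1), "name")
  keep <- match(scores$dataset, nm)
  if (anyNA(keep)) {
    stop("scores reference unknown datasets: ",
         paste(scores$dataset[is.na(keep)], collapse = ", "))
  }
  mapply(function(i, s) {
    d <- datasets[[i]]
    d$score <- s
    d
  }, keep, scores$score, SIMPLIFY = FALSE)
}

#' Integrate scored datasets into a probabilistic functional network
#'
#' Every pair occurring in at least one scored dataset becomes an edge whose
#' evidence list holds the scores of all datasets containing it and whose
#' weight is [edge_ws()] of those scores at the chosen `D`.
#'
#' @param datasets list of scored datasets ([scored_datasets()]); each must
#'   carry a positive `score`.
#' @param D decay parameter, `>= 1` (default 1).
#' @return object of class `pfin`: `nodes` (character), `edges` (data.frame
#'   `a`, `b`, `weight`, `n_datasets`, `evidence` — semicolon-joined
#'   `name:score`, best first), `D`, `n_datasets`.
#' @export
integrate_pfin <- function(datasets, D = 1) {
  if (length(datasets) == 0L) stop("no datasets to integrate")
  if (D < 1) stop("D must be >= 1")
  sc <- vapply(datasets, `[[`, numeric(1), "score")
  if (any(!is.finite(sc) | sc <= 0)) stop("all dataset scores must be positive and finite")

  key <- unlist(lapply(datasets, function(d) d$pairs$keys), use.names = FALSE)
  dname <- rep(vapply(datasets, `[[`, character(1), "name"),
               vapply(datasets, function(d) length(d$pairs), integer(1)))
  dscore <- rep(sc, vapply(datasets, function(d) length(d$pairs), integer(1)))

  # order evidence within pair: score desc, then name (deterministic)
  o <- order(key, -dscore, dname, method = "radix")
  key <- key[o]; dname <- dname[o]; dscore <- dscore[o]
  grp <- factor(key, levels = unique(key))
  weight <- vapply(split(dscore, grp), edge_ws, numeric(1), D = D)
  evid <- vapply(split(sprintf("%s:%.6g", dname, dscore), grp),
                 paste, character(1), collapse = ";")
  n_ds <- as.integer(lengths(split(dscore, grp)))

  genes <- pair_key_genes(levels(grp))
  edges <- data.frame(a = genes[, 1], b = genes[, 2],
                      weight = unname(weight), n_datasets = n_ds,
                      evidence = unname(evid), stringsAsFactors = FALSE)
  structure(
    list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
         D = D, n_datasets = length(datasets)),
    class = "pfin"
  )
}

#' @export
print.pfin <- function(x, ...) {
  cat(sprintf("pfin: %d proteins, %d weighted interactions (D = %g, %d datasets)\n",
              length(x$nodes), nrow(x$edges), x$D, x$n_datasets))
  invisible(x)
}

#' @export
summary.pfin <- function(object, ...) {
  deg <- table(c(object$edges$a, object$edges$b))
  out <- list(
    n_nodes = length(object$nodes),
    n_edges = nrow(object$edges),
    D = object$D,
    weight_summary = summary(object$edges$weight),
    degree_summary = summary(as.integer(deg)),
    avg_degree = 2 * nrow(object$edges) / length(object$nodes)
  )
  class(out) <- "summary.pfin"
  out
}

#' @export
print.summary.pfin <- function(x, ...) {
  cat(sprintf("Probabilistic functional integrated network (D = %g)\n", x$D))
  cat(sprintf("  proteins: %d   interactions: %d   average degree: %.1f\n",
              x$n_nodes, x$n_edges, x$avg_degree))
  cat("  edge weights:\n"); print(x$weight_summary)
  cat("  node degrees:\n"); print(x$degree_summary)
  invisible(x)
}

#' @export
plot.pfin <- function(x, ...) {
  deg <- as.integer(table(c(x$edges$a, x$edges$b)))
  tab <- table(deg)
  graphics::plot(as.integer(names(tab)), as.integer(tab), log = "xy",
                 xlab = "degree", ylab = "frequency",
                 main = "PFIN degree distribution", pch = 19, ...)
  invisible(x)
}

#' Convert a network to an igraph object
#' @param pfin a `pfin`.
#' @param weighted use integrated weights as edge attribute (default TRUE).
#' @return an undirected `igraph` graph.
#' @export
pfin_to_igraph <- function(pfin, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(pfin$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = pfin$nodes)
  if (weighted) igraph::E(g)$weight <- pfin$edges$weight
  g
}

#' Write a network as a TSV edge list
#' @param pfin a `pfin`.
#' @param path output path.
#' @param format `"tsv"` (full edge list), `"abc"` (MCL-compatible
#'   `gene gene weight`) or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_pfin <- function(pfin, path, format = c("tsv", "abc", "sif")) {
  format <- match.arg(format)
  e <- pfin$edges
  out <- switch(format,
    tsv = data.frame(gene_a = e$a, gene_b = e$b, weight = e$weight,
                     n_datasets = e$n_datasets, evidence = e$evidence),
    abc = data.frame(e$a, e$b, e$weight),
    sif = data.frame(e$a, "fa", e$b)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = (format == "tsv"))
  invisible(path)
}

#' Read a network written by [write_pfin()] (tsv format)
#' @param path path to the edge-list TSV.
#' @param D the D value recorded with the network (metadata only).
#' @return a `pfin`.
#' @export
read_pfin <- function(path, D = NA_real_) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  edges <- data.frame(a = e$gene_a, b = e$gene_b, weight = e$weight,
                      n_datasets = e$n_datasets, evidence = e$evidence,
                      stringsAsFactors = FALSE)
  structure(
    list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
         D = D, n_datasets = NA_integer_),
    class = "pfin"
  )
}
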