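# Top-level pipeline: parse -> split -> two-stage scoring -> integration,
# with optional evaluation, topology and clustering downstream.

#' Build a single-source probabilistic functional integrated network
#'
#' Runs the full single-source method on a set of interaction records: split
#' by publication into high-throughput studies and a low-throughput pool
#' (study-size threshold), split the pool by experimental type, score HTP
#' studies against the pooled LTP Gold Standard and each LTP type against the
#' remaining types, then integrate all positively-scoring datasets with the
#' rank-decay weighted sum.
#'
#' @param records data.frame of interaction records ([parse_biogrid()]), or a
#'   `biogrid_parse` object.
#' @param threshold study-size threshold separating HTP from LTP (default
#'   100 unique pairs).
#' @param D integration decay parameter (default 1: plain score sum).
#' @return object of class `ssnet_fit` (also `pfin`): the integrated network
#'   plus `scores` (the `ssnet_scores` object), `threshold`, `data_loss`
#'   (percent proteins/interactions/datasets lost between parsed input and
#'   final network), and the dataset partition (`htp`, `ltp_types`).
#' @examples
#' sim <- simulate_interactome(sim_config(n_genes = 60, n_modules = 4,
#'                                        n_htp_studies = 2,
#'                                        htp_size_range = c(60, 90),
#'                                        n_ltp_studies = 30, seed = 7))
#' net <- ssnet(parse_biogrid(sim$interactions), threshold = 50)
#' net
#' @export
ssnet <- function(records, threshold = 100, D = 1) {
  if (inherits(records, "biogrid_parse")) records <- records$records
  stopifnot(is.data.frame(records), nrow(records) > 0)

  sp <- split_htp_ltp(records, threshold)
  ltp_types <- split_ltp_by_type(sp$ltp_pool)
  scores <- ssnet_score(sp$htp, ltp_types)
  datasets <- scored_datasets(c(sp$htp, ltp_types), scores$scores)
  net <- integrate_pfin(datasets, D = D)

  input_ps <- to_pair_set(records, "input")
  input_genes <- pair_set_genes(input_ps)
  n_datasets_in <- length(sp$htp) + length(ltp_types)
  loss <- list(
    proteins = 100 * (1 - length(net$nodes) / length(input_genes)),
    interactions = 100 * (1 - nrow(net$edges) / length(input_ps)),
    datasets = 100 * (1 - nrow(scores$scores) / n_datasets_in)
  )

  structure(
    c(net, list(scores = scores, threshold = threshold, data_loss = loss,
                htp = sp$htp, ltp_types = ltp_types)),
    class = c("ssnet_fit", "pfin")
  )
}

#' @export
print.ssnet_fit <- function(x, ...) {
  cat("Single-source probabilistic functional integrated network\n")
  cat(sprintf("  threshold: %d unique pairs   D: %g\n", x$threshold, x$D))
  cat(sprintf("  %d HTP studies, %d LTP types; %d datasets integrated\n",
              length(x$htp), length(x$ltp_types), nrow(x$scores$scores)))
  cat(sprintf("  network: %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  data loss: %.1f%% proteins, %.1f%% interactions, %.1f%% datasets\n",
              x$data_loss$proteins, x$data_loss$interactions, x$data_loss$datasets))
  invisible(x)
}

#' @export
summary.ssnet_fit <- function(object, ...) {
  s <- NextMethod()
  s$scores <- object$scores$scores
  s$data_loss <- object$data_loss
  class(s) <- c("summary.ssnet_fit", class(s))
  s
}

#' @export
print.summary.ssnet_fit <- function(x, ...) {
  NextMethod()
  cat("\nDataset scores (top 10):\n")
  print(utils::head(x$scores[, c("dataset", "klass", "score", "status")], 10))
  cat(sprintf("\nData loss: %.1f%% proteins, %.1f%% interactions, %.1f%% datasets\n",
              x$data_loss$proteins, x$data_loss$interactions, x$data_loss$datasets))
  invisible(x)
}

#' Run the full pipeline and write artefacts to a directory
#'
#' Executes split, scoring, integration (per D value), evaluation and
#' topology, writing per-stage artefacts eagerly: the score table, one
#' network edge list per D, the data-loss report, per-term AUC tables, the
#' topology report, cluster assignments and a manifest recording every
#' parameter and input.
#'
#' @param interactions path to a BioGRID-format file.
#' @param obo,gaf optional ontology/annotation paths; when both given the
#'   networks are evaluated by leave-one-out function prediction.
#' @param out_dir output directory.
#' @param organism optional taxon filter for parsing.
#' @param dialect BioGRID dialect (default `"tab3"`).
#' @param threshold study-size threshold (default 100).
#' @param D numeric vector of decay values (default 1; several values run a
#'   D sweep).
#' @param min_count,max_count evaluation term-count bounds (defaults 100 and
#'   1000).
#' @param inflation MCL inflation (default 2).
#' @return (invisibly) list with the fit for the first D, evaluation tables
#'   per D, topology report and manifest.
#' @export
run_pipeline <- function(interactions, obo = NULL, gaf = NULL,
                         out_dir = "ssnet_out", organism = NULL,
                         dialect = "tab3", threshold = 100, D = 1,
                         min_count = 100, max_count = 1000, inflation = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parsed <- parse_biogrid(interactions, dialect = dialect, organism = organism)

  annset <- NULL
  if (!is.null(obo) && !is.null(gaf)) {
    annset <- propagate_annotations(read_obo(obo), read_gaf(gaf))
  }

  fits <- list(); evals <- list()
  for (d in D) {
    fit <- ssnet(parsed, threshold = threshold, D = d)
    tag <- gsub("[^0-9A-Za-z.]", "_", format(d))
    write_pfin(fit, file.path(out_dir, sprintf("network_D%s.tsv", tag)))
    fits[[format(d)]] <- fit
    if (!is.null(annset)) {
      ev <- evaluate_network(fit, annset, min_count, max_count)
      utils::write.table(ev, file.path(out_dir, sprintf("aucs_D%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      evals[[format(d)]] <- ev
    }
  }
  fit1 <- fits[[1]]

  utils::write.table(fit1$scores$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit1$scores$raw, file.path(out_dir, "scores_raw.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fit1$data_loss, file.path(out_dir, "data_loss.json"),
                       auto_unbox = TRUE, digits = NA)

  topo <- topology_stats(fit1)
  jsonlite::write_json(unclass(topo), file.path(out_dir, "topology.json"),
                       auto_unbox = TRUE, digits = NA)
  clusters <- mcl_cluster(fit1, inflation = inflation)
  utils::write.table(data.frame(gene = names(clusters), cluster = clusters),
                     file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    inputs = list(interactions = interactions, obo = obo, gaf = gaf),
    parameters = list(organism = organism, dialect = dialect,
                      threshold = threshold, D = D,
                      min_count = min_count, max_count = max_count,
                      inflation = inflation),
    parse_report = parsed$report,
    discarded_datasets = fit1$scores$raw$dataset[
      !fit1$scores$raw$status %in% c("scored", "infinite")],
    n_clusters = max(clusters),
    versions = list(ssnet = as.character(utils::packageVersion("ssnet")),
                    r = R.version.string)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(fit = fit1, fits = fits, evaluations = evals,
                 topology = topo, clusters = clusters, manifest = manifest))
}
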