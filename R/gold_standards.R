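# Gold Standard construction. A Gold Standard is a protein universe plus a
# set of positive pairs within it; negatives are implied: every unordered
# pair over the universe that is not a positive.

#' Construct a Gold Standard from an explicit pair set
#'
#' The universe is the set of genes incident to at least one pair; the pairs
#' are the positives. This is how the internal low-throughput Gold Standard
#' (LTP_GS) and its leave-one-type-out variants are built.
#'
#' @param pairs a [pair_set()].
#' @param name Gold Standard name.
#' @return object of class `gold_standard`: `name`, `universe` (character),
#'   `positives` (pair keys).
#' @export
build_gs_from_pairs <- function(pairs, name = pairs$name) {
  if (length(pairs) == 0L) stop("cannot build a Gold Standard from an empty pair set")
  structure(
    list(name = name, universe = pair_set_genes(pairs), positives = pairs$keys),
    class = "gold_standard"
  )
}

#' Number of implied negatives of a Gold Standard
#' @param gs a `gold_standard`.
#' @return `choose(|universe|, 2) - |positives|`.
#' @export
gs_n_negatives <- function(gs) {
  choose(length(gs$universe), 2) - length(gs$positives)
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard '%s': %d proteins, %d positives, %.0f implied negatives\n",
              x$name, length(x$universe), length(x$positives), gs_n_negatives(x)))
  invisible(x)
}

#' Construct a pathway-derived Gold Standard
#'
#' Proteins in the same pathway are positives: the positive set is the union
#' over pathways of all within-pathway unordered gene pairs (the complete
#' graph on each pathway's membership).
#'
#' @param membership data.frame with columns `gene`, `pathway`.
#' @param name Gold Standard name (default `"MP_GS"`).
#' @return a `gold_standard`; the universe is every gene in the table.
#' @export
build_pathway_gs <- function(membership, name = "MP_GS") {
  stopifnot(all(c("gene", "pathway") %in% names(membership)),
            nrow(membership) > 0)
  keys <- unlist(lapply(split(membership$gene, membership$pathway), function(gs) {
    gs <- unique(gs)
    if (length(gs) < 2) return(character(0))
    cmb <- utils::combn(sort(gs), 2)
    pair_key(cmb[1, ], cmb[2, ])
  }), use.names = FALSE)
  structure(
    list(name = name, universe = sort(unique(membership$gene)),
         positives = unique(keys)),
    class = "gold_standard"
  )
}

#' Construct a GO biological-process Gold Standard
#'
#' Genes co-annotated to a sufficiently specific process term are positives.
#' Term eligibility is by annotation count in the genome: in `"fraction"`
#' mode terms covering less than `limit` of the genome qualify (e.g. the
#' BP10_GS standard uses `limit = 0.10`); in `"count"` mode terms with fewer
#' than `limit` annotations qualify (BP100_GS uses `limit = 100`).
#'
#' @param annset an `annotation_set` from [propagate_annotations()].
#' @param mode `"fraction"` or `"count"`.
#' @param limit positive eligibility limit (fraction of the genome, or count).
#' @param genome_size denominator for fraction mode; defaults to the number of
#'   genes with at least one annotation in `annset`.
#' @param name Gold Standard name.
#' @return a `gold_standard`; universe = genes with at least one eligible-term
#'   annotation, positives = pairs co-annotated to at least one eligible term.
#' @export
build_go_bp_gs <- function(annset, mode = c("fraction", "count"), limit,
                           genome_size = length(annset$gene_terms),
                           name = NULL) {
  mode <- match.arg(mode)
  stopifnot(limit > 0)
  counts <- annset$term_counts
  eligible <- if (mode == "fraction") {
    names(counts)[counts / genome_size < limit]
  } else {
    names(counts)[counts < limit]
  }
  if (is.null(name)) {
    name <- if (mode == "fraction") sprintf("BP%d_GS", round(limit * 100))
    else sprintf("BP%d_GS", round(limit))
  }

  # term -> genes map restricted to eligible terms
  gene_names <- names(annset$gene_terms)
  term_of <- unlist(annset$gene_terms, use.names = FALSE)
  gene_of <- rep(gene_names, lengths(annset$gene_terms))
  keep <- term_of %in% eligible
  by_term <- split(gene_of[keep], term_of[keep])

  keys <- unlist(lapply(by_term, function(gs) {
    gs <- unique(gs)
    if (length(gs) < 2) return(character(0))
    cmb <- utils::combn(sort(gs), 2)
    pair_key(cmb[1, ], cmb[2, ])
  }), use.names = FALSE)

  structure(
    list(name = name, universe = sort(unique(gene_of[keep])),
         positives = unique(keys)),
    class = "gold_standard"
  )
}
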