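# HTP/LTP partitioning. A study is one publication (PubMed ID); its size is
# its number of unique unordered pairs after self-pair removal. Studies at or
# above the threshold become individual high-throughput evidence datasets;
# everything else forms the low-throughput pool, later split by experimental
# type.

#' Construct an evidence dataset
#' @param name dataset name.
#' @param pairs a [pair_set()].
#' @param klass `"htp_study"` or `"ltp_type"`.
#' @keywords internal
evidence_dataset <- function(name, pairs, klass = c("htp_study", "ltp_type")) {
  klass <- match.arg(klass)
  structure(list(name = name, pairs = pairs, klass = klass),
            class = "evidence_dataset")
}

#' @export
print.evidence_dataset <- function(x, ...) {
  cat(sprintf("evidence_dataset '%s' (%s): %d unique pairs\n",
              x$name, x$klass, length(x$pairs)))
  invisible(x)
}

# "[Author].[PubMed ID]" naming; author strings like "Smith J (2020)" reduce
# to the surname token.
.study_name <- function(author, pubmed_id) {
  surname <- vapply(strsplit(author, "[ ,(]"), function(x) x[1], character(1))
  surname[is.na(surname) | surname == ""] <- "Unknown"
  paste0(surname, ".", pubmed_id)
}

#' Split interaction records into HTP studies and an LTP pool
#'
#' Records are grouped by publication; each study whose unique-pair count is
#' at or above `threshold` becomes one high-throughput evidence dataset, and
#' all remaining records form the low-throughput pool.
#'
#' @param records data.frame of interaction records ([parse_biogrid()]).
#' @param threshold positive integer study-size threshold (default 100).
#' @return list with elements `htp` (list of `evidence_dataset`) and
#'   `ltp_pool` (data.frame of the remaining records).
#' @export
split_htp_ltp <- function(records, threshold = 100) {
  stopifnot(threshold >= 1)
  if (nrow(records) == 0L) return(list(htp = list(), ltp_pool = records))

  by_study <- split(seq_len(nrow(records)), records$pubmed_id)
  sizes <- vapply(by_study, function(idx) {
    length(to_pair_set(records[idx, , drop = FALSE]))
  }, numeric(1))

  htp_ids <- names(by_study)[sizes >= threshold]
  htp <- lapply(htp_ids, function(pm) {
    idx <- by_study[[pm]]
    nm <- .study_name(records$author[idx[1]], pm)
    evidence_dataset(nm, to_pair_set(records[idx, , drop = FALSE], nm),
                     "htp_study")
  })
  # deterministic ordering: largest first, name as tie-break
  ord <- order(-vapply(htp, function(d) length(d$pairs), numeric(1)),
               vapply(htp, `[[`, character(1), "name"))
  htp <- htp[ord]

  ltp_idx <- unlist(by_study[sizes < threshold], use.names = FALSE)
  ltp_pool <- records[sort(ltp_idx), , drop = FALSE]
  rownames(ltp_pool) <- NULL
  list(htp = htp, ltp_pool = ltp_pool)
}

#' Split the LTP pool into per-experimental-type datasets
#'
#' One evidence dataset per distinct experimental system present in the pool.
#' A pair observed under two systems appears in both type datasets.
#'
#' @param ltp_pool data.frame of low-throughput records ([split_htp_ltp()]).
#' @return list of `evidence_dataset` objects (class `ltp_type`), ordered by
#'   decreasing size.
#' @export
split_ltp_by_type <- function(ltp_pool) {
  if (nrow(ltp_pool) == 0L) return(list())
  by_type <- split(seq_len(nrow(ltp_pool)), ltp_pool$experimental_system)
  out <- lapply(names(by_type), function(ty) {
    evidence_dataset(ty, to_pair_set(ltp_pool[by_type[[ty]], , drop = FALSE], ty),
                     "ltp_type")
  })
  ord <- order(-vapply(out, function(d) length(d$pairs), numeric(1)),
               vapply(out, `[[`, character(1), "name"))
  out[ord]
}

#' Sweep the HTP/LTP study-size threshold
#'
#' Recomputes the split at each threshold and reports the sizes and overlap of
#' the HTP and LTP sides, in unique interactions and in unique proteins. Used
#' to choose a threshold that maximises the Gold Standard's coverage while
#' keeping its size manageable.
#'
#' @param records data.frame of interaction records.
#' @param thresholds vector of positive integers.
#' @return data.frame with one row per threshold: `threshold`, `htp_pairs`,
#'   `ltp_pairs`, `overlap_pairs`, `htp_proteins`, `ltp_proteins`,
#'   `overlap_proteins`.
#' @export
threshold_sweep <- function(records, thresholds) {
  stopifnot(length(thresholds) > 0)
  rows <- lapply(thresholds, function(th) {
    sp <- split_htp_ltp(records, th)
    htp_ps <- if (length(sp$htp)) {
      pair_set_union(lapply(sp$htp, `[[`, "pairs"), "htp")
    } else pair_set(character(0), character(0), "htp")
    ltp_ps <- to_pair_set(sp$ltp_pool, "ltp")
    htp_genes <- pair_set_genes(htp_ps)
    ltp_genes <- pair_set_genes(ltp_ps)
    data.frame(
      threshold = th,
      htp_pairs = length(htp_ps),
      ltp_pairs = length(ltp_ps),
      overlap_pairs = length(intersect(htp_ps$keys, ltp_ps$keys)),
      htp_proteins = length(htp_genes),
      ltp_proteins = length(ltp_genes),
      overlap_proteins = length(intersect(htp_genes, ltp_genes))
    )
  })
  do.call(rbind, rows)
}
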