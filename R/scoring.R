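# Log-likelihood dataset scoring (Lee score). For an evidence dataset E and
# Gold Standard with positives P and implied negatives N over universe U:
#
#   lls(E) = ln( (pos/neg) / (|P|/|N|) )
#
# where pos and neg count E's unique pairs (restricted to pairs with both
# genes in U) that are Gold Standard positives and negatives respectively.
# Datasets with pos = 0 do not score; datasets with finite lls <= 0 are
# discarded; datasets with neg = 0 score infinity and are later assigned
# ceil(max finite score) + 1 so they exceed every real score.

#' Log-likelihood score of an evidence dataset against a Gold Standard
#'
#' @param dataset an `evidence_dataset` (or a bare [pair_set()]).
#' @param gs a `gold_standard`.
#' @return one-row data.frame of class `lls_result`: `dataset`, `klass`,
#'   `lls` (natural-log units; `Inf` for perfect overlap, `NA` when
#'   unscoreable), `status` (`scored`, `infinite`, `discarded_nonpositive`,
#'   `discarded_noscore`), `pos_overlap`, `neg_overlap`, `prior_pos`,
#'   `prior_neg`, `scoreable_pairs`.
#' @examples
#' gs <- build_gs_from_pairs(pair_set(c("A", "C"), c("B", "D")), "toy")
#' lls(pair_set(c("A", "A"), c("B", "C"), "E"), gs)
#' @export
lls <- function(dataset, gs) {
  ps <- if (inherits(dataset, "evidence_dataset")) dataset$pairs else dataset
  klass <- if (inherits(dataset, "evidence_dataset")) dataset$klass else NA_character_
  prior_pos <- length(gs$positives)
  prior_neg <- gs_n_negatives(gs)
  if (prior_pos < 1) stop("Gold Standard has no positives")
  if (prior_neg < 1) stop("Gold Standard has no implied negatives; prior odds undefined")

  genes <- pair_key_genes(ps$keys)
  in_universe <- genes[, 1] %in% gs$universe & genes[, 2] %in% gs$universe
  restricted <- ps$keys[in_universe]
  pos <- sum(restricted %in% gs$positives)
  neg <- length(restricted) - pos

  if (pos == 0) {
    score <- NA_real_; status <- "discarded_noscore"
  } else if (neg == 0) {
    score <- Inf; status <- "infinite"
  } else {
    score <- log((pos / neg) / (prior_pos / prior_neg))
    status <- if (score > 0) "scored" else "discarded_nonpositive"
  }

  structure(
    data.frame(dataset = ps$name, klass = klass, lls = score, status = status,
               pos_overlap = pos, neg_overlap = neg,
               prior_pos = prior_pos, prior_neg = prior_neg,
               scoreable_pairs = length(restricted),
               stringsAsFactors = FALSE),
    class = c("lls_result", "data.frame")
  )
}

#' Finalise a batch of log-likelihood scores
#'
#' Removes discarded datasets and replaces infinite scores (perfect Gold
#' Standard overlap) with `ceil(max finite score) + 1`, computed over the
#' whole batch so the replacement exceeds every real score. If every
#' scoreable dataset is infinite the replacement is 1.0. Output is sorted by
#' score, descending.
#'
#' @param results data.frame of stacked `lls_result` rows.
#' @return data.frame of scored datasets with a final `score` column, sorted
#'   by decreasing score.
#' @export
finalize_scores <- function(results) {
  res <- as.data.frame(results)
  kept <- res[res$status %in% c("scored", "infinite"), , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("all datasets were discarded during scoring")
    kept$score <- numeric(0)
    return(kept)
  }
  finite <- kept$lls[kept$status == "scored"]
  inf_score <- if (length(finite)) ceiling(max(finite)) + 1 else 1.0
  kept$score <- ifelse(kept$status == "infinite", inf_score, kept$lls)
  kept <- kept[order(-kept$score, kept$dataset), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Two-stage single-source scoring
#'
#' Stage 1: the pooled low-throughput pairs form the internal Gold Standard
#' (LTP_GS) and every high-throughput study is scored against it. Stage 2:
#' each low-throughput experimental type is scored against the pool of the
#' remaining types (leave-one-type-out). Both stages are finalised as one
#' batch so the infinity replacement is consistent across HTP and LTP scores.
#'
#' @param htp list of `evidence_dataset` (class `htp_study`); may be empty.
#' @param ltp_types list of `evidence_dataset` (class `ltp_type`); at least 2.
#' @return list of class `ssnet_scores`: `scores` (finalised data.frame),
#'   `raw` (all lls results incl. discarded), `ltp_gs` (the stage-1 Gold
#'   Standard).
#' @export
ssnet_score <- function(htp, ltp_types) {
  if (length(ltp_types) < 2) {
    stop("ssnet_score needs at least 2 LTP type datasets: the leave-one-type-out ",
         "Gold Standard would otherwise be empty")
  }
  ltp_sets <- lapply(ltp_types, `[[`, "pairs")
  ltp_gs <- build_gs_from_pairs(pair_set_union(ltp_sets, "LTP_GS"))

  res_htp <- lapply(htp, lls, gs = ltp_gs)
  res_ltp <- lapply(seq_along(ltp_types), function(i) {
    gs_i <- build_gs_from_pairs(pair_set_union(ltp_sets[-i], "LTP_GS_loo"))
    lls(ltp_types[[i]], gs_i)
  })
  raw <- do.call(rbind, c(res_htp, res_ltp))
  structure(
    list(scores = finalize_scores(raw), raw = raw, ltp_gs = ltp_gs),
    class = "ssnet_scores"
  )
}

#' @export
print.ssnet_scores <- function(x, ...) {
  n_disc <- sum(!x$raw$status %in% c("scored", "infinite"))
  cat(sprintf("ssnet_scores: %d datasets scored (%d HTP, %d LTP), %d discarded\n",
              nrow(x$scores), sum(x$scores$klass == "htp_study"),
              sum(x$scores$klass == "ltp_type"), n_disc))
  if (nrow(x$scores)) {
    print(utils::head(x$scores[, c("dataset", "klass", "score", "status")], 10))
    if (nrow(x$scores) > 10) cat("...\n")
  }
  invisible(x)
}
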