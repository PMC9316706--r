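# Guilt-by-association evaluation. Function prediction uses the Maximum
# Weight rule: a protein's score for a term is the weight of its heaviest
# edge to a neighbour annotated with that term. Known annotations are
# assessed leave-one-out: the target protein's own annotations never enter
# its score. Per-term ROC AUC is the Wilcoxon statistic; its standard error
# is the Hanley-McNeil closed form.

#' Maximum Weight term scores over a network
#'
#' For each network node, the prediction score for `term` is the maximum
#' weight among its edges to neighbours annotated with `term` (0 when no
#' annotated neighbour exists). The node's own annotations are masked, which
#' realises leave-one-out validation of known annotations.
#'
#' @param pfin a `pfin`.
#' @param annset an `annotation_set`.
#' @param term ontology term id.
#' @return named numeric vector: node -> score.
#' @export
predict_term_scores <- function(pfin, annset, term) {
  has_term <- vapply(annset$gene_terms, function(ts) term %in% ts, logical(1))
  annotated <- names(annset$gene_terms)[has_term]
  scores <- stats::setNames(numeric(length(pfin$nodes)), pfin$nodes)
  e <- pfin$edges
  # contribute each edge endpoint's weight to the *other* endpoint's score
  # when the annotated end carries the term
  b_ann <- e$b %in% annotated
  a_ann <- e$a %in% annotated
  if (any(b_ann)) {
    mx <- tapply(e$weight[b_ann], e$a[b_ann], max)
    scores[names(mx)] <- pmax(scores[names(mx)], mx)
  }
  if (any(a_ann)) {
    mx <- tapply(e$weight[a_ann], e$b[a_ann], max)
    scores[names(mx)] <- pmax(scores[names(mx)], mx)
  }
  scores
}

#' ROC AUC as the Wilcoxon rank statistic
#'
#' `theta` is the fraction of (positive, negative) pairs where the positive
#' scores higher, counting ties as one half — the normalised Mann-Whitney U.
#'
#' @param scores named numeric vector of prediction scores.
#' @param positives,negatives disjoint, non-empty sets of names of `scores`.
#' @return `theta` in \[0, 1\].
#' @export
term_auc <- function(scores, positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both classes must be non-empty")
  }
  if (length(intersect(positives, negatives)) > 0L) {
    stop("positives and negatives must be disjoint")
  }
  sp <- scores[positives]
  sn <- scores[negatives]
  r <- rank(c(sp, sn))  # mean ranks handle ties as 1/2
  np <- length(sp); nn <- length(sn)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Standard error of the Wilcoxon AUC statistic
#'
#' Hanley-McNeil closed form:
#' `SE = sqrt((theta(1-theta) + (Cp-1)(Q1-theta^2) + (Cn-1)(Q2-theta^2)) / (Cp Cn))`
#' with `Q1 = theta/(2-theta)` and `Q2 = 2 theta^2/(1+theta)`.
#'
#' @param theta AUC in \[0, 1\].
#' @param c_p,c_n positive and negative class sizes (`>= 1`).
#' @return the standard error.
#' @export
se_w <- function(theta, c_p, c_n) {
  if (any(theta < 0 | theta > 1)) stop("theta must be in [0, 1]")
  stopifnot(c_p >= 1, c_n >= 1)
  q1 <- theta / (2 - theta)
  q2 <- 2 * theta^2 / (1 + theta)
  v <- (theta * (1 - theta) + (c_p - 1) * (q1 - theta^2) +
          (c_n - 1) * (q2 - theta^2)) / (c_p * c_n)
  sqrt(pmax(v, 0))
}

#' Leave-one-out functional prediction over eligible process terms
#'
#' Terms with genome-wide annotation counts inside `[min_count, max_count]`
#' (measured on the propagated annotation set) are evaluated. For each term,
#' positives are the network nodes annotated to it and negatives the network
#' nodes with at least one annotation but not that term; terms lacking either
#' class in the network are skipped.
#'
#' @param pfin a `pfin`.
#' @param annset a propagated `annotation_set` (IEA excluded for evaluation).
#' @param min_count,max_count term eligibility bounds (defaults 100 and 1000).
#' @return data.frame of class `roc_results`: `term`, `theta`, `se`, `n_pos`,
#'   `n_neg`.
#' @export
evaluate_network <- function(pfin, annset, min_count = 100, max_count = 1000) {
  counts <- annset$term_counts
  eligible <- names(counts)[counts >= min_count & counts <= max_count]
  annotated_nodes <- intersect(pfin$nodes, names(annset$gene_terms))
  if (length(annotated_nodes) == 0L) {
    warning("network has no annotated nodes")
    return(structure(data.frame(term = character(0), theta = numeric(0),
                                se = numeric(0), n_pos = integer(0),
                                n_neg = integer(0)),
                     class = c("roc_results", "data.frame")))
  }
  node_terms <- annset$gene_terms[annotated_nodes]

  rows <- lapply(eligible, function(t) {
    pos <- annotated_nodes[vapply(node_terms, function(ts) t %in% ts, logical(1))]
    neg <- setdiff(annotated_nodes, pos)
    if (length(pos) == 0L || length(neg) == 0L) return(NULL)
    sc <- predict_term_scores(pfin, annset, t)
    th <- term_auc(sc, pos, neg)
    data.frame(term = t, theta = th, se = se_w(th, length(pos), length(neg)),
               n_pos = length(pos), n_neg = length(neg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), theta = numeric(0), se = numeric(0),
                      n_pos = integer(0), n_neg = integer(0))
  }
  rownames(out) <- NULL
  structure(out, class = c("roc_results", "data.frame"))
}

#' Compare per-term AUCs of two networks
#'
#' For each term evaluated in both networks, reports the AUC difference and
#' whether it is statistically significant under a two-sided z-test with
#' independent errors: `|dtheta| > 1.96 * sqrt(se_a^2 + se_b^2)`.
#'
#' @param a,b `roc_results` data.frames from [evaluate_network()].
#' @return list of class `network_comparison`: `terms` (data.frame `term`,
#'   `theta_a`, `theta_b`, `dtheta`, `significant`) and `summary` (counts of
#'   improved terms per side, total and among significant changes).
#' @export
compare_networks <- function(a, b) {
  shared <- intersect(a$term, b$term)
  if (length(shared) == 0L) stop("no shared terms to compare")
  ia <- match(shared, a$term); ib <- match(shared, b$term)
  dtheta <- a$theta[ia] - b$theta[ib]
  sig <- abs(dtheta) > 1.96 * sqrt(a$se[ia]^2 + b$se[ib]^2)
  terms <- data.frame(term = shared,
                      theta_a = a$theta[ia], theta_b = b$theta[ib],
                      dtheta = dtheta, significant = sig,
                      stringsAsFactors = FALSE)
  structure(
    list(terms = terms,
         summary = list(
           n_terms = length(shared),
           improved_a = sum(dtheta > 0), improved_b = sum(dtheta < 0),
           n_significant = sum(sig),
           significant_improved_a = sum(sig & dtheta > 0),
           significant_improved_b = sum(sig & dtheta < 0))),
    class = "network_comparison"
  )
}

#' @export
print.network_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("network comparison over %d terms: %d improved in A, %d in B\n",
              s$n_terms, s$improved_a, s$improved_b))
  cat(sprintf("  %d significant changes (%d favour A, %d favour B)\n",
              s$n_significant, s$significant_improved_a, s$significant_improved_b))
  invisible(x)
}
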