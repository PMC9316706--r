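# Independent brute-force oracles, deliberately structured differently from
# the package implementation.

# Log-likelihood score by direct frequency ratios: enumerate every unordered
# pair over the Gold Standard universe, classify it, and read the dataset's
# linkage frequencies straight off that enumeration.
oracle_lls <- function(dataset_keys, universe, gs_positive_keys) {
  universe <- sort(universe)
  all_pairs <- if (length(universe) >= 2) {
    cmb <- combn(universe, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\t")
  } else character(0)
  is_pos <- all_pairs %in% gs_positive_keys
  in_data <- all_pairs %in% dataset_keys

  pos <- sum(in_data & is_pos)
  neg <- sum(in_data & !is_pos)
  prior_pos <- sum(is_pos)
  prior_neg <- sum(!is_pos)

  if (pos == 0) return(list(lls = NA_real_, status = "discarded_noscore",
                            pos = pos, neg = neg))
  if (neg == 0) return(list(lls = Inf, status = "infinite", pos = pos, neg = neg))
  p_le <- pos / (pos + neg)
  p_l <- prior_pos / (prior_pos + prior_neg)
  score <- log((p_le / (1 - p_le)) / (p_l / (1 - p_l)))
  list(lls = score,
       status = if (score > 0) "scored" else "discarded_nonpositive",
       pos = pos, neg = neg)
}

# AUC by exhaustive pair comparison
oracle_auc <- function(scores, positives, negatives) {
  tot <- 0
  for (p in positives) {
    for (n in negatives) {
      tot <- tot + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
    }
  }
  unname(tot / (length(positives) * length(negatives)))
}

# all-pairs shortest paths by BFS on an edge list (unweighted)
oracle_bfs_distances <- function(nodes, edge_a, edge_b) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edge_a)) {
    adj[[edge_a[i]]] <- c(adj[[edge_a[i]]], edge_b[i])
    adj[[edge_b[i]]] <- c(adj[[edge_b[i]]], edge_a[i])
  }
  d <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# random evidence dataset over a gene alphabet
random_pair_set <- function(genes, n_pairs, name = "rand") {
  a <- sample(genes, n_pairs, replace = TRUE)
  b <- sample(genes, n_pairs, replace = TRUE)
  pair_set(a, b, name)
}

# small interaction-record data.frame builder
make_records <- function(a, b, system = "Two-hybrid", pubmed = "1",
                         author = "Smith J (2020)", org = "559292",
                         type = "physical") {
  n <- length(a)
  data.frame(gene_a = a, gene_b = b,
             experimental_system = rep_len(system, n),
             system_type = rep_len(type, n),
             author = rep_len(author, n),
             pubmed_id = rep_len(pubmed, n),
             organism_a = rep_len(org, n), organism_b = rep_len(org, n),
             stringsAsFactors = FALSE)
}

# tiny evidence dataset from explicit pairs
make_dataset <- function(a, b, name, klass = "htp_study") {
  structure(list(name = name, pairs = pair_set(a, b, name), klass = klass),
            class = "evidence_dataset")
}

# minimal pfin from an explicit weighted edge list
make_pfin <- function(a, b, w, D = 1) {
  edges <- data.frame(a = a, b = b, weight = w,
                      n_datasets = 1L, evidence = "x:1",
                      stringsAsFactors = FALSE)
  structure(list(nodes = sort(unique(c(a, b))), edges = edges,
                 D = D, n_datasets = 1L),
            class = "pfin")
}

# annotation_set built directly from a gene -> terms list (already propagated)
make_annset <- function(gene_terms, exclude_iea = TRUE) {
  counts <- table(unlist(gene_terms, use.names = FALSE))
  structure(list(gene_terms = gene_terms,
                 term_counts = setNames(as.integer(counts), names(counts)),
                 namespace = "biological_process", exclude_iea = exclude_iea,
                 skipped_unknown_terms = 0L),
            class = "annotation_set")
}

# pair keys of all unordered pairs over a gene vector
all_pair_keys <- function(genes) {
  genes <- sort(genes)
  if (length(genes) < 2) return(character(0))
  cmb <- combn(genes, 2)
  paste(cmb[1, ], cmb[2, ], sep = "\t")
}
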