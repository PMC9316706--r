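toy_gs <- function() {
  build_gs_from_pairs(pair_set(c("A", "C"), c("B", "D")), "toy")
}

test_that("log-likelihood score matches hand-derived frequency ratios", {
  gs <- toy_gs()  # universe {A,B,C,D}, positives {AB,CD}, prior odds 0.5
  r <- lls(pair_set(c("A", "A"), c("B", "C"), "E"), gs)
  expect_equal(r$pos_overlap, 1L)
  expect_equal(r$neg_overlap, 1L)
  expect_equal(r$prior_pos, 2L)
  expect_equal(r$prior_neg, 4)
  expect_equal(r$lls, log(2), tolerance = 1e-15)
  expect_equal(r$status, "scored")
})

test_that("discard and infinity statuses follow the stated rules", {
  gs <- toy_gs()
  # perfect overlap -> infinite
  r_inf <- lls(pair_set(c("A", "C"), c("B", "D"), "perfect"), gs)
  expect_equal(r_inf$status, "infinite")
  expect_true(is.infinite(r_inf$lls))
  # no pair in the universe -> no score
  r_out <- lls(pair_set("X", "Y", "out"), gs)
  expect_equal(r_out$status, "discarded_noscore")
  expect_equal(r_out$scoreable_pairs, 0L)
  # positive:negative ratio equal to the prior ratio -> lls 0, nonpositive
  # dataset {AB, AC, AD}: 1 pos, 2 neg; odds 0.5 == prior odds
  r_zero <- lls(pair_set(c("A", "A", "A"), c("B", "C", "D"), "flat"), gs)
  expect_equal(r_zero$lls, 0)
  expect_equal(r_zero$status, "discarded_nonpositive")
  # degenerate Gold Standard without negatives is rejected
  expect_error(lls(pair_set("A", "B"), build_gs_from_pairs(pair_set("A", "B"))),
               "negatives")
})

test_that("infinite scores are replaced by ceil(max finite) + 1 batch-wide", {
  res <- rbind(
    data.frame(dataset = "d1", klass = "htp_study", lls = 0.7, status = "scored",
               pos_overlap = 1, neg_overlap = 1, prior_pos = 1, prior_neg = 1,
               scoreable_pairs = 2),
    data.frame(dataset = "d2", klass = "htp_study", lls = 2.3, status = "scored",
               pos_overlap = 1, neg_overlap = 1, prior_pos = 1, prior_neg = 1,
               scoreable_pairs = 2),
    data.frame(dataset = "d3", klass = "ltp_type", lls = Inf, status = "infinite",
               pos_overlap = 1, neg_overlap = 0, prior_pos = 1, prior_neg = 1,
               scoreable_pairs = 1))
  fin <- finalize_scores(res)
  expect_equal(fin$score[fin$dataset == "d3"], ceiling(2.3) + 1)
  expect_equal(fin$dataset, c("d3", "d2", "d1"))  # sorted by score desc

  # no infinities: identity on scores
  fin2 <- finalize_scores(res[1:2, ])
  expect_equal(sort(fin2$score), sort(res$lls[1:2]))

  # all infinite: documented fallback score 1.0
  fin3 <- finalize_scores(res[3, ])
  expect_equal(fin3$score, 1.0)

  # all discarded: empty output with a warning
  resd <- res[1, ]; resd$status <- "discarded_noscore"
  expect_warning(fin4 <- finalize_scores(resd), "discarded")
  expect_equal(nrow(fin4), 0L)
})

test_that("scores equal the brute-force frequency-ratio oracle on random instances", {
  set.seed(3)
  for (rep in 1:50) {
    genes <- LETTERS[1:sample(4:8, 1)]
    gs_ps <- random_pair_set(genes, sample(3:10, 1), "gs")
    if (length(gs_ps) == 0 ||
        length(gs_ps) >= choose(length(pair_set_genes(gs_ps)), 2)) next
    gs <- build_gs_from_pairs(gs_ps)
    ds <- random_pair_set(LETTERS[1:10], sample(2:12, 1), "E")
    got <- lls(ds, gs)
    want <- oracle_lls(ds$keys, gs$universe, gs$positives)
    expect_equal(got$status, want$status)
    expect_equal(got$pos_overlap, want$pos)
    expect_equal(got$neg_overlap, want$neg)
    if (got$status %in% c("scored", "discarded_nonpositive")) {
      expect_equal(got$lls, want$lls, tolerance = 1e-12)
    }
  }
})

test_that("lls is invariant to gene relabelling, duplication and outside pairs", {
  set.seed(19)
  genes <- sprintf("g%d", 1:8)
  gs <- build_gs_from_pairs(random_pair_set(genes, 8, "gs"))
  ds_a <- sample(genes, 12, replace = TRUE)
  ds_b <- sample(genes, 12, replace = TRUE)
  base <- lls(pair_set(ds_a, ds_b, "E"), gs)

  # permutation equivariance: relabel genes consistently everywhere
  perm <- setNames(sprintf("h%d", sample(8)), genes)
  gs_p <- build_gs_from_pairs(pair_set(
    perm[pair_key_genes(gs$positives)[, 1]],
    perm[pair_key_genes(gs$positives)[, 2]], "gs"))
  rel <- lls(pair_set(perm[ds_a], perm[ds_b], "E"), gs_p)
  expect_equal(rel$lls, base$lls)
  expect_equal(rel$status, base$status)

  # pairs outside the universe change nothing
  plus_out <- lls(pair_set(c(ds_a, "zz1"), c(ds_b, "zz2"), "E"), gs)
  expect_equal(plus_out[, c("lls", "pos_overlap", "neg_overlap")],
               base[, c("lls", "pos_overlap", "neg_overlap")])

  # duplicating every pair changes nothing (unique pairs only)
  dup <- lls(pair_set(rep(ds_a, 2), rep(ds_b, 2), "E"), gs)
  expect_equal(dup$lls, base$lls)
})

test_that("more stringent priors raise the score, overlaps fixed", {
  for (prior_neg in c(10, 20, 50, 100)) {
    # same overlaps (3 pos, 5 neg), growing prior negative pool
    val <- log((3 / 5) / (4 / prior_neg))
    if (prior_neg > 10) expect_gt(val, prev)
    prev <- val
  }
  # and through the implementation: enlarge the universe with unlinked genes
  base_pairs <- pair_set(c("A", "C", "E"), c("B", "D", "F"), "gs")
  scores <- vapply(c(0, 3, 6), function(extra) {
    filler_a <- if (extra > 0) sprintf("z%d", seq_len(extra)) else character(0)
    gs <- build_gs_from_pairs(pair_set(
      c(c("A", "C", "E"), filler_a), c(c("B", "D", "F"), rep("A", extra)), "gs"))
    lls(pair_set(c("A", "C", "A"), c("B", "D", "D"), "E"), gs)$lls
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("two-stage scoring scores each LTP type against the others", {
  # smallest legal instance: 2 LTP types, no HTP
  t1 <- make_dataset(c("A", "C", "E"), c("B", "D", "F"), "Two-hybrid", "ltp_type")
  t2 <- make_dataset(c("A", "C", "A"), c("B", "D", "E"), "PCA", "ltp_type")
  sc <- ssnet_score(list(), list(t1, t2))
  # type 1 scored against GS(type 2) and vice versa
  gs2 <- build_gs_from_pairs(t2$pairs)
  gs1 <- build_gs_from_pairs(t1$pairs)
  raw <- sc$raw
  expect_equal(raw$lls[raw$dataset == "Two-hybrid"],
               lls(t1, gs2)$lls)
  expect_equal(raw$lls[raw$dataset == "PCA"],
               lls(t2, gs1)$lls)
  expect_error(ssnet_score(list(), list(t1)), "at least 2 LTP")
})

test_that("HTP and LTP infinity replacement shares one batch", {
  # HTP dataset with perfect LTP_GS overlap scores infinity and must exceed
  # the finite LTP scores from the same run
  t1 <- make_dataset(c("A", "C", "E", "A"), c("B", "D", "F", "D"),
                     "Two-hybrid", "ltp_type")
  t2 <- make_dataset(c("A", "C", "B"), c("B", "D", "C"), "PCA", "ltp_type")
  htp <- make_dataset(c("A", "C"), c("B", "D"), "Smith.1", "htp_study")
  sc <- ssnet_score(list(htp), list(t1, t2))
  s <- sc$scores
  if ("infinite" %in% s$status) {
    finite_max <- max(s$score[s$status != "infinite"])
    expect_equal(unique(s$score[s$status == "infinite"]),
                 ceiling(finite_max) + 1)
  }
  expect_true(all(s$score > 0))
})
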