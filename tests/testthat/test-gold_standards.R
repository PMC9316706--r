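test_that("pair-derived Gold Standard has the incident-gene universe", {
  gs <- build_gs_from_pairs(pair_set(c("A", "C"), c("B", "D")), "gs")
  expect_equal(gs$universe, c("A", "B", "C", "D"))
  expect_length(gs$positives, 2L)
  expect_equal(gs_n_negatives(gs), 4)  # C(4,2) - 2

  single <- build_gs_from_pairs(pair_set("A", "B"))
  expect_length(single$positives, 1L)
  expect_equal(gs_n_negatives(single), 0)

  expect_error(build_gs_from_pairs(pair_set(character(0), character(0))),
               "empty")
})

test_that("pathway Gold Standard is the union of within-pathway complete graphs", {
  m1 <- data.frame(gene = c("A", "B", "C"), pathway = "p1")
  gs1 <- build_pathway_gs(m1)
  expect_setequal(gs1$positives, c("A\tB", "A\tC", "B\tC"))

  m2 <- data.frame(gene = c("A", "B", "C", "D", "E"),
                   pathway = c("p1", "p1", "p2", "p2", "p2"))
  expect_length(build_pathway_gs(m2)$positives, 1L + 3L)

  # brute force on random membership
  set.seed(21)
  memb <- data.frame(gene = sprintf("g%03d", 1:100),
                     pathway = sample(sprintf("pw%02d", 1:10), 100, replace = TRUE))
  gs <- build_pathway_gs(memb)
  brute <- 0L
  for (i in 1:99) for (j in (i + 1):100) {
    if (memb$pathway[i] == memb$pathway[j]) brute <- brute + 1L
  }
  expect_length(gs$positives, brute)
})

test_that("genes in several pathways contribute all cross-memberships once", {
  memb <- data.frame(gene = c("A", "B", "A", "C"),
                     pathway = c("p1", "p1", "p2", "p2"))
  gs <- build_pathway_gs(memb)
  expect_setequal(gs$positives, c("A\tB", "A\tC"))
})

# --- ontology fixtures -------------------------------------------------------

write_toy_obo <- function(extra = character(0)) {
  f <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: mid a", "namespace: biological_process",
    "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: mid b", "namespace: biological_process",
    "relationship: part_of GO:1 ! root", "",
    "[Term]", "id: GO:4", "name: leaf", "namespace: biological_process",
    "is_a: GO:2 ! mid a", "is_a: GO:3 ! mid b", "",
    "[Term]", "id: GO:5", "name: dead", "namespace: biological_process",
    "is_obsolete: true", "",
    "[Term]", "id: GO:9", "name: other aspect", "namespace: molecular_function", "",
    extra), f)
  f
}

write_toy_gaf <- function(rows) {
  f <- tempfile(fileext = ".gaf")
  lines <- c("!gaf-version: 2.1",
             vapply(rows, function(r) {
               paste(c("DB", r$gene, r$gene, r$qual %||% "", r$term, "REF",
                       r$ev %||% "IDA", "", "P", "", "", "protein",
                       "taxon:559292", "20200101", "DB", "", ""),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, f)
  f
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("annotations propagate to all ancestors over is_a and part_of", {
  obo <- read_obo(write_toy_obo())
  gaf <- read_gaf(write_toy_gaf(list(list(gene = "g1", term = "GO:4"))))
  ann <- propagate_annotations(obo, gaf)
  expect_setequal(ann$gene_terms$g1, c("GO:4", "GO:2", "GO:3", "GO:1"))
})

test_that("NOT-qualified, IEA, obsolete and off-namespace rows are excluded", {
  obo <- read_obo(write_toy_obo())
  gaf <- read_gaf(write_toy_gaf(list(
    list(gene = "g1", term = "GO:2", qual = "NOT"),
    list(gene = "g2", term = "GO:2", ev = "IEA"),
    list(gene = "g3", term = "GO:5"),
    list(gene = "g4", term = "GO:9"),
    list(gene = "g5", term = "GO:2"))))
  ann <- propagate_annotations(obo, gaf, exclude_iea = TRUE)
  expect_equal(names(ann$gene_terms), "g5")
  # IEA kept when not excluded
  ann2 <- propagate_annotations(obo, gaf, exclude_iea = FALSE)
  expect_setequal(names(ann2$gene_terms), c("g2", "g5"))
})

test_that("unknown terms are skipped with a message, cycles are fatal", {
  obo <- read_obo(write_toy_obo())
  gaf <- read_gaf(write_toy_gaf(list(list(gene = "g1", term = "GO:999"),
                                     list(gene = "g1", term = "GO:2"))))
  expect_message(ann <- propagate_annotations(obo, gaf), "unknown")
  expect_equal(ann$skipped_unknown_terms, 1L)

  cyc <- write_toy_obo(c("[Term]", "id: GO:7", "name: c1",
                         "namespace: biological_process", "is_a: GO:8", "",
                         "[Term]", "id: GO:8", "name: c2",
                         "namespace: biological_process", "is_a: GO:7", ""))
  expect_error(propagate_annotations(read_obo(cyc), gaf), "cycle")
})

test_that("propagated term counts match brute-force transitive closure", {
  # 10-term random DAG (edges only from higher to lower index), 20 GAF rows
  set.seed(17)
  terms <- sprintf("GO:%02d", 1:10)
  parent_of <- lapply(2:10, function(i) {
    sample(terms[1:(i - 1)], min(i - 1, sample(1:2, 1)))
  })
  stanza <- c("format-version: 1.2", "")
  for (i in 1:10) {
    stanza <- c(stanza, "[Term]", paste0("id: ", terms[i]),
                paste0("name: t", i), "namespace: biological_process",
                if (i > 1) paste0("is_a: ", parent_of[[i - 1]]), "")
  }
  f <- tempfile(); writeLines(stanza, f)
  obo <- read_obo(f)

  genes <- sprintf("g%02d", 1:8)
  rows <- lapply(1:20, function(i) {
    list(gene = sample(genes, 1), term = sample(terms, 1))
  })
  ann <- propagate_annotations(obo, read_gaf(write_toy_gaf(rows)))

  # oracle: reflexive-transitive closure by repeated parent lookup
  closure <- function(t) {
    out <- t
    repeat {
      ps <- unlist(lapply(out, function(x) {
        i <- match(x, terms)
        if (i > 1) parent_of[[i - 1]] else character(0)
      }))
      new <- union(out, ps)
      if (length(new) == length(out)) return(out)
      out <- new
    }
  }
  direct <- lapply(split(vapply(rows, `[[`, character(1), "term"),
                         vapply(rows, `[[`, character(1), "gene")),
                   function(ts) unique(unlist(lapply(unique(ts), closure))))
  for (g in names(direct)) {
    expect_setequal(ann$gene_terms[[g]], direct[[g]])
  }
  brute_counts <- table(unlist(direct))
  expect_equal(ann$term_counts[names(brute_counts)],
               setNames(as.integer(brute_counts), names(brute_counts)))
})

test_that("GO-process Gold Standard respects eligibility modes and limits", {
  # 10-gene genome; term t.big annotates all, t.a {A,B,C}, t.b {C,D}
  genes <- LETTERS[1:10]
  gene_terms <- setNames(lapply(genes, function(g) {
    ts <- "t.big"
    if (g %in% c("A", "B", "C")) ts <- c(ts, "t.a")
    if (g %in% c("C", "D")) ts <- c(ts, "t.b")
    ts
  }), genes)
  ann <- make_annset(gene_terms)

  gs <- build_go_bp_gs(ann, mode = "fraction", limit = 0.10, genome_size = 10)
  expect_length(gs$positives, 0L)  # 3/10 and 2/10 >= 0.10? no: only t.big excluded
  gs <- build_go_bp_gs(ann, mode = "fraction", limit = 0.35, genome_size = 10)
  expect_setequal(gs$positives, c("A\tB", "A\tC", "B\tC", "C\tD"))
  expect_setequal(gs$universe, c("A", "B", "C", "D"))

  gs100 <- build_go_bp_gs(ann, mode = "count", limit = 4)
  expect_setequal(gs100$positives, c("A\tB", "A\tC", "B\tC", "C\tD"))
  # larger limit admits more terms -> superset of positives
  gs_all <- build_go_bp_gs(ann, mode = "count", limit = 100)
  expect_true(all(gs100$positives %in% gs_all$positives))
  expect_length(gs_all$positives, choose(10, 2))
})

test_that("co-annotation positives match brute-force enumeration", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:40)
  terms <- sprintf("t%02d", 1:12)
  gene_terms <- setNames(lapply(genes, function(g) {
    sample(terms, sample(1:4, 1))
  }), genes)
  ann <- make_annset(gene_terms)
  limit <- 10
  gs <- build_go_bp_gs(ann, mode = "count", limit = limit)

  eligible <- names(ann$term_counts)[ann$term_counts < limit]
  brute <- character(0)
  for (i in 1:39) for (j in (i + 1):40) {
    shared <- intersect(gene_terms[[genes[i]]], gene_terms[[genes[j]]])
    if (any(shared %in% eligible)) {
      brute <- c(brute, paste(sort(c(genes[i], genes[j])), collapse = "\t"))
    }
  }
  expect_setequal(gs$positives, brute)
})
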