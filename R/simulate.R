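# Synthetic interactome generator with planted ground truth. Genes are
# partitioned into functional modules; each simulated study samples pairs
# within modules with its true-positive fraction and across modules
# otherwise (noise). Each module maps to one ontology term and one pathway,
# so every pipeline stage — parsing, partitioning, scoring, integration,
# evaluation, clustering — can be exercised against known truth without
# external downloads.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 200 genes in 10
#' equal modules; three high-throughput studies of 150-400 unique pairs with
#' true-positive fractions 0.9, 0.5 and 0.1 (high-throughput screens span a
#' wide quality range); 150 low-throughput studies of 5-40 pairs at 0.95
#' (targeted studies are near-clean) spread over four experimental types, so
#' the pooled low-throughput data covers most of the within-module pair
#' space — the accumulation of targeted data that makes it usable as an
#' internal Gold Standard.
#'
#' @param n_genes number of genes.
#' @param n_modules number of functional modules (genes split evenly).
#' @param n_htp_studies number of high-throughput studies.
#' @param htp_tp_fraction per-study probability that a sampled pair is
#'   within-module (recycled to `n_htp_studies`).
#' @param htp_size_range range of unique-pair counts per HTP study.
#' @param n_ltp_studies number of low-throughput studies.
#' @param ltp_tp_fraction within-module probability for LTP studies.
#' @param ltp_size_range range of unique-pair counts per LTP study (keep the
#'   maximum below the split threshold).
#' @param ltp_types experimental-system labels cycled over LTP studies.
#' @param organism taxon id written to the interaction file.
#' @param seed RNG seed; the same seed yields byte-identical output files.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_modules = 10,
                       n_htp_studies = 3,
                       htp_tp_fraction = c(0.9, 0.5, 0.1),
                       htp_size_range = c(150, 400),
                       n_ltp_studies = 150,
                       ltp_tp_fraction = 0.95,
                       ltp_size_range = c(5, 40),
                       ltp_types = c("Two-hybrid", "Affinity Capture-MS",
                                     "Reconstituted Complex", "Synthetic Lethality"),
                       organism = "559292",
                       seed = 42) {
  stopifnot(n_genes >= 2 * n_modules, n_modules >= 1,
            all(htp_tp_fraction >= 0 & htp_tp_fraction <= 1),
            ltp_tp_fraction >= 0, ltp_tp_fraction <= 1,
            htp_size_range[1] <= htp_size_range[2],
            ltp_size_range[1] <= ltp_size_range[2])
  htp_tp_fraction <- rep_len(htp_tp_fraction, n_htp_studies)
  structure(
    list(n_genes = n_genes, n_modules = n_modules,
         n_htp_studies = n_htp_studies, htp_tp_fraction = htp_tp_fraction,
         htp_size_range = htp_size_range,
         n_ltp_studies = n_ltp_studies, ltp_tp_fraction = ltp_tp_fraction,
         ltp_size_range = ltp_size_range, ltp_types = ltp_types,
         organism = organism, seed = seed),
    class = "sim_config"
  )
}

# Sample `size` unique pairs for one study: a binomially-rounded quota of
# within-module pairs (the study's true-positive fraction of its size) drawn
# without replacement from the within-module pair pool, the rest unique
# cross-module pairs. The emitted unique-pair within fraction therefore
# equals the configured fraction up to rounding, not just in expectation.
.sample_study_pairs <- function(genes, module_of, size, tp_fraction) {
  within_pool <- unlist(lapply(split(genes, module_of), function(g) {
    if (length(g) < 2) return(character(0))
    cmb <- utils::combn(sort(g), 2)
    pair_key(cmb[1, ], cmb[2, ])
  }), use.names = FALSE)
  n_total <- choose(length(genes), 2)
  if (size > n_total) stop("study size ", size, " exceeds available unique pairs")

  n_within <- round(size * tp_fraction)
  n_cross <- size - n_within
  n_cross_avail <- n_total - length(within_pool)
  if (n_within > length(within_pool) || n_cross > n_cross_avail) {
    stop("cannot sample ", size, " unique pairs at within fraction ",
         tp_fraction, " (infeasible config)")
  }
  within <- sample(within_pool, n_within)

  cross <- character(0)
  while (length(cross) < n_cross) {
    a <- sample(genes, 2 * (n_cross - length(cross) + 5), replace = TRUE)
    b <- sample(genes, length(a), replace = TRUE)
    ok <- module_of[match(a, genes)] != module_of[match(b, genes)]
    cross <- unique(c(cross, pair_key(a[ok], b[ok])))
  }
  cross <- cross[seq_len(n_cross)]
  sample(c(within, cross))
}

#' Generate a synthetic interactome with planted ground truth
#'
#' Writes a BioGRID-style TAB3 interaction archive, a GAF annotation file, an
#' OBO ontology (one term per module under a small shared ancestor DAG), a
#' two-column pathway membership table and a JSON truth record into `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list of class `sim_result`: file paths (`interactions`, `gaf`,
#'   `obo`, `pathways`, `truth_json`) and the in-memory `truth` record (module
#'   membership, per-study class/type/size/quality, config echo).
#' @export
simulate_interactome <- function(config = sim_config(), dir = tempfile("sim")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  genes <- sprintf("YG%04dW", seq_len(config$n_genes))
  module_of <- rep_len(seq_len(config$n_modules), config$n_genes)
  module_of <- sort(module_of)

  phys <- c("Two-hybrid", "Affinity Capture-MS", "Reconstituted Complex",
            "Affinity Capture-Western", "PCA", "Co-fractionation")
  sys_type <- function(sys) ifelse(sys %in% phys, "physical", "genetic")

  studies <- list()
  # HTP studies
  htp_sizes <- sample(seq(config$htp_size_range[1], config$htp_size_range[2]),
                      config$n_htp_studies, replace = TRUE)
  for (i in seq_len(config$n_htp_studies)) {
    keys <- .sample_study_pairs(genes, module_of, htp_sizes[i],
                                config$htp_tp_fraction[i])
    studies[[length(studies) + 1L]] <- list(
      pubmed = sprintf("%d", 1000000L + i),
      author = sprintf("Htpauthor%d A (2020)", i),
      system = "Affinity Capture-MS", klass = "htp",
      tp_fraction = config$htp_tp_fraction[i], keys = keys)
  }
  # LTP studies
  ltp_sizes <- sample(seq(config$ltp_size_range[1], config$ltp_size_range[2]),
                      config$n_ltp_studies, replace = TRUE)
  types <- rep_len(config$ltp_types, config$n_ltp_studies)
  for (i in seq_len(config$n_ltp_studies)) {
    keys <- .sample_study_pairs(genes, module_of, ltp_sizes[i],
                                config$ltp_tp_fraction)
    studies[[length(studies) + 1L]] <- list(
      pubmed = sprintf("%d", 2000000L + i),
      author = sprintf("Ltpauthor%d B (2019)", i),
      system = types[i], klass = "ltp",
      tp_fraction = config$ltp_tp_fraction, keys = keys)
  }

  records <- do.call(rbind, lapply(studies, function(s) {
    g <- pair_key_genes(s$keys)
    data.frame(gene_a = g[, 1], gene_b = g[, 2],
               experimental_system = s$system,
               system_type = sys_type(s$system),
               author = s$author, pubmed_id = s$pubmed,
               organism_a = config$organism, organism_b = config$organism,
               stringsAsFactors = FALSE)
  }))

  paths <- list(
    interactions = file.path(dir, "interactions.tab3.txt"),
    gaf = file.path(dir, "annotations.gaf"),
    obo = file.path(dir, "ontology.obo"),
    pathways = file.path(dir, "pathways.tsv"),
    truth_json = file.path(dir, "truth.json")
  )
  write_biogrid(records, paths$interactions, dialect = "tab3")

  # ontology: root <- 2 branch terms <- module terms
  root <- "GO:0008150"
  branch <- c("GO:2000001", "GO:2000002")
  mod_terms <- sprintf("GO:10%05d", seq_len(config$n_modules))
  obo <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", root), "name: biological_process",
           "namespace: biological_process", "")
  for (j in seq_along(branch)) {
    obo <- c(obo, "[Term]", paste0("id: ", branch[j]),
             sprintf("name: branch process %d", j),
             "namespace: biological_process",
             paste0("is_a: ", root, " ! biological_process"), "")
  }
  for (m in seq_len(config$n_modules)) {
    obo <- c(obo, "[Term]", paste0("id: ", mod_terms[m]),
             sprintf("name: module %d process", m),
             "namespace: biological_process",
             paste0("is_a: ", branch[(m %% 2) + 1L], " ! branch"), "")
  }
  writeLines(obo, paths$obo)

  gaf_row <- function(gene, term) {
    paste(c("SSIM", gene, gene, "", term, "SIM:0000001", "IDA", "", "P",
            gene, "", "protein", paste0("taxon:", config$organism),
            "20200101", "SSIM", "", ""), collapse = "\t")
  }
  gaf <- c("!gaf-version: 2.1",
           vapply(seq_along(genes), function(i) {
             gaf_row(genes[i], mod_terms[module_of[i]])
           }, character(1)))
  writeLines(gaf, paths$gaf)

  utils::write.table(
    data.frame(gene = genes, pathway = sprintf("PW%03d", module_of)),
    paths$pathways, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    modules = stats::setNames(as.list(module_of), genes),
    studies = lapply(studies, function(s) {
      list(pubmed = s$pubmed, author = s$author, system = s$system,
           klass = s$klass, tp_fraction = s$tp_fraction,
           n_pairs = length(s$keys))
    }),
    module_terms = mod_terms,
    config = unclass(config)
  )
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE, digits = NA)

  structure(c(paths, list(truth = truth, dir = dir)), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result in %s: %d studies over %d genes\n", x$dir,
              length(x$truth$studies), length(x$truth$modules)))
  invisible(x)
}
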