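# BioGRID tab-format readers. Two dialects are supported: TAB2 (the classic
# 24-column format) and TAB3 (the current format; organism columns renamed and
# a Publication Source column added). Columns are located by header name, so
# extra columns are tolerated.

.tab2_cols <- c(
  gene_a  = "Systematic Name Interactor A",
  gene_b  = "Systematic Name Interactor B",
  system  = "Experimental System",
  type    = "Experimental System Type",
  author  = "Author",
  pubmed  = "Pubmed ID",
  org_a   = "Organism Interactor A",
  org_b   = "Organism Interactor B"
)

.tab3_cols <- c(
  gene_a  = "Systematic Name Interactor A",
  gene_b  = "Systematic Name Interactor B",
  system  = "Experimental System",
  type    = "Experimental System Type",
  author  = "Author",
  pubmed  = "Publication Source",
  org_a   = "Organism ID Interactor A",
  org_b   = "Organism ID Interactor B"
)

# Controlled vocabulary of BioGRID experimental system names. Used for
# validation of generated fixtures; real archives may add systems, so unknown
# names are kept with a warning counter rather than dropped.
.biogrid_systems <- c(
  "Affinity Capture-MS", "Affinity Capture-RNA", "Affinity Capture-Western",
  "Affinity Capture-Luminescence", "Biochemical Activity", "Co-crystal Structure",
  "Co-fractionation", "Co-localization", "Co-purification", "Far Western",
  "FRET", "PCA", "Protein-peptide", "Protein-RNA", "Proximity Label-MS",
  "Reconstituted Complex", "Two-hybrid", "Dosage Growth Defect",
  "Dosage Lethality", "Dosage Rescue", "Negative Genetic", "Phenotypic Enhancement",
  "Phenotypic Suppression", "Positive Genetic", "Synthetic Growth Defect",
  "Synthetic Haploinsufficiency", "Synthetic Lethality", "Synthetic Rescue"
)

#' Parse a BioGRID tab-delimited interaction archive
#'
#' Reads a TAB2 or TAB3 archive into canonical interaction records. Gene
#' identity uses the systematic-name column; an optional two-column mapping
#' table can translate identifiers first. Rows with a missing identifier
#' (`-` or empty) for either interactor are dropped and counted; when an
#' organism filter is given, rows where either interactor belongs to another
#' taxon are excluded.
#'
#' @param path path to the tab-delimited file (plain text; `#`-prefixed header
#'   is accepted).
#' @param dialect `"tab3"` (default) or `"tab2"`.
#' @param organism optional taxon identifier (e.g. `"559292"`); keep only rows
#'   where both interactors match.
#' @param id_map optional data.frame with columns `from`, `to` mapping external
#'   identifiers onto the canonical key.
#' @return A list of class `biogrid_parse` with elements `records` (data.frame
#'   with columns `gene_a`, `gene_b`, `experimental_system`, `system_type`,
#'   `author`, `pubmed_id`, `organism_a`, `organism_b`) and `report` (named
#'   counts of kept and dropped rows by reason).
#' @examples
#' f <- tempfile(fileext = ".tab3.txt")
#' write_biogrid(data.frame(gene_a = "YAL001C", gene_b = "YBR001C",
#'                          experimental_system = "Two-hybrid",
#'                          system_type = "physical", author = "Smith J (2020)",
#'                          pubmed_id = "1", organism_a = "559292",
#'                          organism_b = "559292"), f)
#' parse_biogrid(f)$records
#' @export
parse_biogrid <- function(path, dialect = c("tab3", "tab2"), organism = NULL,
                          id_map = NULL) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "tab3") .tab3_cols else .tab2_cols
  if (!file.exists(path)) stop("file not found: ", path)

  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  # BioGRID headers begin "#BioGRID Interaction ID"; strip the leading '#'.
  names(raw)[1] <- sub("^#", "", names(raw)[1])
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("not a ", dialect, " file; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }

  rec <- data.frame(
    gene_a = raw[[cols["gene_a"]]],
    gene_b = raw[[cols["gene_b"]]],
    experimental_system = raw[[cols["system"]]],
    system_type = raw[[cols["type"]]],
    author = raw[[cols["author"]]],
    pubmed_id = raw[[cols["pubmed"]]],
    organism_a = raw[[cols["org_a"]]],
    organism_b = raw[[cols["org_b"]]],
    stringsAsFactors = FALSE
  )
  # TAB3 Publication Source is "PUBMED:123"; normalise to the bare id.
  rec$pubmed_id <- sub("^PUBMED:", "", rec$pubmed_id)

  n_input <- nrow(rec)
  if (!is.null(id_map)) {
    stopifnot(all(c("from", "to") %in% names(id_map)))
    ia <- match(rec$gene_a, id_map$from)
    ib <- match(rec$gene_b, id_map$from)
    rec$gene_a[!is.na(ia)] <- id_map$to[ia[!is.na(ia)]]
    rec$gene_b[!is.na(ib)] <- id_map$to[ib[!is.na(ib)]]
  }

  bad_id <- rec$gene_a %in% c("", "-") | rec$gene_b %in% c("", "-") |
    is.na(rec$gene_a) | is.na(rec$gene_b)
  dropped_missing_id <- sum(bad_id)
  rec <- rec[!bad_id, , drop = FALSE]

  dropped_organism <- 0L
  if (!is.null(organism)) {
    keep <- rec$organism_a == as.character(organism) &
      rec$organism_b == as.character(organism)
    dropped_organism <- sum(!keep)
    rec <- rec[keep, , drop = FALSE]
  }

  unknown_system <- sum(!rec$experimental_system %in% .biogrid_systems)
  if (unknown_system > 0) {
    warning(unknown_system, " rows use experimental systems outside the ",
            "known BioGRID vocabulary (kept)")
  }
  rownames(rec) <- NULL

  structure(
    list(records = rec,
         report = list(
           input_rows = n_input,
           kept = nrow(rec),
           dropped_missing_id = dropped_missing_id,
           dropped_organism = dropped_organism,
           unknown_system = unknown_system,
           dialect = dialect)),
    class = "biogrid_parse"
  )
}

#' @export
print.biogrid_parse <- function(x, ...) {
  cat(sprintf("BioGRID %s parse: %d/%d rows kept (%d missing id, %d other-organism)\n",
              x$report$dialect, x$report$kept, x$report$input_rows,
              x$report$dropped_missing_id, x$report$dropped_organism))
  invisible(x)
}

#' Write interaction records as a BioGRID-format file
#'
#' Emits a minimal but dialect-conformant tab-delimited archive readable by
#' [parse_biogrid()]; used by the fixture generator and for round-tripping
#' subsets of parsed data.
#'
#' @param records data.frame with the columns produced by [parse_biogrid()].
#' @param path output file path.
#' @param dialect `"tab3"` (default) or `"tab2"`.
#' @return `path`, invisibly.
#' @export
write_biogrid <- function(records, path, dialect = c("tab3", "tab2")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "tab3") .tab3_cols else .tab2_cols
  out <- data.frame(
    id = seq_len(nrow(records)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- "#BioGRID Interaction ID"
  pub <- records$pubmed_id
  if (dialect == "tab3") pub <- paste0("PUBMED:", pub)
  out[[cols["gene_a"]]] <- records$gene_a
  out[[cols["gene_b"]]] <- records$gene_b
  out[[cols["system"]]] <- records$experimental_system
  out[[cols["type"]]] <- records$system_type
  out[[cols["author"]]] <- records$author
  out[[cols["pubmed"]]] <- pub
  out[[cols["org_a"]]] <- records$organism_a
  out[[cols["org_b"]]] <- records$organism_b
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
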