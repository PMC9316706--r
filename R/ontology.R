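# Minimal OBO and GAF readers plus true-path annotation propagation.
# Only the fields the method needs are read: term ids, names, namespaces,
# obsoletion flags and the is_a / part_of hierarchy.

#' Read an OBO 1.2/1.4 ontology file
#'
#' Parses `[Term]` stanzas into a term table and a child-to-parent edge list
#' over the `is_a` and `part_of` relations. Alternate ids and all other
#' relationship types are ignored.
#'
#' @param path path to an OBO file.
#' @return list of class `obo_ontology`: `terms` (data.frame: `id`, `name`,
#'   `namespace`, `obsolete`) and `edges` (data.frame: `child`, `parent`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  is_term <- lines[starts] == "[Term]"
  ends <- c(starts[-1] - 1L, length(lines))

  ids <- character(0); names_ <- character(0); ns <- character(0)
  obs <- logical(0); child <- character(0); parent <- character(0)
  for (k in which(is_term)) {
    block <- lines[starts[k]:ends[k]]
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ": *"), "", grep(paste0("^", tag, ":"), block, value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    ns <- c(ns, get1("namespace"))
    obs <- c(obs, identical(get1("is_obsolete"), "true"))
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
    po <- grep("^relationship: part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: part_of *", "", po))
    par <- c(isa, po)
    child <- c(child, rep(id, length(par)))
    parent <- c(parent, par)
  }
  terms <- data.frame(id = ids, name = names_, namespace = ns,
                      obsolete = obs, stringsAsFactors = FALSE)
  edges <- data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  # drop edges out of the declared term set (dangling references)
  edges <- edges[edges$parent %in% terms$id & edges$child %in% terms$id, , drop = FALSE]
  structure(list(terms = terms, edges = edges), class = "obo_ontology")
}

#' @export
print.obo_ontology <- function(x, ...) {
  cat(sprintf("obo_ontology: %d terms (%d obsolete), %d is_a/part_of edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

#' Read a GAF 2.1/2.2 annotation file
#'
#' @param path path to a GAF file (`!` comment lines skipped).
#' @param id_column which column identifies the gene: `"symbol"` (column 3,
#'   default) or `"id"` (column 2).
#' @return data.frame with columns `gene`, `qualifier`, `term`, `evidence`,
#'   `aspect`.
#' @export
read_gaf <- function(path, id_column = c("symbol", "id")) {
  id_column <- match.arg(id_column)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene = character(0), qualifier = character(0),
                      term = character(0), evidence = character(0),
                      aspect = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else "", character(1))
  data.frame(
    gene = col(if (id_column == "symbol") 3L else 2L),
    qualifier = col(4L),
    term = col(5L),
    evidence = col(7L),
    aspect = col(9L),
    stringsAsFactors = FALSE
  )
}

# ancestor sets (excluding the term itself) for every term, by memoised DFS
.term_ancestors <- function(ontology) {
  parents <- split(ontology$edges$parent, ontology$edges$child)
  anc <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    p <- parents[[t]]
    res <- if (is.null(p)) character(0) else {
      unique(c(p, unlist(lapply(p, get_anc), use.names = FALSE)))
    }
    anc[[t]] <- res
    res
  }
  out <- lapply(ontology$terms$id, get_anc)
  names(out) <- ontology$terms$id
  out
}

#' Propagate GO annotations up the ontology (true-path rule)
#'
#' Builds per-gene annotation sets closed under `is_a`/`part_of` ancestry,
#' restricted to one namespace. Rows with a `NOT` qualifier, obsolete terms,
#' terms outside the ontology (logged, skipped) and — optionally — IEA
#' evidence are excluded. Per-term genome counts are computed after
#' propagation.
#'
#' @param ontology an `obo_ontology` from [read_obo()].
#' @param annotations a GAF data.frame from [read_gaf()].
#' @param namespace ontology namespace to keep (default
#'   `"biological_process"`).
#' @param exclude_iea drop rows with evidence code IEA (default `TRUE`).
#' @return list of class `annotation_set`: `gene_terms` (named list:
#'   gene -> character vector of term ids), `term_counts` (named integer:
#'   term -> number of annotated genes), `namespace`, `exclude_iea`,
#'   `skipped_unknown_terms` count.
#' @export
propagate_annotations <- function(ontology, annotations,
                                  namespace = "biological_process",
                                  exclude_iea = TRUE) {
  g <- igraph::graph_from_data_frame(ontology$edges[, c("child", "parent")],
                                     vertices = ontology$terms$id)
  if (igraph::ecount(g) > 0 && !igraph::is_dag(g)) {
    stop("ontology contains a cycle over is_a/part_of")
  }

  keep_terms <- ontology$terms$id[!ontology$terms$obsolete &
                                    ontology$terms$namespace == namespace]
  ann <- annotations
  ann <- ann[!grepl("NOT", ann$qualifier), , drop = FALSE]
  if (exclude_iea) ann <- ann[ann$evidence != "IEA", , drop = FALSE]
  unknown <- !(ann$term %in% ontology$terms$id)
  n_unknown <- sum(unknown)
  if (n_unknown > 0) {
    message(n_unknown, " annotation rows reference unknown terms; skipped")
    ann <- ann[!unknown, , drop = FALSE]
  }
  ann <- ann[ann$term %in% keep_terms, , drop = FALSE]

  anc <- .term_ancestors(ontology)
  gene_terms <- lapply(split(ann$term, ann$gene), function(ts) {
    ts <- unique(ts)
    all_t <- unique(c(ts, unlist(anc[ts], use.names = FALSE)))
    # propagation can reach terms of other namespaces only if edges cross
    # namespaces; restrict to the requested one
    intersect(all_t, keep_terms)
  })

  counts <- table(unlist(gene_terms, use.names = FALSE))
  term_counts <- stats::setNames(as.integer(counts), names(counts))

  structure(
    list(gene_terms = gene_terms, term_counts = term_counts,
         namespace = namespace, exclude_iea = exclude_iea,
         skipped_unknown_terms = n_unknown),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set (%s%s): %d genes, %d terms\n",
              x$namespace, if (x$exclude_iea) ", IEA excluded" else "",
              length(x$gene_terms), length(x$term_counts)))
  invisible(x)
}
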