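#' @keywords internal
"_PACKAGE"

# Unordered gene pairs are represented throughout as canonical string keys
# "lo\thi" with lo < hi (lexicographic). Self-pairs are never keyed.

#' Canonical keys for unordered gene pairs
#'
#' @param a,b character vectors of gene identifiers (recycled to common length).
#' @return character vector of keys; `NA` where `a == b` (self-pair).
#' @keywords internal
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  out <- paste(lo, hi, sep = "\t")
  out[a == b] <- NA_character_
  out
}

#' Split pair keys back into a two-column character matrix
#' @param keys character vector of pair keys.
#' @keywords internal
pair_key_genes <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  }
  m <- matrix(unlist(strsplit(keys, "\t", fixed = TRUE)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("a", "b")
  m
}

#' Construct a pair set
#'
#' A `pair_set` is a named set of unique unordered gene pairs with per-pair
#' multiplicity (how many source records collapsed into each pair).
#' Self-interactions are dropped; `(a,b)` and `(b,a)` are one element.
#'
#' @param a,b character vectors of interactor identifiers.
#' @param name dataset name.
#' @return object of class `pair_set`: fields `name`, `keys` (unique pair
#'   keys), `mult` (integer multiplicity aligned with `keys`).
#' @export
pair_set <- function(a, b, name = "") {
  keys <- pair_key(a, b)
  keys <- keys[!is.na(keys)]
  tab <- table(keys)
  structure(
    list(name = name,
         keys = names(tab),
         mult = as.integer(tab)),
    class = "pair_set"
  )
}

#' @export
length.pair_set <- function(x) length(x$keys)

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set '%s': %d unique pairs, %d genes, %d source records\n",
              x$name, length(x$keys), length(pair_set_genes(x)), sum(x$mult)))
  invisible(x)
}

#' Genes incident to any pair of a pair set
#' @param ps a `pair_set`.
#' @return sorted character vector of unique gene identifiers.
#' @export
pair_set_genes <- function(ps) {
  sort(unique(as.vector(pair_key_genes(ps$keys))))
}

#' Union of several pair sets
#' @param sets list of `pair_set` objects.
#' @param name name for the union.
#' @return a `pair_set`; multiplicities are summed across sets.
#' @export
pair_set_union <- function(sets, name = "union") {
  keys <- unlist(lapply(sets, `[[`, "keys"), use.names = FALSE)
  mult <- unlist(lapply(sets, `[[`, "mult"), use.names = FALSE)
  agg <- tapply(mult, keys, sum)
  structure(
    list(name = name, keys = names(agg), mult = as.integer(agg)),
    class = "pair_set"
  )
}

#' Convert interaction records to a pair set
#'
#' Collapses curated interaction rows to unique unordered gene pairs:
#' self-interactions are removed, duplicates (including swapped orientation
#' and repeat observations under different experimental systems) collapse to
#' one element with the multiplicity recorded.
#'
#' @param records data.frame of interaction records from [parse_biogrid()].
#' @param name dataset name.
#' @return a [pair_set()].
#' @export
to_pair_set <- function(records, name = "") {
  if (nrow(records) == 0L) return(pair_set(character(0), character(0), name))
  pair_set(records$gene_a, records$gene_b, name)
}
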