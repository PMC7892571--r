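#' IUPAC degeneracy algebra
#'
#' Utilities for the 15-letter IUPAC nucleotide ambiguity alphabet:
#' expanding a symbol to its base set, collapsing a base set to its symbol,
#' and counting the unambiguous expansions of a degenerate sequence.
#'
#' @name iupac
NULL

# symbol -> sorted base string, e.g. R -> "AG" (the standard 15-letter map)
.iupac_map <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  vapply(m, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
})
.iupac_rev <- local({
  r <- names(.iupac_map)
  names(r) <- .iupac_map
  r
})

.norm_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

.check_iupac <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% names(.iupac_map))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC character '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(chars)
}

#' Expand an IUPAC symbol to its base set
#'
#' @param symbol A single IUPAC nucleotide letter (one of the 15 symbols
#'   `A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`; `U` and lowercase accepted).
#' @return Character vector of unambiguous bases, sorted (subset of A,C,G,T).
#' @examples
#' iupac_expand("R") # A G
#' iupac_expand("N") # A C G T
#' @seealso [iupac_union()], [degeneracy()]
#' @export
iupac_expand <- function(symbol) {
  stopifnot(length(symbol) == 1L)
  symbol <- .norm_seq(symbol)
  if (!symbol %in% names(.iupac_map)) {
    stop(sprintf("'%s' is not a valid IUPAC nucleotide symbol", symbol),
         call. = FALSE)
  }
  strsplit(.iupac_map[[symbol]], "")[[1]]
}

#' Collapse a base set to its IUPAC symbol
#'
#' Inverse of [iupac_expand()]: `iupac_union(iupac_expand(s)) == s` for all
#' 15 symbols.
#'
#' @param bases Non-empty character vector, a subset of `c("A","C","G","T")`
#'   (duplicates allowed and ignored).
#' @return A single IUPAC letter.
#' @examples
#' iupac_union(c("A", "G")) # "R"
#' iupac_union(c("A", "T")) # "W"
#' @export
iupac_union <- function(bases) {
  bases <- unique(.norm_seq(bases))
  if (length(bases) == 0L) stop("empty base set", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("base set must be a subset of {A,C,G,T}, got: ",
         paste(bases, collapse = ","), call. = FALSE)
  }
  .iupac_rev[[paste(sort(bases), collapse = "")]]
}

#' Degeneracy of an IUPAC sequence
#'
#' The number of distinct unambiguous sequences encoded by a degenerate
#' sequence: the product over positions of the expansion sizes.
#'
#' @param seq A single IUPAC nucleotide string.
#' @return Integer-valued numeric (can exceed `.Machine$integer.max` for
#'   heavily degenerate sequences).
#' @examples
#' degeneracy("ACGT")  # 1
#' degeneracy("ACRWT") # 4
#' @export
degeneracy <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- .norm_seq(seq)
  chars <- .check_iupac(seq)
  prod(nchar(.iupac_map[chars]))
}

#' Enumerate all unambiguous expansions of an IUPAC sequence
#'
#' @param seq A single IUPAC string with [degeneracy()] at most `max_n`.
#' @param max_n Refuse to enumerate more than this many expansions.
#' @return Character vector of all distinct unambiguous sequences.
#' @export
iupac_expansions <- function(seq, max_n = 4096) {
  seq <- .norm_seq(seq)
  chars <- .check_iupac(seq)
  if (degeneracy(seq) > max_n) {
    stop("degeneracy exceeds max_n = ", max_n, call. = FALSE)
  }
  sets <- lapply(chars, function(ch) strsplit(.iupac_map[[ch]], "")[[1]])
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' Reverse complement of an IUPAC sequence
#'
#' Ambiguity-aware: complements degenerate symbols correctly (R <-> Y etc.).
#'
#' @param seq A single IUPAC nucleotide string.
#' @return The reverse complement, 5'->3'.
#' @export
revcomp <- function(seq) {
  seq <- .norm_seq(seq)
  .check_iupac(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
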