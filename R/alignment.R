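#' Multiple-alignment container
#'
#' A light container for an aligned set of sequences: unique ids, equal
#' lengths, declared alphabet (`"nt"` or `"aa"`). Coordinates throughout the
#' package are 1-based and inclusive.
#'
#' @param seqs Named character vector of aligned sequences (names are ids),
#'   or an unnamed vector plus `ids`.
#' @param alphabet `"nt"` or `"aa"`.
#' @param ids Optional ids if `seqs` is unnamed.
#' @return An object of class `alignment`: list with `ids`, `seqs` (named
#'   character vector, uppercased; for nt, U normalised to T) and
#'   `alphabet`; `length(aln)` gives the number of columns.
#' @export
alignment <- function(seqs, alphabet = c("nt", "aa"), ids = names(seqs)) {
  alphabet <- match.arg(alphabet)
  if (is.null(ids)) stop("sequence ids are required", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(seqs) == 0L) stop("empty alignment", call. = FALSE)
  seqs <- toupper(as.character(seqs))
  if (alphabet == "nt") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop("aligned sequences must have equal lengths, found: ",
         paste(w, collapse = ", "), call. = FALSE)
  }
  ok_chars <- if (alphabet == "nt") {
    c(names(.iupac_map), "-")
  } else {
    c(.aa_alphabet, "X", "B", "Z", "J", "*", "-")
  }
  pat <- paste0("[^", paste(gsub("([*-])", "\\\\\\1", ok_chars), collapse = ""), "]")
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    stop("invalid ", alphabet, " character(s) in sequence(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(ids = as.character(ids),
                 seqs = stats::setNames(seqs, ids),
                 alphabet = alphabet),
            class = "alignment")
}

#' @export
length.alignment <- function(x) nchar(x$seqs[[1]])

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d x %d (%s)\n", length(x$ids), length(x),
              x$alphabet))
  invisible(x)
}

# character matrix view (rows = sequences, columns = sites)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$ids
  m
}

#' Define a named column window on an alignment
#'
#' @param name Window name (e.g. `"folmer"`, `"elongation"`).
#' @param start,end 1-based inclusive column coordinates.
#' @return A `region_window` object.
#' @export
region_window <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("need 1 <= start <= end, got [", start, ", ", end, "]",
         call. = FALSE)
  }
  structure(list(name = as.character(name), start = start, end = end),
            class = "region_window")
}

#' @export
print.region_window <- function(x, ...) {
  cat(sprintf("<region_window> %s: [%d, %d] (%d columns)\n",
              x$name, x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

.check_window <- function(aln, region) {
  if (!inherits(region, "region_window")) {
    stop("'region' must be a region_window", call. = FALSE)
  }
  if (region$end > length(aln)) {
    stop(sprintf("window [%d, %d] exceeds alignment length %d",
                 region$start, region$end, length(aln)), call. = FALSE)
  }
  invisible(region)
}

#' Extract a column window from an alignment
#'
#' @param x An [alignment()].
#' @param region A [region_window()] within the alignment.
#' @param ... Unused.
#' @return The column slice as a new `alignment` (ids preserved).
#' @exportS3Method stats::window
#' @export
window.alignment <- function(x, region, ...) {
  .check_window(x, region)
  alignment(substr(x$seqs, region$start, region$end), alphabet = x$alphabet,
            ids = x$ids)
}

#' Subset alignment rows by id
#'
#' @param aln An [alignment()].
#' @param ids Ids to keep (order preserved as given).
#' @return A new `alignment`.
#' @export
subset_ids <- function(aln, ids) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing)) {
    stop("unknown sequence id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  alignment(aln$seqs[ids], alphabet = aln$alphabet, ids = ids)
}
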