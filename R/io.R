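#' Read a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; the rest of
#' the header is kept as the description. CRLF line endings, wrapped and
#' single-line records are all accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences with a `descriptions`
#'   attribute (named character vector, `""` where absent).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(as.character(set), ids)
  attr(out, "descriptions") <- stats::setNames(desc, ids)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (names become headers; a
#'   `descriptions` attribute, if present, is appended after the id).
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  desc <- attr(seqs, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    d <- if (!is.null(desc) && nzchar(desc[[id]])) paste0(" ", desc[[id]])
      else ""
    writeLines(paste0(">", id, d), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read an aligned FASTA file as an alignment
#'
#' @param path Path to an aligned FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @return An [alignment()].
#' @export
read_alignment <- function(path, alphabet = c("nt", "aa")) {
  alignment(read_fasta(path), alphabet = match.arg(alphabet))
}

#' Read primers from a TSV table or FASTA file
#'
#' TSV format: columns `name`, `seq`, `orientation` (header required,
#' `#` comments allowed). FASTA: orientation is read from the description
#' (a token `forward` or `reverse`; default forward).
#'
#' @param path Path to the primer file.
#' @param format `"tsv"` or `"fasta"`; guessed from the extension by
#'   default.
#' @return A named list of [degenerate_primer()]s.
#' @export
read_primers <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- read_fasta(path)
    desc <- attr(seqs, "descriptions")
    primers <- lapply(names(seqs), function(id) {
      orient <- if (grepl("\\breverse\\b", desc[[id]], ignore.case = TRUE))
        "reverse" else "forward"
      degenerate_primer(id, seqs[[id]], orient)
    })
  } else {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("name", "seq", "orientation")
    if (!all(need %in% names(tab))) {
      stop("primer TSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    primers <- Map(degenerate_primer, tab$name, tab$seq, tab$orientation)
  }
  stats::setNames(primers, vapply(primers, `[[`, "", "name"))
}

#' Write amplicon regions as a BED-like TSV
#'
#' BED convention: 0-based half-open `start`, 1-based `end`.
#'
#' @param amplicons A list of `amplicon_region`s (see [amplicon()]).
#' @param path Output path.
#' @param name Feature name column (recycled).
#' @return `path`, invisibly.
#' @export
write_amplicon_bed <- function(amplicons, path, name = "amplicon") {
  if (inherits(amplicons, "amplicon_region")) amplicons <- list(amplicons)
  tab <- data.frame(
    chrom = vapply(amplicons, `[[`, "", "template_id"),
    start = vapply(amplicons, `[[`, 0L, "start") - 1L,
    end = vapply(amplicons, `[[`, 0L, "end"),
    name = name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract amplicon sequences from templates
#'
#' @param amplicons A list of `amplicon_region`s.
#' @param templates Named character vector of template sequences.
#' @return Named character vector of amplified subsequences (named
#'   `template:start-end`).
#' @export
extract_amplicons <- function(amplicons, templates) {
  if (inherits(amplicons, "amplicon_region")) amplicons <- list(amplicons)
  out <- vapply(amplicons, function(a) {
    substr(templates[[a$template_id]], a$start, a$end)
  }, "")
  names(out) <- vapply(amplicons, function(a) {
    sprintf("%s:%d-%d", a$template_id, a$start, a$end)
  }, "")
  out
}

# write a data frame as TSV (shared helper for CLI artifacts)
write_tsv <- function(tab, path) {
  is_list <- vapply(tab, is.list, NA)
  tab[is_list] <- lapply(tab[is_list], function(col) {
    vapply(col, paste, "", collapse = ",")
  })
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
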