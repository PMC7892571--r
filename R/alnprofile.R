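#' Column-wise alignment profiles
#'
#' Per-column symbol counts, frequencies and sequence-logo information
#' content. For each column with at least one unambiguous symbol, the
#' Shannon entropy is `H = -sum(f * log2(f))` over the observed unambiguous
#' symbols and the information content is `R = log2(s) - H` with `s = 4`
#' (nt) or `s = 20` (aa). No small-sample correction is applied by default
#' (set `correct = TRUE` for the `(s - 1) / (2 * ln(2) * n)` correction,
#' truncated at zero).
#'
#' Gaps (`-`) and ambiguity symbols (nt: the 11 degenerate IUPAC letters;
#' aa: `X,B,Z,J,*`) are counted separately and excluded from frequencies.
#'
#' @param aln An [alignment()].
#' @param correct Apply the small-sample correction to the information
#'   content (default `FALSE`).
#' @return A data frame with one row per column: `column`, one count column
#'   per unambiguous symbol, `gap`, `ambiguous`, `n` (unambiguous count),
#'   `entropy` and `info` (bits; `NA` for columns with no unambiguous
#'   symbol). Symbol counts carry the attribute `"symbols"`.
#' @export
column_profiles <- function(aln, correct = FALSE) {
  stopifnot(inherits(aln, "alignment"))
  m <- aln_matrix(aln)
  syms <- if (aln$alphabet == "nt") c("A", "C", "G", "T") else .aa_alphabet
  s <- length(syms)
  counts <- vapply(syms, function(sym) colSums(m == sym),
                   numeric(ncol(m)))
  counts <- matrix(counts, ncol = s, dimnames = list(NULL, syms))
  gap <- colSums(m == "-")
  n <- rowSums(counts)
  ambiguous <- nrow(m) - n - gap
  f <- counts / ifelse(n > 0, n, NA_real_)
  plogp <- ifelse(is.na(f) | f == 0, 0, f * log2(f))
  entropy <- -rowSums(plogp)
  entropy[n == 0] <- NA_real_
  info <- log2(s) - entropy
  if (correct) {
    info <- pmax(0, info - (s - 1) / (2 * log(2) * n))
  }
  out <- data.frame(column = seq_len(ncol(m)), counts, gap = gap,
                    ambiguous = ambiguous, n = n, entropy = entropy,
                    info = info)
  attr(out, "symbols") <- syms
  attr(out, "alphabet") <- aln$alphabet
  out
}

#' Sequence-logo letter heights
#'
#' Long-form logo data: per column and symbol, the letter height
#' `f * info`, as plotted by sequence-logo tools.
#'
#' @inheritParams column_profiles
#' @return Data frame with columns `column`, `symbol`, `freq`, `height`.
#' @export
logo_heights <- function(aln, correct = FALSE) {
  prof <- column_profiles(aln, correct = correct)
  syms <- attr(prof, "symbols")
  out <- do.call(rbind, lapply(syms, function(sym) {
    data.frame(column = prof$column, symbol = sym,
               freq = prof[[sym]] / ifelse(prof$n > 0, prof$n, NA_real_),
               height = prof[[sym]] / ifelse(prof$n > 0, prof$n, NA_real_) *
                 prof$info)
  }))
  out <- out[out$freq > 0 & !is.na(out$freq), ]
  out[order(out$column, -out$height), , drop = FALSE]
}

#' Consensus sequence of an alignment
#'
#' Per column, the unambiguous symbol whose frequency among unambiguous
#' (non-gap, non-ambiguity) characters is at least `threshold`; otherwise
#' `N` (nt) or `X` (aa). With `threshold = 1` this is the strict (100%)
#' consensus. For nucleotide alignments, `mode = "iupac"` instead emits the
#' IUPAC union of all bases observed in the column, i.e. a degenerate
#' consensus.
#'
#' @param aln An [alignment()].
#' @param threshold Fraction in (0, 1].
#' @param mode `"majority"` (default) or `"iupac"` (nt only).
#' @return A single consensus string.
#' @examples
#' a <- alignment(c(x = "ACGA", y = "ACGG"))
#' consensus(a, 1)                 # "ACGN"
#' consensus(a, 1, mode = "iupac") # "ACGR"
#' @export
consensus <- function(aln, threshold = 1, mode = c("majority", "iupac")) {
  stopifnot(inherits(aln, "alignment"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  if (mode == "iupac" && aln$alphabet != "nt") {
    stop("IUPAC consensus mode is defined for nucleotide alignments only",
         call. = FALSE)
  }
  prof <- column_profiles(aln)
  syms <- attr(prof, "symbols")
  unknown <- if (aln$alphabet == "nt") "N" else "X"
  counts <- as.matrix(prof[, syms, drop = FALSE])
  if (mode == "iupac") {
    cons <- apply(counts, 1L, function(cnt) {
      present <- syms[cnt > 0]
      if (length(present) == 0L) return(unknown)
      iupac_union(present)
    })
  } else {
    best <- max.col(counts, ties.method = "first")
    ok <- prof$n > 0 & counts[cbind(seq_len(nrow(counts)), best)] >=
      threshold * prof$n - 1e-9
    cons <- ifelse(ok, syms[best], unknown)
  }
  paste(cons, collapse = "")
}

#' Count variable sites in an alignment window
#'
#' A column is variable iff at least two distinct unambiguous symbols occur
#' among the selected rows; gaps and ambiguity symbols never contribute to
#' variability.
#'
#' @param aln An [alignment()].
#' @param region A [region_window()]; default: the full alignment.
#' @param ids Optional id subset to restrict the rows.
#' @return List with `n_variable`, `n_total` (window width) and `percent`
#'   (`100 * n_variable / n_total`).
#' @export
variable_sites <- function(aln, region = NULL, ids = NULL) {
  stopifnot(inherits(aln, "alignment"))
  if (is.null(region)) region <- region_window("full", 1L, length(aln))
  .check_window(aln, region)
  if (!is.null(ids)) aln <- subset_ids(aln, ids)
  sub <- window.alignment(aln, region)
  prof <- column_profiles(sub)
  syms <- attr(prof, "symbols")
  n_distinct <- rowSums(as.matrix(prof[, syms, drop = FALSE]) > 0)
  n_variable <- sum(n_distinct >= 2L)
  n_total <- length(sub)
  list(n_variable = n_variable, n_total = n_total,
       percent = 100 * n_variable / n_total)
}

#' Collapse sequences into haplotypes
#'
#' Groups sequences that are byte-identical after uppercasing and U -> T
#' normalisation. Full-length identity is required: sequences of different
#' lengths are distinct haplotypes. Group order and representatives follow
#' first appearance.
#'
#' @param seqs Named character vector of (ungapped) sequences; names are
#'   ids.
#' @return A `haplotypes` object: list of groups, each with
#'   `representative`, `ids` and `seq`; `n_haplotypes` attribute.
#' @export
dereplicate <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique ids as names", call. = FALSE)
  }
  norm <- .norm_seq(as.character(seqs))
  keys <- factor(norm, levels = unique(norm))
  groups <- lapply(levels(keys), function(k) {
    ids <- names(seqs)[norm == k]
    list(representative = ids[[1]], ids = ids, seq = k)
  })
  structure(groups, class = "haplotypes", n_haplotypes = length(groups))
}

#' @export
print.haplotypes <- function(x, ...) {
  cat(sprintf("<haplotypes> %d haplotype(s) from %d sequence(s)\n",
              attr(x, "n_haplotypes"), sum(lengths(lapply(x, `[[`, "ids")))))
  for (g in x) {
    cat(sprintf("  %s: %d sequence(s)\n", g$representative, length(g$ids)))
  }
  invisible(x)
}
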