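#' Primer design policy
#'
#' @param max_total_degeneracy Largest tolerated primer degeneracy (product
#'   of per-position expansion sizes; default 32).
#' @param major_base_threshold When degenerating a column would blow the
#'   budget, fall back to the most frequent base if its frequency is at
#'   least this (default 0.5); otherwise the degenerate union is used
#'   anyway, with a warning.
#' @param clamp_len Number of 3'-terminal positions that must be invariant
#'   by the genetic code (default 2).
#' @param code Genetic code used for the codon-level invariance analysis
#'   (see [genetic_code()]).
#' @return A `design_policy` object.
#' @export
design_policy <- function(max_total_degeneracy = 32,
                          major_base_threshold = 0.5,
                          clamp_len = 2L,
                          code = genetic_code("standard")) {
  if (major_base_threshold <= 0 || major_base_threshold > 1) {
    stop("major_base_threshold must be in (0, 1]", call. = FALSE)
  }
  if (clamp_len < 1L) stop("clamp_len must be >= 1", call. = FALSE)
  structure(list(max_total_degeneracy = max_total_degeneracy,
                 major_base_threshold = major_base_threshold,
                 clamp_len = as.integer(clamp_len),
                 code = genetic_code(code)),
            class = "design_policy")
}

# per-column observed base sets (IUPAC symbols in sequences expanded)
.column_base_sets <- function(aln) {
  m <- aln_matrix(aln)
  lapply(seq_len(ncol(m)), function(j) {
    sort(unique(unlist(strsplit(.iupac_map[m[, j]], ""))))
  })
}

#' Degenerate consensus under a degeneracy budget
#'
#' Per column, left to right: an invariant column contributes its base; a
#' variable column contributes the IUPAC union of the observed bases if
#' that keeps the running total degeneracy within
#' `policy$max_total_degeneracy`, otherwise the most frequent base if its
#' frequency reaches `policy$major_base_threshold`, otherwise the union
#' anyway (with a warning). Gap-containing columns are not allowed.
#'
#' @param aln A nucleotide [alignment()] (typically a primer-length
#'   window).
#' @param policy A [design_policy()].
#' @return A single IUPAC string, one symbol per column.
#' @export
degenerate_consensus <- function(aln, policy = design_policy()) {
  stopifnot(inherits(aln, "alignment"), aln$alphabet == "nt")
  if (any(grepl("-", aln$seqs, fixed = TRUE))) {
    stop("gapped columns cannot be degenerated into a primer", call. = FALSE)
  }
  sets <- .column_base_sets(aln)
  m <- aln_matrix(aln)
  total <- 1
  syms <- character(length(sets))
  for (j in seq_along(sets)) {
    s <- sets[[j]]
    if (length(s) == 1L) {
      syms[j] <- s
      next
    }
    if (total * length(s) <= policy$max_total_degeneracy) {
      syms[j] <- iupac_union(s)
      total <- total * length(s)
      next
    }
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    major <- names(tab)[which.max(tab)]
    if (max(tab) / sum(tab) >= policy$major_base_threshold) {
      syms[j] <- major
    } else {
      warning(sprintf(
        "column %d: degeneracy budget exhausted and no base reaches %.0f%%; using the union anyway",
        j, 100 * policy$major_base_threshold))
      syms[j] <- iupac_union(s)
      total <- total * length(s)
    }
  }
  paste(syms, collapse = "")
}

# Observed amino-acid set at the codon covering alignment column 'col'
# (frame = codon position of column 1). Codons with gap/N/degenerate
# symbols, or truncated by the alignment edge, yield "X".
.codon_aa_set <- function(m, col, frame, code) {
  cpos <- ((col - frame) %% 3L) + 1L
  cstart <- col - cpos + 1L
  if (cstart < 1L || cstart + 2L > ncol(m)) return("X")
  codons <- paste0(m[, cstart], m[, cstart + 1L], m[, cstart + 2L])
  aa <- ifelse(grepl("[^ACGT]", codons), "X",
               code$codon_map[codons])
  unique(aa)
}

# codon position (1|2|3) of alignment column 'col'
.codon_pos <- function(col, frame) ((col - frame) %% 3L) + 1L

#' Design a degenerate primer on a codon alignment window
#'
#' Builds a primer from the observed column variation of a codon-aligned
#' nucleotide alignment, with a genetic-code aware 3' anchor: the
#' `clamp_len` 3'-terminal positions must be *invariant by the code* — for
#' the amino acids observed at the covering codon, every codon the code
#' allows carries the same base there (see [guaranteed_positions()]). A
#' candidate 3' end failing this (e.g. the first position of a conserved
#' glycine under the ascidian mitochondrial code, where both A and G
#' occur) is rejected and the end is shifted upstream one base at a time,
#' up to one full codon, before the window is declared undesignable. The
#' remaining positions follow [degenerate_consensus()].
#'
#' For `orientation = "reverse"` the primer is designed on the reverse
#' complement; its 3' end then sits at the *start* (smallest forward
#' coordinate) of the window, and shifting upstream means towards larger
#' forward coordinates.
#'
#' @param aln A codon-aligned nucleotide [alignment()] (no gaps inside the
#'   window).
#' @param region A [region_window()] of length at least 15 giving the
#'   primer footprint on the alignment.
#' @param policy A [design_policy()].
#' @param orientation `"forward"` or `"reverse"`.
#' @param frame Codon position (1, 2 or 3) of alignment column 1.
#' @param name Primer name.
#' @return A [degenerate_primer()] whose `anchor` records the alignment
#'   coordinate of the 3' end.
#' @export
design_primer <- function(aln, region, policy = design_policy(),
                          orientation = c("forward", "reverse"),
                          frame = 1L, name = "designed") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(aln, "alignment"), aln$alphabet == "nt")
  .check_window(aln, region)
  if (region$end - region$start + 1L < 15L) {
    stop("design window must be at least 15 columns", call. = FALSE)
  }
  m <- aln_matrix(aln)
  if (any(m[, region$start:region$end] == "-")) {
    stop("design window contains gap characters", call. = FALSE)
  }
  code <- policy$code
  rejected <- character()

  clamp_ok <- function(end3) {
    # clamp columns: for forward, the 'clamp_len' columns ending at end3
    # (towards 5' = smaller coords); for reverse, starting at end3
    # (towards 5' = larger coords)
    cols <- if (orientation == "forward") {
      end3 - seq_len(policy$clamp_len) + 1L
    } else {
      end3 + seq_len(policy$clamp_len) - 1L
    }
    for (col in cols) {
      aa_set <- .codon_aa_set(m, col, frame, code)
      if ("X" %in% aa_set) {
        rejected <<- c(rejected, sprintf(
          "column %d: untranslatable codon (gap/N or alignment edge)", col))
        return(FALSE)
      }
      gp <- guaranteed_positions(aa_set, code)[[.codon_pos(col, frame)]]
      if (!gp$invariant) {
        rejected <<- c(rejected, sprintf(
          "column %d: codon position %d of conserved {%s} admits {%s} under code '%s'",
          col, gp$codon_position, paste(sort(aa_set), collapse = ","),
          paste(gp$allowed, collapse = ","), code$name))
        return(FALSE)
      }
    }
    TRUE
  }

  ends <- if (orientation == "forward") {
    region$end - 0:3
  } else {
    region$start + 0:3
  }
  end3 <- NA_integer_
  for (e in ends) {
    if (clamp_ok(e)) { end3 <- e; break }
  }
  if (is.na(end3)) {
    stop(paste0("no admissible 3' anchor within one codon of the window ",
                if (orientation == "forward") "end" else "start",
                "; rejected positions:\n  ",
                paste(rejected, collapse = "\n  ")), call. = FALSE)
  }
  span <- if (orientation == "forward") {
    region_window(region$name, region$start, end3)
  } else {
    region_window(region$name, end3, region$end)
  }
  cons <- degenerate_consensus(window.alignment(aln, span), policy)
  seq <- if (orientation == "reverse") revcomp(cons) else cons
  degenerate_primer(name, seq, orientation,
                    anchor = list(reference = "alignment", end3 = end3))
}

#' Derive a primer from an anchor primer and a consensus
#'
#' Re-targets an existing primer to a sequence collection: positions where
#' the anchor already matches the consensus (the consensus base set is
#' contained in the anchor symbol's expansion) are kept; mismatched
#' positions are replaced by the consensus symbol, which may be
#' degenerate. Boundaries are unchanged, so the derived primer maps at
#' exactly the anchor's position. The consensus must be given 5'->3' in
#' the primer's own orientation and with the primer's length.
#'
#' @param anchor_primer A [degenerate_primer()].
#' @param consensus An IUPAC string of the same length (e.g. from
#'   [degenerate_consensus()] or [consensus()] in IUPAC mode).
#' @param name Name for the derived primer (default: anchor name +
#'   `"_derived"`).
#' @return A [degenerate_primer()].
#' @export
derive_from_anchor <- function(anchor_primer, consensus,
                               name = paste0(anchor_primer$name, "_derived")) {
  stopifnot(inherits(anchor_primer, "degenerate_primer"))
  consensus <- .norm_seq(consensus)
  .check_iupac(consensus, "consensus")
  if (nchar(consensus) != nchar(anchor_primer$seq)) {
    stop(sprintf("consensus length (%d) differs from primer length (%d)",
                 nchar(consensus), nchar(anchor_primer$seq)), call. = FALSE)
  }
  pa <- strsplit(anchor_primer$seq, "")[[1]]
  pc <- strsplit(consensus, "")[[1]]
  keep <- mapply(function(a, c) {
    all(iupac_expand(c) %in% iupac_expand(a))
  }, pa, pc)
  out <- ifelse(keep, pa, pc)
  if (mean(!keep) > 0.5) {
    warning(sprintf("%d of %d positions replaced by the consensus symbol",
                    sum(!keep), length(keep)))
  }
  degenerate_primer(name, paste(out, collapse = ""),
                    anchor_primer$orientation,
                    anchor = anchor_primer$anchor)
}
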