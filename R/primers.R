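#' Degenerate primer
#'
#' An IUPAC primer written 5'->3' with an orientation. Reverse primers are
#' written on the minus strand (as ordered from a synthesis house) and are
#' matched against the reverse complement of templates.
#'
#' @param name Primer name.
#' @param seq IUPAC sequence, 5'->3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @param anchor Optional list `(reference = id, end3 = coordinate)`
#'   recording where the 3' end maps on a reference.
#' @param tm_range Optional numeric length-2 melting-temperature range
#'   (degrees C); see [primer_tm_range()].
#' @return A `degenerate_primer` object.
#' @examples
#' degenerate_primer("dinF", "CGTTGRTTTATRTCTACWAATCATAARGA", "forward")
#' @export
degenerate_primer <- function(name, seq, orientation = c("forward", "reverse"),
                              anchor = NULL, tm_range = NULL) {
  orientation <- match.arg(orientation)
  seq <- .norm_seq(seq)
  .check_iupac(seq, what = paste0("primer '", name, "'"))
  if (nchar(seq) < 15L) {
    stop("primer '", name, "' is shorter than 15 nt", call. = FALSE)
  }
  structure(list(name = as.character(name), seq = seq,
                 orientation = orientation, anchor = anchor,
                 tm_range = tm_range),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s): 5'-%s-3' (degeneracy %d)\n",
              x$name, x$orientation, x$seq, degeneracy(x$seq)))
  invisible(x)
}

# Per-position allowed-base lookup for a primer scanned along the forward
# strand. For reverse primers the reverse complement is scanned, so window
# position j (1..L, left to right) corresponds to 3'-end offset j - 1;
# for forward primers the offset is L - j.
.primer_scan_sets <- function(primer) {
  scanned <- if (primer$orientation == "reverse") revcomp(primer$seq) else
    primer$seq
  chars <- strsplit(scanned, "")[[1]]
  L <- length(chars)
  offsets <- if (primer$orientation == "reverse") seq_len(L) - 1L else
    L - seq_len(L)
  list(sets = strsplit(.iupac_map[chars], ""), offsets = offsets, L = L)
}

#' Map a degenerate primer on a template
#'
#' Slides the primer along the template (reverse primers are matched
#' against the reverse complement; coordinates are always reported on the
#' forward strand, 1-based inclusive). A template base matches a primer
#' symbol iff the base is in the symbol's IUPAC expansion; `N` in the
#' template always counts as a mismatch. Windows are kept iff the mismatch
#' count is at most `max_mismatches` and no mismatch falls within `clamp`
#' bases of the primer's 3' end (offsets `0..clamp-1`); results are sorted
#' by (mismatch count, start).
#'
#' @param primer A [degenerate_primer()].
#' @param template A single nucleotide string over `A,C,G,T,N` (any case).
#' @param max_mismatches Maximum mismatches per window (default 6).
#' @param clamp Number of 3'-terminal positions that must be mismatch-free
#'   (default 2; 0 disables the clamp).
#' @param template_id Id reported in the result (default `"template"`).
#' @return A data frame of matches: `template_id`, `start`, `end`,
#'   `strand`, `mismatch_count`, `mp_flag` (mismatch at 3'-penultimate
#'   offset 1), `terminal_flag` (mismatch at offset 0) and a list column
#'   `mismatch_offsets` (3'-end offsets, 0 = terminal). Zero rows if no
#'   window qualifies; a primer longer than the template yields zero rows
#'   with a warning.
#' @export
find_matches <- function(primer, template, max_mismatches = 6L, clamp = 2L,
                         template_id = "template") {
  stopifnot(inherits(primer, "degenerate_primer"))
  template <- .norm_seq(template)
  tchars <- strsplit(template, "")[[1]]
  bad <- which(!tchars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("invalid template character '%s' at position %d (template must be unambiguous or N)",
                 tchars[bad[1]], bad[1]), call. = FALSE)
  }
  scan <- .primer_scan_sets(primer)
  L <- scan$L
  n <- length(tchars)
  empty <- data.frame(template_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatch_count = integer(), mp_flag = logical(),
                      terminal_flag = logical())
  empty$mismatch_offsets <- list()
  if (L > n) {
    warning(sprintf("primer '%s' (%d nt) longer than template '%s' (%d nt)",
                    primer$name, L, template_id, n))
    return(empty)
  }
  # mism[j, s]: TRUE if primer scan-position j mismatches template position
  # s + j - 1, for window start s
  match_pos <- matrix(FALSE, nrow = L, ncol = n)
  for (j in seq_len(L)) {
    match_pos[j, ] <- tchars %in% scan$sets[[j]]
  }
  rows <- lapply(seq_len(n - L + 1L), function(s) {
    hit <- match_pos[cbind(seq_len(L), s:(s + L - 1L))]
    mm_j <- which(!hit)
    offsets <- sort(scan$offsets[mm_j])
    if (length(offsets) > max_mismatches) return(NULL)
    if (clamp > 0L && any(offsets < clamp)) return(NULL)
    list(start = s, end = s + L - 1L, mismatch_count = length(offsets),
         offsets = offsets)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    template_id = template_id,
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    strand = if (primer$orientation == "reverse") "-" else "+",
    mismatch_count = vapply(rows, `[[`, 0L, "mismatch_count"),
    mp_flag = vapply(rows, function(r) 1L %in% r$offsets, NA),
    terminal_flag = vapply(rows, function(r) 0L %in% r$offsets, NA))
  out$mismatch_offsets <- lapply(rows, `[[`, "offsets")
  out <- out[order(out$mismatch_count, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-match mismatch profile of a primer across templates
#'
#' For each template, the best window (fewest mismatches, leftmost on tie)
#' with the 3' clamp relaxed to 0 — so clamp violations are observed, not
#' hidden — and mismatches allowed up to half the primer length. The MP
#' flag marks a mismatch at the 3'-penultimate position (offset 1), the
#' failure mode that degenerate-code-unaware primers suffer on templates
#' whose overlapped glycine codon starts with A.
#'
#' @param primer A [degenerate_primer()].
#' @param templates Named character vector of template sequences.
#' @return Data frame with one row per template: `template_id`,
#'   `mismatch_count` (`NA` if no window scores at most half the primer
#'   length: "no site found"), `mp_flag`, `terminal_flag`, `start`, `end`,
#'   `strand`.
#' @export
mp_scan <- function(primer, templates) {
  if (is.null(names(templates))) {
    names(templates) <- paste0("template", seq_along(templates))
  }
  half <- nchar(primer$seq) %/% 2L
  rows <- lapply(names(templates), function(id) {
    m <- find_matches(primer, templates[[id]], max_mismatches = half,
                      clamp = 0L, template_id = id)
    if (nrow(m) == 0L) {
      data.frame(template_id = id, mismatch_count = NA_integer_,
                 mp_flag = NA, terminal_flag = NA, start = NA_integer_,
                 end = NA_integer_, strand = NA_character_)
    } else {
      m[1L, c("template_id", "mismatch_count", "mp_flag", "terminal_flag",
              "start", "end", "strand")]
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Amplicon spanned by a forward/reverse primer match pair
#'
#' @param fwd_match,rev_match Single-row match records (as returned by
#'   [find_matches()]) on the same template, forward on `+`, reverse on
#'   `-`, with non-overlapping footprints (forward entirely upstream).
#' @return An `amplicon_region`: list with `template_id`, `start`, `end`
#'   (inclusive of both primer footprints) and `length`.
#' @export
amplicon <- function(fwd_match, rev_match) {
  f <- as.list(fwd_match[1, ]); r <- as.list(rev_match[1, ])
  if (!identical(f$template_id, r$template_id)) {
    stop("matches are on different templates", call. = FALSE)
  }
  if (!identical(f$strand, "+") || !identical(r$strand, "-")) {
    stop("need a forward (+) and a reverse (-) match, got (",
         f$strand, ", ", r$strand, ")", call. = FALSE)
  }
  if (f$end >= r$start) {
    stop("primer footprints overlap or are out of order (forward ends at ",
         f$end, ", reverse starts at ", r$start, ")", call. = FALSE)
  }
  structure(list(template_id = f$template_id, start = f$start, end = r$end,
                 length = r$end - f$start + 1L),
            class = "amplicon_region")
}

#' @export
print.amplicon_region <- function(x, ...) {
  cat(sprintf("<amplicon_region> %s:%d-%d (%d bp)\n", x$template_id,
              x$start, x$end, x$length))
  invisible(x)
}

#' Screen a primer panel against a template panel
#'
#' Best-match mismatch counts (3' clamp relaxed, as in [mp_scan()]) for
#' every primer x template combination, plus a cumulative summary: per
#' primer, the number of templates with at most k mismatches for
#' k = 0..6. Templates where no window scores at most half the primer
#' length are reported with `NA` ("no site found") and excluded from the
#' summary counts.
#'
#' @param primers List of [degenerate_primer()]s.
#' @param templates Named character vector of template sequences.
#' @return A `panel_screen`: list with `results` (long data frame:
#'   `primer`, plus the [mp_scan()] columns) and `summary` (data frame:
#'   `primer`, `le_0` .. `le_6`, `no_site`).
#' @export
screen_panel <- function(primers, templates) {
  if (inherits(primers, "degenerate_primer")) primers <- list(primers)
  res <- do.call(rbind, lapply(primers, function(p) {
    cbind(primer = p$name, mp_scan(p, templates))
  }))
  rownames(res) <- NULL
  summ <- do.call(rbind, lapply(split(res, res$primer), function(d) {
    counts <- vapply(0:6, function(k) {
      sum(!is.na(d$mismatch_count) & d$mismatch_count <= k)
    }, 0L)
    out <- data.frame(primer = d$primer[[1]])
    out[paste0("le_", 0:6)] <- as.list(counts)
    out$no_site <- sum(is.na(d$mismatch_count))
    out
  }))
  rownames(summ) <- NULL
  structure(list(results = res, summary = summ), class = "panel_screen")
}

#' @export
print.panel_screen <- function(x, ...) {
  cat(sprintf("<panel_screen> %d primer(s) x %d template(s)\n",
              nrow(x$summary), length(unique(x$results$template_id))))
  print(x$summary)
  invisible(x)
}

# SantaLucia (1998) unified nearest-neighbour parameters:
# dH (kcal/mol), dS (cal/(mol K)) per 5'->3' dinucleotide step.
.nn_dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

# Tm (deg C) of one unambiguous oligo vs its perfect complement,
# nearest-neighbour unified model; initiation: terminal A.T pair dH 2.3 /
# dS 4.1, terminal G.C pair dH 0.1 / dS -2.8; salt-corrected entropy.
.nn_tm <- function(seq, conc = 5e-7, na = 0.05) {
  chars <- strsplit(seq, "")[[1]]
  steps <- paste0(chars[-length(chars)], chars[-1])
  ends <- chars[c(1, length(chars))] %in% c("A", "T")
  dH <- sum(.nn_dH[steps]) + sum(ifelse(ends, 2.3, 0.1))
  dS <- sum(.nn_dS[steps]) + sum(ifelse(ends, 4.1, -2.8))
  dS <- dS + 0.368 * (length(chars) - 1) * log(na)
  1000 * dH / (dS + 1.987 * log(conc / 4)) - 273.15
}

#' Melting-temperature range of a degenerate primer
#'
#' Nearest-neighbour (unified-parameter) melting temperatures of the
#' least- and most-stable unambiguous expansions, reported as a range. For
#' degeneracy at most `max_enum` all expansions are enumerated; beyond
#' that the AT-richest and GC-richest expansions are used.
#'
#' @param primer A [degenerate_primer()] or IUPAC string.
#' @param conc Primer concentration (M, default 5e-7).
#' @param na Monovalent cation concentration (M, default 0.05).
#' @param max_enum Enumeration cap (default 256).
#' @return Numeric length-2: `c(min, max)` Tm in degrees C.
#' @export
primer_tm_range <- function(primer, conc = 5e-7, na = 0.05, max_enum = 256) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$seq else
    .norm_seq(primer)
  if (degeneracy(seq) <= max_enum) {
    tms <- vapply(iupac_expansions(seq, max_n = max_enum), .nn_tm, 0,
                  conc = conc, na = na)
    return(range(tms))
  }
  chars <- strsplit(seq, "")[[1]]
  pick <- function(prefer) vapply(chars, function(ch) {
    set <- iupac_expand(ch)
    hit <- intersect(prefer, set)
    if (length(hit)) hit[[1]] else set[[1]]
  }, "")
  lo <- paste(pick(c("A", "T", "G", "C")), collapse = "")
  hi <- paste(pick(c("G", "C", "A", "T")), collapse = "")
  range(.nn_tm(lo, conc, na), .nn_tm(hi, conc, na))
}
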