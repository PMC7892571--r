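#' Genetic-code tables
#'
#' A `genetic_code` object maps all 64 unambiguous codons to one-letter
#' amino-acid symbols (stop = `*`). Two codes are built in:
#'
#' * `"standard"` (NCBI translation table 1);
#' * `"ascidian_mt"` (NCBI translation table 13), in which AGA/AGG encode
#'   Gly (alongside GGN), ATA encodes Met and TGA encodes Trp. The complete
#'   64-entry table is taken from the NCBI numbering as shipped with
#'   Biostrings; see the package vignette for why table 13 is used for the
#'   ascidian mitochondrial code.
#'
#' User codes can be loaded from plain-text files with
#' [read_genetic_code()].
#'
#' @param code Either a `genetic_code` object (returned unchanged), a name
#'   (`"standard"`, `"ascidian_mt"`), or an NCBI-style table id (1 or 13).
#' @return An object of class `genetic_code`: a list with `name`,
#'   `table_id` and `codon_map` (named character vector of length 64).
#' @examples
#' gc <- genetic_code("ascidian_mt")
#' gc$codon_map[["AGA"]] # "G"
#' @export
genetic_code <- function(code = "standard") {
  if (inherits(code, "genetic_code")) return(code)
  if (is.numeric(code)) code <- as.character(as.integer(code))
  spec <- switch(as.character(code),
    "standard" = , "1" = list(name = "standard", id = 1L, ncbi = "1"),
    "ascidian_mt" = , "13" = list(name = "ascidian_mt", id = 13L, ncbi = "13"),
    stop("unknown genetic code: ", code,
         " (built-ins: 'standard'/1, 'ascidian_mt'/13)", call. = FALSE)
  )
  map <- Biostrings::getGeneticCode(spec$ncbi)
  map <- map[order(names(map))]
  attributes(map) <- list(names = names(map))
  new_genetic_code(spec$name, spec$id, map)
}

new_genetic_code <- function(name, table_id, codon_map) {
  codon_map <- codon_map[order(names(codon_map))]
  codons <- names(codon_map)
  bases <- c("A", "C", "G", "T")
  all64 <- sort(do.call(paste0, expand.grid(bases, bases, bases)))
  if (length(codon_map) != 64L || !identical(codons, all64)) {
    stop("codon_map must contain exactly the 64 unambiguous codons",
         call. = FALSE)
  }
  ok <- codon_map %in% c(.aa_alphabet, "*")
  if (!all(ok)) {
    stop("invalid amino-acid symbol(s) in codon_map: ",
         paste(unique(codon_map[!ok]), collapse = ","), call. = FALSE)
  }
  structure(list(name = name, table_id = as.integer(table_id),
                 codon_map = codon_map),
            class = "genetic_code")
}

.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> %s (table id %d)\n", x$name, x$table_id))
  cat("  stops:", paste(names(x$codon_map)[x$codon_map == "*"],
                        collapse = " "), "\n")
  invisible(x)
}

#' Read a genetic code from a plain-text table
#'
#' Format: one line per codon, `"AAA K"`, 64 non-comment lines; `#` starts a
#' comment; blank lines ignored. Codons may use U for T and any case.
#'
#' @param path Path to the table file.
#' @param name Name for the code (default: file base name).
#' @param table_id NCBI-style id; 0 marks a custom code.
#' @return A `genetic_code` object.
#' @export
read_genetic_code <- function(path, name = NULL, table_id = 0L) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != 64L) {
    stop(sprintf("genetic-code file must have 64 entries, found %d: %s",
                 length(lines), path), call. = FALSE)
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed genetic-code line: '", lines[bad[1]], "'", call. = FALSE)
  }
  codons <- .norm_seq(vapply(parts, `[[`, "", 1L))
  aas <- toupper(vapply(parts, `[[`, "", 2L))
  if (anyDuplicated(codons)) {
    stop("duplicate codon(s): ",
         paste(unique(codons[duplicated(codons)]), collapse = ","),
         call. = FALSE)
  }
  map <- stats::setNames(aas, codons)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  new_genetic_code(name, table_id, map)
}

#' Write a genetic code to its plain-text table format
#'
#' @param code A `genetic_code` object (or name/id accepted by
#'   [genetic_code()]).
#' @param path Output file path.
#' @export
write_genetic_code <- function(code, path) {
  code <- genetic_code(code)
  writeLines(c(sprintf("# genetic code: %s (table id %d)", code$name,
                       code$table_id),
               paste(names(code$codon_map), code$codon_map)),
             path)
  invisible(path)
}

#' Translate a codon-aligned nucleotide sequence
#'
#' One amino-acid symbol per complete codon, starting at `frame`. Codons
#' containing a gap (`-`) or `N` translate to `X`; stop codons to `*`. A
#' trailing partial codon is dropped. `U` is normalised to `T` and lowercase
#' to uppercase.
#'
#' @param nt_seq A single nucleotide string over `A,C,G,T,U,-,N` (any case).
#' @param code Genetic code (see [genetic_code()]).
#' @param frame Reading-frame offset: translation starts at position 1, 2
#'   or 3.
#' @return A single amino-acid string.
#' @examples
#' translate("AGA", genetic_code("ascidian_mt")) # "G"
#' translate("AGA", genetic_code("standard"))    # "R"
#' translate("GA-")                              # "X"
#' @export
translate <- function(nt_seq, code = genetic_code("standard"), frame = 1L) {
  stopifnot(length(nt_seq) == 1L, frame %in% 1:3)
  code <- genetic_code(code)
  s <- .norm_seq(nt_seq)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (expected A,C,G,T,U,-,N)",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  chars <- chars[frame:length(chars)]
  n_codon <- length(chars) %/% 3L
  if (n_codon == 0L) return("")
  idx <- seq_len(n_codon * 3L)
  m <- matrix(chars[idx], nrow = 3L)
  codons <- apply(m, 2L, paste, collapse = "")
  aa <- ifelse(grepl("[-N]", codons), "X", code$codon_map[codons])
  paste(aa, collapse = "")
}

#' Codons encoding a set of amino acids
#'
#' The exact inverse image of `aa_set` under the code's codon map. Stop
#' codons are returned only if `*` is explicitly in `aa_set`.
#'
#' @param aa_set Character vector of one-letter amino-acid symbols (and/or
#'   `*`).
#' @param code Genetic code (see [genetic_code()]).
#' @return Character vector of codons, sorted.
#' @examples
#' codons_for("D")                              # GAC GAT
#' codons_for("G", genetic_code("ascidian_mt")) # AGA AGG GGA GGC GGG GGT
#' @export
codons_for <- function(aa_set, code = genetic_code("standard")) {
  code <- genetic_code(code)
  aa_set <- unique(toupper(aa_set))
  if (length(aa_set) == 0L) stop("empty amino-acid set", call. = FALSE)
  unknown <- setdiff(aa_set, unique(code$codon_map))
  if (length(unknown)) {
    stop("symbol(s) not encoded by code '", code$name, "': ",
         paste(unknown, collapse = ","), call. = FALSE)
  }
  sort(names(code$codon_map)[code$codon_map %in% aa_set])
}

#' Codon positions guaranteed invariant for an amino-acid set
#'
#' For each of the three codon positions, the union of bases observed over
#' all codons encoding `aa_set` under `code`. A position whose union is a
#' singleton is invariant: any codon for any of those amino acids carries
#' that base, so a primer base placed there pairs perfectly regardless of
#' synonymous (or within-set) substitution. This is the codon-level
#' invariance analysis behind genetic-code aware 3' anchor placement: e.g.
#' Asp/Glu are jointly encoded by GAN, so positions 1-2 are guaranteed "GA",
#' whereas under the ascidian mitochondrial code Gly (GGN + AGR) has an
#' ambiguous first position (A or G).
#'
#' @inheritParams codons_for
#' @return A list of three `position_constraint` objects, each a list with
#'   `codon_position` (1-3), `allowed` (sorted base vector), `iupac` (the
#'   union symbol) and `invariant` (logical).
#' @examples
#' guaranteed_positions(c("D", "E"))
#' guaranteed_positions("G", genetic_code("ascidian_mt"))
#' @export
guaranteed_positions <- function(aa_set, code = genetic_code("standard")) {
  code <- genetic_code(code)
  codons <- codons_for(aa_set, code)
  lapply(1:3, function(pos) {
    allowed <- sort(unique(substr(codons, pos, pos)))
    structure(list(codon_position = pos,
                   allowed = allowed,
                   iupac = iupac_union(allowed),
                   invariant = length(allowed) == 1L),
              class = "position_constraint")
  })
}

#' @export
print.position_constraint <- function(x, ...) {
  cat(sprintf("codon position %d: {%s}%s\n", x$codon_position,
              paste(x$allowed, collapse = ","),
              if (x$invariant) " [invariant]" else ""))
  invisible(x)
}
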