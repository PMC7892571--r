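# Independent brute-force oracles and fixture builders used across tests.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# random IUPAC primer of length L with at most 'max_deg' total degeneracy
random_primer <- function(L, max_deg = 64) {
  chars <- sample(BASES, L, replace = TRUE)
  deg <- 1
  for (i in sample(L)) {
    sym <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"),
                  1)
    mult <- length(iupac_expand(sym))
    if (deg * mult <= max_deg && stats::runif(1) < 0.4) {
      chars[i] <- sym
      deg <- deg * mult
    }
  }
  paste(chars, collapse = "")
}

# oracle: per window, the minimum Hamming distance between the template
# window and any unambiguous expansion of the primer (N never matches)
brute_min_mismatches <- function(primer_seq, template) {
  exps <- iupac_expansions(primer_seq)
  em <- do.call(rbind, strsplit(exps, ""))
  tchars <- strsplit(template, "")[[1]]
  L <- ncol(em)
  n <- length(tchars)
  vapply(seq_len(n - L + 1L), function(s) {
    win <- tchars[s:(s + L - 1L)]
    win[win == "N"] <- "?"  # N mismatches every base
    min(rowSums(em != matrix(win, nrow(em), L, byrow = TRUE)))
  }, 0)
}

# oracle: per-column variability scan (>= 2 distinct unambiguous symbols)
brute_variable_count <- function(seqs, start, end, alphabet = "nt") {
  m <- do.call(rbind, strsplit(seqs, ""))
  syms <- if (alphabet == "nt") BASES else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sum(vapply(start:end, function(j) {
    length(unique(m[m[, j] %in% syms, j])) >= 2
  }, NA))
}

# oracle: adjusted Rand index by explicit pair counting
brute_ari <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  n <- length(a)
  pairs <- utils::combn(n, 2)
  s1 <- a[pairs[1, ]] == a[pairs[2, ]]
  s2 <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(s1 & s2); n10 <- sum(s1 & !s2)
  n01 <- sum(!s1 & s2); n00 <- sum(!s1 & !s2)
  M <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / M
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}

# planted-cluster distance matrix: intra in [0, a], inter in [b, c]
planted_matrix <- function(sizes, a = 0.01, b = 0.25, c = 0.35) {
  ids <- unlist(lapply(seq_along(sizes), function(k) {
    paste0("g", k, "_", seq_len(sizes[k]))
  }))
  labels <- rep(seq_along(sizes), sizes)
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dm[i, j] <- dm[j, i] <- if (labels[i] == labels[j]) {
      stats::runif(1, 0, a)
    } else {
      stats::runif(1, b, c)
    }
  }
  attr(dm, "truth") <- stats::setNames(paste0("g", labels), ids)
  attr(dm, "metric") <- "p"
  class(dm) <- c("distance_matrix", "matrix", "array")
  dm
}

# small codon alignment fixture with a conserved Asp/Glu anchor at the end
# of the window, gap-free, frame 1
anchor_alignment <- function(n_seq = 6, n_codons = 10, anchor_aa = "D",
                             code = genetic_code("standard"), seed = 42) {
  set.seed(seed)
  anc <- sample(codons_for(setdiff(unique(code$codon_map), "*"), code),
                n_codons, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(i) {
    cods <- anc
    # synonymous-ish noise at a few codons, anchor codon synonymous only
    cods[n_codons] <- sample(codons_for(anchor_aa, code), 1)
    j <- sample(n_codons - 1, 2)
    cods[j] <- vapply(cods[j], function(cd) {
      aa <- code$codon_map[[cd]]
      sample(codons_for(aa, code), 1)
    }, "")
    paste(cods, collapse = "")
  }, "")
  alignment(stats::setNames(seqs, paste0("s", seq_len(n_seq))), "nt")
}
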