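#' Configuration for the codon-alignment simulator
#'
#' Describes a synthetic barcode study: `n_species` planted species
#' clusters of `n_per_species` individuals each, over `n_codons` codons.
#' A random ancestral codon sequence (sense codons only) is drawn; each
#' species founder accumulates substitutions at per-site rate
#' `inter_sub_rate` from the ancestor, and each individual at rate
#' `intra_sub_rate` from its founder. Substitutions are transition-biased:
#' given an event, a transition is chosen with probability
#' `ti_tv_ratio / (ti_tv_ratio + 1)`, the two transversions equiprobably.
#' Codons listed in `conserved_aa_profile` only ever exchange
#' synonymously: any event hitting such a codon redraws it uniformly from
#' [codons_for()] of its configured amino acid, so the protein is exactly
#' conserved there. Sites are i.i.d. and there are no indels.
#'
#' @param n_species Number of species clusters.
#' @param n_per_species Individuals per species.
#' @param n_codons Alignment length in codons.
#' @param code Genetic code (see [genetic_code()]).
#' @param conserved_aa_profile Named character vector: names are codon
#'   indices (1-based), values one-letter amino-acid symbols (e.g.
#'   `c("10" = "D")`), or `NULL`.
#' @param intra_sub_rate,inter_sub_rate Per-site substitution
#'   probabilities in `[0, 1)` with `intra < inter` (defaults 0.005 and
#'   0.15, a well-separated barcode-gap regime).
#' @param ti_tv_ratio Transition/transversion probability ratio
#'   (default 4).
#' @param seed Mandatory integer seed; simulation is deterministic given
#'   the config.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_species, n_per_species, n_codons,
                       code = genetic_code("standard"),
                       conserved_aa_profile = NULL,
                       intra_sub_rate = 0.005, inter_sub_rate = 0.15,
                       ti_tv_ratio = 4, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (intra_sub_rate < 0 || intra_sub_rate >= 1 ||
      inter_sub_rate < 0 || inter_sub_rate >= 1) {
    stop("substitution rates must be in [0, 1)", call. = FALSE)
  }
  if (intra_sub_rate > inter_sub_rate) {
    stop("intra_sub_rate must not exceed inter_sub_rate", call. = FALSE)
  }
  code <- genetic_code(code)
  if (!is.null(conserved_aa_profile)) {
    idx <- as.integer(names(conserved_aa_profile))
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_codons)) {
      stop("conserved_aa_profile names must be codon indices in 1..n_codons",
           call. = FALSE)
    }
    for (aa in unique(conserved_aa_profile)) {
      codons_for(aa, code) # errors if unsatisfiable under the code
    }
  }
  structure(list(n_species = as.integer(n_species),
                 n_per_species = as.integer(n_per_species),
                 n_codons = as.integer(n_codons), code = code,
                 conserved_aa_profile = conserved_aa_profile,
                 intra_sub_rate = intra_sub_rate,
                 inter_sub_rate = inter_sub_rate,
                 ti_tv_ratio = ti_tv_ratio, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d species x %d individuals, %d codons (code %s), intra %g / inter %g, ti/tv %g, seed %d\n",
    x$n_species, x$n_per_species, x$n_codons, x$code$name,
    x$intra_sub_rate, x$inter_sub_rate, x$ti_tv_ratio, x$seed))
  invisible(x)
}

.transition <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

# mutate 'chars' (base vector) at per-site rate, honouring conserved
# codons; returns list(chars, log) where log is a data.frame of events
.mutate_seq <- function(chars, rate, kappa, conserved_idx, conserved_aa,
                        code, stage, id) {
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  log <- list()
  if (length(hit) == 0L) {
    return(list(chars = chars,
                log = data.frame(id = character(), stage = character(),
                                 site = integer(), from = character(),
                                 to = character())))
  }
  hit_codon <- (hit - 1L) %/% 3L + 1L
  cons_hit <- unique(hit_codon[hit_codon %in% conserved_idx])
  plain_hit <- hit[!(hit_codon %in% conserved_idx)]
  for (s in plain_hit) {
    from <- chars[s]
    to <- if (stats::runif(1) < kappa / (kappa + 1)) .transition[[from]]
      else sample(.transversions[[from]], 1L)
    chars[s] <- to
    log[[length(log) + 1L]] <- data.frame(id = id, stage = stage, site = s,
                                          from = from, to = to)
  }
  for (cd in cons_hit) {
    cols <- (cd - 1L) * 3L + 1:3
    from <- paste(chars[cols], collapse = "")
    aa <- conserved_aa[[as.character(cd)]]
    to <- sample(codons_for(aa, code), 1L)
    chars[cols] <- strsplit(to, "")[[1]]
    log[[length(log) + 1L]] <- data.frame(id = id, stage = stage,
                                          site = cols[1], from = from,
                                          to = to)
  }
  list(chars = chars, log = do.call(rbind, log))
}

#' Simulate a codon alignment with planted species clusters
#'
#' See [sim_config()] for the generative model. Sequence ids are
#' `sp<k>_ind<j>`.
#'
#' @param object A [sim_config()].
#' @param nsim,seed,... Unused (the seed lives in the config); present for
#'   compatibility with the [stats::simulate()] generic.
#' @return A `sim_output`: list with `alignment` (nucleotide
#'   [alignment()]), `true_partition` (named id -> species-label vector),
#'   `ancestor` (string), `mutation_log` (data frame: `id`, `stage`,
#'   `site`, `from`, `to`) and `config`.
#' @export
simulate.sim_config <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  n_nt <- cfg$n_codons * 3L
  sense <- codons_for(setdiff(unique(cfg$code$codon_map), "*"), cfg$code)
  cons_idx <- if (is.null(cfg$conserved_aa_profile)) integer() else
    as.integer(names(cfg$conserved_aa_profile))
  anc_codons <- sample(sense, cfg$n_codons, replace = TRUE)
  for (cd in cons_idx) {
    anc_codons[cd] <- sample(
      codons_for(cfg$conserved_aa_profile[[as.character(cd)]], cfg$code), 1L)
  }
  ancestor <- unlist(strsplit(anc_codons, ""))
  seqs <- character()
  labels <- character()
  logs <- list()
  for (k in seq_len(cfg$n_species)) {
    sp_id <- paste0("sp", k)
    founder <- .mutate_seq(ancestor, cfg$inter_sub_rate, cfg$ti_tv_ratio,
                           cons_idx, cfg$conserved_aa_profile, cfg$code,
                           "inter", sp_id)
    logs[[length(logs) + 1L]] <- founder$log
    for (j in seq_len(cfg$n_per_species)) {
      id <- paste0(sp_id, "_ind", j)
      ind <- .mutate_seq(founder$chars, cfg$intra_sub_rate, cfg$ti_tv_ratio,
                         cons_idx, cfg$conserved_aa_profile, cfg$code,
                         "intra", id)
      logs[[length(logs) + 1L]] <- ind$log
      seqs[[id]] <- paste(ind$chars, collapse = "")
      labels[[id]] <- sp_id
    }
  }
  structure(list(alignment = alignment(seqs, "nt"),
                 true_partition = unlist(labels),
                 ancestor = paste(ancestor, collapse = ""),
                 mutation_log = do.call(rbind, logs),
                 config = cfg),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d sequence(s) x %d nt, %d species, %d mutation event(s)\n",
              length(x$alignment$ids), length(x$alignment),
              x$config$n_species, nrow(x$mutation_log)))
  invisible(x)
}

#' Plant a primer binding site into simulated sequences
#'
#' Overwrites the primer footprint `[at, at + length - 1]` (forward-strand
#' coordinates) in every simulated sequence with one random unambiguous
#' expansion of the primer per sequence (reverse primers are planted as
#' the reverse complement of an expansion), guaranteeing that
#' [find_matches()] finds a 0-mismatch site in every sequence. If the
#' footprint touches a conserved codon, planting is refused unless *every*
#' expansion-compatible codon still encodes the configured amino acid.
#'
#' @param sim A `sim_output` from [simulate.sim_config()].
#' @param primer A [degenerate_primer()].
#' @param at 1-based start coordinate of the footprint.
#' @return A modified `sim_output` (the mutation log is unchanged).
#' @export
plant_primer_site <- function(sim, primer, at) {
  stopifnot(inherits(sim, "sim_output"),
            inherits(primer, "degenerate_primer"))
  cfg <- sim$config
  L <- nchar(primer$seq)
  n_nt <- cfg$n_codons * 3L
  at <- as.integer(at)
  if (at < 1L || at + L - 1L > n_nt) {
    stop(sprintf("footprint [%d, %d] outside sequence bounds [1, %d]",
                 at, at + L - 1L, n_nt), call. = FALSE)
  }
  planted_fwd <- if (primer$orientation == "reverse") revcomp(primer$seq)
    else primer$seq
  site_sets <- strsplit(.iupac_map[strsplit(planted_fwd, "")[[1]]], "")
  cons_idx <- if (is.null(cfg$conserved_aa_profile)) integer() else
    as.integer(names(cfg$conserved_aa_profile))
  # conserved codons overlapped by the footprint must keep their amino
  # acid under every admissible expansion
  m <- aln_matrix(sim$alignment)
  cover <- at:(at + L - 1L)
  for (cd in intersect(cons_idx, unique((cover - 1L) %/% 3L + 1L))) {
    cols <- (cd - 1L) * 3L + 1:3
    aa <- cfg$conserved_aa_profile[[as.character(cd)]]
    for (row in seq_len(nrow(m))) {
      opts <- lapply(cols, function(col) {
        if (col %in% cover) site_sets[[match(col, cover)]] else m[row, col]
      })
      cand <- apply(expand.grid(opts, stringsAsFactors = FALSE), 1L,
                    paste, collapse = "")
      if (!all(cfg$code$codon_map[cand] == aa)) {
        stop(sprintf(
          "footprint contradicts conserved codon %d (%s): expansion could encode %s",
          cd, aa,
          paste(setdiff(unique(cfg$code$codon_map[cand]), aa),
                collapse = ",")), call. = FALSE)
      }
    }
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 1L)
  seqs <- sim$alignment$seqs
  for (i in seq_along(seqs)) {
    fill <- vapply(site_sets, function(s) sample(s, 1L), "")
    substr(seqs[[i]], at, at + L - 1L) <- paste(fill, collapse = "")
  }
  sim$alignment <- alignment(seqs, "nt", ids = sim$alignment$ids)
  sim
}
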