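#' Configuration for barcode-gap partitioning
#'
#' Parameters of the barcode-gap search, mirroring the common ABGD-style
#' names: a geometric (log-spaced) grid of `steps` prior intraspecific
#' divergences from `pmin` to `pmax` (endpoints included), a histogram
#' resolution `nb_bins` used to size the local-slope window, and a minimum
#' relative gap width `x`.
#'
#' @param pmin,pmax Prior intraspecific divergence range (defaults 0.001
#'   and 0.1: from a single-nucleotide difference on a barcode-length
#'   fragment up to 10%).
#' @param steps Number of priors in the geometric grid (default 10).
#' @param nb_bins Number of bins dividing the sorted distances; the local
#'   gap-width window spans `ceiling(m / nb_bins)` consecutive ranks
#'   (default 20).
#' @param x Minimum relative gap width: a candidate gap must exceed `x`
#'   times the local mean difference (default 1.5; on weakly separated data
#'   1.0-1.1 are common fallbacks).
#' @param metric Distance metric label (`"p"`, `"JC69"`, `"K80"`); recorded
#'   in partitions and used by pipeline wrappers.
#' @return A `gap_config` object.
#' @export
gap_config <- function(pmin = 0.001, pmax = 0.1, steps = 10L, nb_bins = 20L,
                       x = 1.5, metric = c("JC69", "K80", "p")) {
  metric <- match.arg(metric)
  if (!(pmin > 0 && pmin < pmax && pmax < 1)) {
    stop("need 0 < pmin < pmax < 1", call. = FALSE)
  }
  if (steps < 2L) stop("steps must be >= 2", call. = FALSE)
  if (x <= 0) stop("x must be > 0", call. = FALSE)
  structure(list(pmin = pmin, pmax = pmax, steps = as.integer(steps),
                 nb_bins = as.integer(nb_bins), x = x, metric = metric),
            class = "gap_config")
}

#' @export
print.gap_config <- function(x, ...) {
  cat(sprintf("<gap_config> priors %g..%g (%d steps), nb_bins %d, X %g, metric %s\n",
              x$pmin, x$pmax, x$steps, x$nb_bins, x$x, x$metric))
  invisible(x)
}

# geometric grid of priors, endpoints included
prior_grid <- function(cfg) {
  exp(seq(log(cfg$pmin), log(cfg$pmax), length.out = cfg$steps))
}

# Find the barcode gap in a set of pairwise distances at prior P.
# Returns the clustering threshold T, or NA if no gap is found.
# m sorted distances d(1..m); consecutive differences g(k) = d(k+1) - d(k);
# local width w(k) = mean of g over a window of max(2, ceiling(m/nb_bins))
# consecutive ranks centred on k (window includes k; see vignette for why
# the window is never a single rank). The gap is the smallest k whose upper
# edge reaches the prior (d(k+1) >= P) with w(k) > 0 and g(k) > X * w(k);
# the prior bounds where the interspecific side of the gap may start, so
# the gap separating distances at most P from the rest is still found when
# its lower edge lies below P (see vignette). T = d(k) + g(k)/2.
find_gap_threshold <- function(dists, prior, nb_bins, x) {
  d <- sort(dists)
  m <- length(d)
  if (m < 2L) return(NA_real_)
  g <- diff(d)
  win <- max(2L, as.integer(ceiling(m / nb_bins)))
  for (k in seq_len(m - 1L)) {
    if (d[k + 1L] < prior) next
    lo <- k - (win - 1L) %/% 2L
    hi <- lo + win - 1L
    if (lo < 1L) { hi <- min(hi + (1L - lo), m - 1L); lo <- 1L }
    if (hi > m - 1L) { lo <- max(1L, lo - (hi - (m - 1L))); hi <- m - 1L }
    w <- mean(g[lo:hi])
    if (w > 0 && g[k] > x * w) {
      return(d[k] + g[k] / 2)
    }
  }
  NA_real_
}

# single-linkage components of the graph joining pairs with d < threshold
single_linkage <- function(dm, threshold) {
  ids <- rownames(dm)
  n <- length(ids)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (dm[i, j] < threshold && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  # relabel contiguously by first appearance
  stats::setNames(match(comp, unique(comp)), ids)
}

new_partition <- function(assignment, prior, threshold, stage, no_gap = FALSE) {
  structure(list(assignment = assignment, prior = prior,
                 threshold = threshold, stage = stage, no_gap = no_gap),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %s, prior %.4g: %d OTU(s)%s\n", x$stage, x$prior,
              max(x$assignment), if (x$no_gap) " [no gap]" else ""))
  invisible(x)
}

#' Number of OTUs in a partition
#' @param p A `partition`.
#' @return Integer count of OTUs.
#' @export
n_otus <- function(p) max(p$assignment)

#' Barcode-gap species partitioning
#'
#' Infers species partitions from a pairwise distance matrix by locating
#' the barcode gap — the gap separating the intraspecific and
#' interspecific parts of the sorted distance distribution — at each prior
#' intraspecific divergence of the configured grid. At prior `P`, the
#' smallest sorted distance `d(k) >= P` whose following difference exceeds
#' `X` times the local mean difference marks the gap; sequences are then
#' clustered by single linkage below the mid-gap threshold (pairs closer
#' than the threshold are conspecific, transitively). The recursive
#' partition reapplies the same search within each group on its submatrix
#' until no group splits further. When no gap is found at a prior, the
#' initial partition is the single all-inclusive group, flagged `no_gap`.
#'
#' @param dm A [distance_matrix()] (n >= 3, no saturated pairs).
#' @param cfg A [gap_config()].
#' @return A `gap_partitions` object: list with one element per prior, each
#'   holding `prior`, `initial` and `recursive` [partition][n_otus]s.
#' @export
barcode_gap_partition <- function(dm, cfg = gap_config()) {
  stopifnot(inherits(cfg, "gap_config"))
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 sequences", call. = FALSE)
  sat <- attr(dm, "saturated_pairs")
  if (!is.null(sat) && nrow(sat) > 0) {
    stop("distance matrix contains saturated pair(s), e.g. (",
         paste(sat[1, ], collapse = ", "),
         "); partitioning refuses saturated inputs", call. = FALSE)
  }
  if (anyNA(dm)) stop("distance matrix contains NA", call. = FALSE)
  ids <- rownames(dm)
  out <- lapply(prior_grid(cfg), function(prior) {
    thr <- find_gap_threshold(dm[upper.tri(dm)], prior, cfg$nb_bins, cfg$x)
    if (is.na(thr)) {
      init <- new_partition(stats::setNames(rep(1L, n), ids), prior,
                            NA_real_, "initial", no_gap = TRUE)
      recur <- new_partition(init$assignment, prior, NA_real_, "recursive",
                             no_gap = TRUE)
    } else {
      assign_init <- single_linkage(dm, thr)
      init <- new_partition(assign_init, prior, thr, "initial")
      recur <- new_partition(
        recurse_partition(dm, assign_init, prior, cfg), prior, thr,
        "recursive")
    }
    list(prior = prior, initial = init, recursive = recur)
  })
  structure(out, class = "gap_partitions", metric = attr(dm, "metric"),
            config = cfg)
}

# split each group of 'assignment' on its submatrix until stable
recurse_partition <- function(dm, assignment, prior, cfg) {
  ids <- rownames(dm)
  repeat {
    changed <- FALSE
    next_assign <- assignment
    label_max <- max(assignment)
    for (grp in unique(assignment)) {
      members <- ids[assignment == grp]
      if (length(members) < 3L) next
      sub <- dm[members, members, drop = FALSE]
      thr <- find_gap_threshold(sub[upper.tri(sub)], prior, cfg$nb_bins,
                                cfg$x)
      if (is.na(thr)) next
      sub_assign <- single_linkage(sub, thr)
      if (max(sub_assign) > 1L) {
        changed <- TRUE
        # keep the group's label for the first sub-group, new labels after
        new_labels <- c(grp, label_max + seq_len(max(sub_assign) - 1L))
        next_assign[members] <- new_labels[sub_assign]
        label_max <- label_max + max(sub_assign) - 1L
      }
    }
    if (!changed) break
    assignment <- next_assign
  }
  stats::setNames(match(assignment, unique(assignment)), ids)
}

#' @export
print.gap_partitions <- function(x, ...) {
  cat(sprintf("<gap_partitions> %d prior(s), metric %s\n", length(x),
              attr(x, "metric")))
  for (e in x) {
    cat(sprintf("  prior %.4g: initial %d OTU(s)%s, recursive %d OTU(s)\n",
                e$prior, n_otus(e$initial),
                if (e$initial$no_gap) " [no gap]" else "",
                n_otus(e$recursive)))
  }
  invisible(x)
}

#' Export partitions as a long-form table
#'
#' @param gp A `gap_partitions` object from [barcode_gap_partition()].
#' @return Data frame with `id`, `otu`, `prior`, `stage`, `no_gap`.
#' @export
partitions_table <- function(gp) {
  do.call(rbind, lapply(gp, function(e) {
    do.call(rbind, lapply(list(e$initial, e$recursive), function(p) {
      data.frame(id = names(p$assignment), otu = unname(p$assignment),
                 prior = p$prior, stage = p$stage, no_gap = p$no_gap)
    }))
  }))
}

#' Compare two partitions of the same sequences
#'
#' Reports whether the induced set-partitions are identical, how many
#' groups of each are exactly matched in the other, how many groups of
#' `p1` are split across several groups of `p2` (and vice versa, merges),
#' and the adjusted Rand index.
#'
#' @param p1,p2 `partition` objects or plain named assignment vectors
#'   (id -> label).
#' @param restrict Optional id subset on which to compare.
#' @return A `partition_comparison`: list with `identical`, `n_matched`,
#'   `n_split`, `n_merged`, `ari`, `n_ids`, `n_otus1`, `n_otus2`.
#' @export
compare_partitions <- function(p1, p2, restrict = NULL) {
  a1 <- if (inherits(p1, "partition")) p1$assignment else p1
  a2 <- if (inherits(p2, "partition")) p2$assignment else p2
  if (is.null(names(a1)) || is.null(names(a2))) {
    stop("assignments must be named by sequence id", call. = FALSE)
  }
  ids <- intersect(names(a1), names(a2))
  if (!is.null(restrict)) ids <- intersect(ids, restrict)
  if (length(ids) == 0L) {
    stop("no shared ids between the two partitions", call. = FALSE)
  }
  a1 <- a1[ids]; a2 <- a2[ids]
  sets1 <- split(ids, a1)
  sets2 <- split(ids, a2)
  key <- function(s) paste(sort(s), collapse = "\r")
  k1 <- vapply(sets1, key, ""); k2 <- vapply(sets2, key, "")
  n_matched <- sum(k1 %in% k2)
  # group of p1 split: its members land in >1 group of p2
  n_split <- sum(vapply(sets1, function(s) length(unique(a2[s])) > 1L, NA))
  n_merged <- sum(vapply(sets2, function(s) length(unique(a1[s])) > 1L, NA))
  structure(list(identical = all(k1 %in% k2) && all(k2 %in% k1),
                 n_matched = n_matched, n_split = n_split,
                 n_merged = n_merged,
                 ari = mclust::adjustedRandIndex(a1, a2),
                 n_ids = length(ids),
                 n_otus1 = length(sets1), n_otus2 = length(sets2)),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf(
    "<partition_comparison> %d ids: %d vs %d OTUs; %s (ARI %.4f, %d matched, %d split, %d merged)\n",
    x$n_ids, x$n_otus1, x$n_otus2,
    if (x$identical) "identical" else "different",
    x$ari, x$n_matched, x$n_split, x$n_merged))
  invisible(x)
}

#' Compare two barcode regions of one alignment
#'
#' Convenience pipeline mirroring a common barcoding question: do a longer
#' and a shorter window of the same alignment support the same species
#' partition, and how does their variability compare? For each window the
#' variable-site statistics, the distance matrix and the barcode-gap
#' partitions are computed; the initial partitions at each prior are then
#' compared.
#'
#' @param aln A nucleotide [alignment()].
#' @param region1,region2 [region_window()]s.
#' @param cfg A [gap_config()].
#' @param ids Optional id subset.
#' @return List with `variability` (data frame per region),
#'   `partitions1`, `partitions2` (gap_partitions) and `concordance`
#'   (data frame per prior: OTU counts, identical flag, ARI).
#' @export
compare_regions <- function(aln, region1, region2, cfg = gap_config(),
                            ids = NULL) {
  if (!is.null(ids)) aln <- subset_ids(aln, ids)
  vs <- lapply(list(region1, region2), function(rg) {
    v <- variable_sites(aln, rg)
    data.frame(region = rg$name, start = rg$start, end = rg$end,
               n_variable = v$n_variable, n_total = v$n_total,
               percent = v$percent)
  })
  gps <- lapply(list(region1, region2), function(rg) {
    barcode_gap_partition(distance_matrix(window.alignment(aln, rg),
                                          cfg$metric), cfg)
  })
  conc <- do.call(rbind, Map(function(e1, e2) {
    cmp <- compare_partitions(e1$initial, e2$initial)
    data.frame(prior = e1$prior, otus1 = n_otus(e1$initial),
               otus2 = n_otus(e2$initial),
               identical = cmp$identical, ari = cmp$ari)
  }, gps[[1]], gps[[2]]))
  list(variability = do.call(rbind, vs), partitions1 = gps[[1]],
       partitions2 = gps[[2]], concordance = conc)
}
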