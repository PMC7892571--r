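test_that("pair distances match their closed forms", {
  # 2 mismatches over 20 sites: p = 0.1
  a20 <- paste(rep(c("A", "C"), each = 10), collapse = "")
  b_jc <- paste(c("G", "G", rep("A", 8), rep("C", 10)), collapse = "")
  jc <- pair_distance(a20, b_jc, "JC69")
  expect_equal(jc$p, 0.1)
  expect_equal(jc$d, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(jc$d, 0.107325632, tolerance = 1e-8)

  # 2 transitions + 1 transversion over 20 sites: P = 0.1, Q = 0.05
  b_k80 <- paste(c("G", "G", rep("A", 8), "A", rep("C", 9)), collapse = "")
  k80 <- pair_distance(a20, b_k80, "K80")
  expect_equal(k80$P, 0.1)
  expect_equal(k80$Q, 0.05)
  expect_equal(k80$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_equal(k80$d, 0.170181165, tolerance = 1e-8)
  expect_equal(k80$p, k80$P + k80$Q)

  ident <- pair_distance("ACGTACGT", "ACGTACGT", "K80")
  expect_equal(ident$d, 0)

  # pairwise deletion of gap/ambiguity columns
  pd <- pair_distance("AC-TRA", "ACGTAN", "p")
  expect_identical(pd$n_compared, 3L)
  expect_equal(pd$d, 0)
  expect_error(pair_distance("---", "ACG", "p"), "no comparable")
})

test_that("JC69 and K80 converge to p at small distances and saturate cleanly", {
  n <- 10000
  one_diff <- paste0("G", paste(rep("A", n - 1), collapse = ""))
  base <- paste(rep("A", n), collapse = "")
  p <- pair_distance(base, one_diff, "p")$d
  jc <- pair_distance(base, one_diff, "JC69")$d
  k80 <- pair_distance(base, one_diff, "K80")$d
  expect_equal(jc / p, 1, tolerance = 1e-3)
  expect_equal(k80 / p, 1, tolerance = 1e-3)
  expect_true(k80 >= p)

  # saturation yields a flagged sentinel, not an error
  sat <- pair_distance(paste(rep("A", 10), collapse = ""),
                       paste(rep("G", 10), collapse = ""), "JC69")
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))
  satk <- pair_distance(paste(rep("A", 10), collapse = ""),
                        paste(rep("G", 10), collapse = ""), "K80")
  expect_true(satk$saturated)
})

test_that("distance matrices agree with ape::dist.dna under pairwise deletion", {
  skip_if_not_installed("ape")
  set.seed(14)
  n <- 8
  anc <- strsplit(random_dna(300), "")[[1]]
  seqs <- vapply(1:n, function(i) {
    s <- anc
    idx <- sample(300, 25)
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(BASES, b), 1), "")
    paste(s, collapse = "")
  }, "")
  aln <- alignment(stats::setNames(seqs, paste0("s", 1:n)))
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  rownames(bin) <- aln$ids
  for (pair in list(c("p", "raw"), c("JC69", "JC69"), c("K80", "K80"))) {
    dm <- distance_matrix(aln, pair[1])
    ref <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                   pairwise.deletion = TRUE))
    expect_equal(unclass(dm), ref[rownames(dm), colnames(dm)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and JC-dominated", {
  set.seed(15)
  anc <- strsplit(random_dna(150), "")[[1]]
  seqs <- vapply(1:5, function(i) {
    s <- anc
    idx <- sample(150, 20)
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(BASES, b), 1), "")
    paste(s, collapse = "")
  }, "")
  aln <- alignment(stats::setNames(seqs, paste0("s", 1:5)))
  p <- distance_matrix(aln, "p")
  jc <- distance_matrix(aln, "JC69")
  expect_equal(unclass(p), t(unclass(p)), ignore_attr = TRUE)
  expect_equal(diag(p), rep(0, 5), ignore_attr = TRUE)
  expect_true(all(jc >= p - 1e-12)) # convexity of the JC transform

  two <- distance_matrix(alignment(c(a = "ACGT", b = "ACGT")), "p")
  expect_equal(unclass(two),
               matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
})

test_that("barcode-gap partitioning recovers planted clusters and flags gapless data", {
  set.seed(16)
  # 3 clusters of 3, intra 0.01, inter 0.30, X = 1.0
  ids <- paste0("s", 1:9)
  lab <- rep(1:3, each = 3)
  dm <- matrix(0.30, 9, 9, dimnames = list(ids, ids))
  dm[outer(lab, lab, "==")] <- 0.01
  diag(dm) <- 0
  attr(dm, "metric") <- "p"
  class(dm) <- c("distance_matrix", "matrix", "array")
  gp <- barcode_gap_partition(dm, gap_config(x = 1.0))
  truth <- stats::setNames(paste0("g", lab), ids)
  for (e in gp) {
    if (e$prior <= 0.01) {
      expect_identical(n_otus(e$initial), 3L)
      expect_equal(compare_partitions(e$initial$assignment, truth)$ari, 1)
    }
  }

  # all distances equal: no gap, one OTU at every prior
  flat <- matrix(0.2, 6, 6, dimnames = list(paste0("s", 1:6),
                                            paste0("s", 1:6)))
  diag(flat) <- 0
  attr(flat, "metric") <- "p"
  class(flat) <- c("distance_matrix", "matrix", "array")
  gp_flat <- barcode_gap_partition(flat, gap_config())
  for (e in gp_flat) {
    expect_true(e$initial$no_gap)
    expect_identical(n_otus(e$initial), 1L)
  }

  expect_error(barcode_gap_partition(flat[1:2, 1:2], gap_config()),
               "at least 3")
})

test_that("recursive partitions split heterogeneity-masked groups and refine initial ones", {
  set.seed(17)
  # cluster 1 = subgroups A and B (tight within, ~0.04-0.05 between);
  # cluster 2 = C, whose intraspecific spread fills the range between
  # those levels so that, globally, the distances below the 0.4 jump form
  # one evenly spaced ramp with no detectable gap: A|B is only separable
  # on the cluster-1 submatrix, i.e. by the recursive pass.
  ids <- c(paste0("a", 1:3), paste0("b", 1:3), paste0("c", 1:6))
  n <- length(ids)
  grp <- c(rep("A", 3), rep("B", 3), rep("C", 6))
  ramp <- seq(0.004, 0.051, length.out = 30)
  pool <- list(intra = ramp[1:6], c_fill = ramp[7:21], ab = ramp[22:30])
  take <- function(what) {
    v <- pool[[what]][1]
    pool[[what]] <<- pool[[what]][-1]
    v
  }
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- if (grp[i] == grp[j]) {
      if (grp[i] == "C") take("c_fill") else take("intra")
    } else if (grp[i] %in% c("A", "B") && grp[j] %in% c("A", "B")) {
      take("ab")
    } else {
      stats::runif(1, 0.39, 0.41)
    }
    dm[i, j] <- dm[j, i] <- d
  }
  attr(dm, "metric") <- "p"
  class(dm) <- c("distance_matrix", "matrix", "array")
  gp <- barcode_gap_partition(dm, gap_config(x = 1.5))
  init2 <- vapply(gp, function(e) n_otus(e$initial), 0L)
  recur3 <- vapply(gp, function(e) n_otus(e$recursive), 0L)
  # initial sees the two clusters; some recursive pass also splits cluster 1
  expect_true(all(init2 == 2L))
  expect_true(any(recur3 == 3L))
  three <- gp[[which(recur3 == 3L)[1]]]$recursive
  expect_equal(
    compare_partitions(three$assignment,
                       stats::setNames(c(rep("A", 3), rep("B", 3),
                                         rep("C", 6)), ids))$ari, 1)

  # refinement: every recursive OTU is a subset of an initial OTU
  for (e in gp) {
    tab <- table(e$recursive$assignment, e$initial$assignment[
      names(e$recursive$assignment)])
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("partitioning is invariant to row order up to relabelling", {
  set.seed(18)
  dm <- planted_matrix(c(4, 3, 5))
  cfg <- gap_config()
  gp1 <- barcode_gap_partition(dm, cfg)
  perm <- sample(nrow(dm))
  dmp <- dm[perm, perm]
  attr(dmp, "metric") <- "p"
  class(dmp) <- c("distance_matrix", "matrix", "array")
  gp2 <- barcode_gap_partition(dmp, cfg)
  for (i in seq_along(gp1)) {
    for (stage in c("initial", "recursive")) {
      expect_equal(
        compare_partitions(gp1[[i]][[stage]]$assignment,
                           gp2[[i]][[stage]]$assignment)$ari, 1)
    }
  }
})

test_that("planted partitions are recovered at any prior inside the gap", {
  set.seed(19)
  for (k in 2:6) {
    dm <- planted_matrix(rep(3, k), a = 0.02, b = 0.25, c = 0.35)
    truth <- attr(dm, "truth")
    gp <- barcode_gap_partition(dm, gap_config())
    for (e in gp) {
      if (e$prior >= 0.02 && e$prior < 0.25) {
        expect_equal(compare_partitions(e$initial$assignment, truth)$ari, 1)
      }
    }
  }
})

test_that("saturated matrices are refused by the partitioner", {
  aln <- alignment(c(a = paste(rep("A", 12), collapse = ""),
                     b = paste(rep("G", 12), collapse = ""),
                     c = paste(rep("A", 12), collapse = "")))
  dm <- distance_matrix(aln, "JC69")
  expect_identical(nrow(attr(dm, "saturated_pairs")), 2L)
  expect_error(barcode_gap_partition(dm, gap_config()), "saturated")
})

test_that("compare_partitions reports identity, splits and pair-counting ARI", {
  p1 <- stats::setNames(c(1, 1, 2, 2, 3, 3), paste0("s", 1:6))
  expect_true(compare_partitions(p1, p1)$identical)
  expect_equal(compare_partitions(p1, p1)$ari, 1)

  split <- stats::setNames(c(1, 4, 2, 2, 3, 3), paste0("s", 1:6))
  cmp <- compare_partitions(p1, split)
  expect_false(cmp$identical)
  expect_identical(cmp$n_split, 1L)
  expect_identical(cmp$n_merged, 0L)
  expect_identical(cmp$n_matched, 2L)
  expect_equal(cmp$ari, brute_ari(p1, split))

  # singletons vs one big group: ARI at or below zero
  singles <- stats::setNames(1:4, paste0("s", 1:4))
  lump <- stats::setNames(rep(1, 4), paste0("s", 1:4))
  expect_true(compare_partitions(singles, lump)$ari <= 0)

  # random partitions agree with the brute-force pair-counting oracle
  set.seed(20)
  for (rep in 1:10) {
    a <- stats::setNames(sample(3, 12, replace = TRUE), paste0("s", 1:12))
    b <- stats::setNames(sample(4, 12, replace = TRUE), paste0("s", 1:12))
    expect_equal(compare_partitions(a, b)$ari, brute_ari(a, b),
                 tolerance = 1e-12)
  }

  expect_error(compare_partitions(
    stats::setNames(1, "x"), stats::setNames(1, "y")), "no shared ids")
})

test_that("phylip and long-form distance exports round-trip", {
  set.seed(21)
  anc <- strsplit(random_dna(80), "")[[1]]
  seqs <- vapply(1:4, function(i) {
    s <- anc
    idx <- sample(80, 10)
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(BASES, b), 1), "")
    paste(s, collapse = "")
  }, "")
  aln <- alignment(stats::setNames(seqs, paste0("seq", 1:4)))
  dm <- distance_matrix(aln, "JC69")
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip_dist(dm, path)
  back <- read_phylip_dist(path)
  expect_equal(back, unclass(dm), tolerance = 1e-7, ignore_attr = TRUE)
  long <- dist_long(dm)
  expect_identical(nrow(long), 6L)
  expect_equal(long$distance[long$id1 == "seq1" & long$id2 == "seq2"],
               dm["seq1", "seq2"])
})
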