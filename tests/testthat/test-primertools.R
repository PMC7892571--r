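test_that("find_matches honours degeneracy, the mismatch cap and the 3' clamp", {
  set.seed(8)
  template <- random_dna(120)
  site <- substr(template, 41, 60)
  p <- degenerate_primer("exact", site, "forward")
  m <- find_matches(p, template)
  expect_identical(m$start[1], 41L)
  expect_identical(m$end[1], 60L)
  expect_identical(m$mismatch_count[1], 0L)
  expect_identical(m$strand[1], "+")

  # R over A counts as a match
  chars <- strsplit(site, "")[[1]]
  chars[5] <- "R"
  tchars <- strsplit(template, "")[[1]]
  tchars[45] <- "A" # template position paired with primer position 5
  template2 <- paste(tchars, collapse = "")
  m2 <- find_matches(degenerate_primer("deg", paste(chars, collapse = ""),
                                       "forward"), template2)
  expect_true(any(m2$start == 41 & m2$mismatch_count == 0))

  # mismatch at the 3'-terminal base excludes the window...
  chars <- strsplit(site, "")[[1]]
  wrong <- setdiff(BASES, chars[20])[1]
  chars[20] <- wrong
  p_term <- degenerate_primer("term", paste(chars, collapse = ""), "forward")
  m3 <- find_matches(p_term, template)
  expect_false(any(m3$start == 41))
  # ...but is visible with the clamp relaxed
  m4 <- find_matches(p_term, template, clamp = 0)
  hit <- m4[m4$start == 41, ]
  expect_identical(hit$mismatch_count, 1L)
  expect_true(hit$terminal_flag)

  # more than max_mismatches excludes
  chars <- strsplit(site, "")[[1]]
  for (i in 3:9) chars[i] <- setdiff(BASES, chars[i])[1]
  m5 <- find_matches(degenerate_primer("many", paste(chars, collapse = ""),
                                       "forward"), template)
  expect_false(any(m5$start == 41))

  # template N is always a mismatch, even against primer N
  tN <- paste0(substr(template, 1, 40), "N", substr(template, 42, 120))
  pN <- strsplit(site, "")[[1]]; pN[1] <- "N"
  mN <- find_matches(degenerate_primer("n", paste(pN, collapse = ""),
                                       "forward"), tN, clamp = 0)
  expect_identical(mN$mismatch_count[mN$start == 41], 1L)

  # primer longer than template: empty result with a warning
  expect_warning(
    empty <- find_matches(p, substr(template, 1, 10)), "longer")
  expect_identical(nrow(empty), 0L)

  expect_error(find_matches(p, "ACGTRCGTACGTACGTACGTACGT"), "unambiguous")
})

test_that("reverse primers are matched on the minus strand with forward coordinates", {
  set.seed(9)
  template <- random_dna(100)
  footprint <- substr(template, 61, 80)
  p <- degenerate_primer("rev", revcomp(footprint), "reverse")
  m <- find_matches(p, template)
  expect_identical(m$start[1], 61L)
  expect_identical(m$end[1], 80L)
  expect_identical(m$strand[1], "-")
  expect_identical(m$mismatch_count[1], 0L)

  # a mismatch at the reverse primer's 3' end sits at the window's LEFT edge
  tchars <- strsplit(template, "")[[1]]
  tchars[61] <- setdiff(BASES, tchars[61])[1]
  m2 <- find_matches(p, paste(tchars, collapse = ""), clamp = 0)
  hit <- m2[m2$start == 61, ]
  expect_true(hit$terminal_flag)
  expect_identical(hit$mismatch_offsets[[1]], 0L)
})

test_that("degenerate matching equals brute-force expansion matching", {
  set.seed(10)
  for (rep in 1:60) {
    L <- sample(15:18, 1)
    template <- random_dna(60)
    if (rep %% 3 == 0) { # sprinkle N into some templates
      tc <- strsplit(template, "")[[1]]
      tc[sample(60, 3)] <- "N"
      template <- paste(tc, collapse = "")
    }
    pseq <- random_primer(L, max_deg = 64)
    p <- degenerate_primer(paste0("p", rep), pseq, "forward")
    oracle <- brute_min_mismatches(pseq, template)
    got <- find_matches(p, template, max_mismatches = L, clamp = 0,
                        template_id = "t")
    got <- got[order(got$start), ]
    expect_identical(got$mismatch_count, as.integer(oracle))
  }
})

test_that("matching agrees with Biostrings fixed-subject semantics", {
  set.seed(11)
  template <- random_dna(300)
  pseq <- random_primer(18, max_deg = 16)
  p <- degenerate_primer("x", pseq, "forward")
  for (k in c(0, 2, 4)) {
    got <- find_matches(p, template, max_mismatches = k, clamp = 0)
    ref <- Biostrings::matchPattern(
      Biostrings::DNAString(pseq), Biostrings::DNAString(template),
      max.mismatch = k, fixed = "subject")
    expect_setequal(got$start, BiocGenerics::start(ref))
  }
})

test_that("mp_scan flags penultimate-position mispairing", {
  # template whose overlapped Gly codon starts with A: a G-ending primer
  # mismatches at its penultimate position when the terminal base matches
  set.seed(12)
  core <- random_dna(18)
  primer <- degenerate_primer("glyG", paste0(core, "GG"), "forward")
  # template carries AG where the primer expects GG (AGR glycine)
  template <- paste0(random_dna(20), core, "AG", random_dna(20))
  scan <- mp_scan(primer, c(t1 = template))
  expect_identical(scan$mismatch_count, 1L)
  expect_true(scan$mp_flag)
  expect_false(scan$terminal_flag)

  # a GA-anchored primer on a GAY/GAR Asp/Glu codon pairs perfectly
  dinF_like <- degenerate_primer("asp", paste0(core, "GA"), "forward")
  for (third in BASES) {
    t2 <- paste0(random_dna(20), core, "GA", third, random_dna(17))
    s2 <- mp_scan(dinF_like, c(t = t2))
    expect_identical(s2$mismatch_count, 0L)
    expect_false(s2$mp_flag)
  }

  # a primer on its own exact site
  own <- mp_scan(primer, c(self = paste0("ACGT", core, "GG", "TTAA")))
  expect_identical(own$mismatch_count, 0L)
  expect_false(own$mp_flag)
})

test_that("amplicon arithmetic spans both footprints and validates orientation", {
  fwd <- data.frame(template_id = "t", start = 1L, end = 29L, strand = "+")
  rev <- data.frame(template_id = "t", start = 834L, end = 856L,
                    strand = "-")
  a <- amplicon(fwd, rev)
  expect_identical(a$start, 1L)
  expect_identical(a$end, 856L)
  expect_identical(a$length, 856L)

  b <- amplicon(data.frame(template_id = "t", start = 10L, end = 34L,
                           strand = "+"),
                data.frame(template_id = "t", start = 100L, end = 120L,
                           strand = "-"))
  expect_identical(b$length, 111L)

  # length is invariant under a coordinate-origin shift
  sh <- amplicon(data.frame(template_id = "t", start = 510L, end = 534L,
                            strand = "+"),
                 data.frame(template_id = "t", start = 600L, end = 620L,
                            strand = "-"))
  expect_identical(sh$length, b$length)

  overlap <- data.frame(template_id = "t", start = 20L, end = 40L,
                        strand = "-")
  expect_error(amplicon(data.frame(template_id = "t", start = 10L,
                                   end = 34L, strand = "+"), overlap),
               "overlap")
  expect_error(amplicon(rev, rev), "forward")
  expect_error(amplicon(fwd, data.frame(template_id = "u", start = 834L,
                                        end = 856L, strand = "-")),
               "different templates")
})

test_that("screen_panel bookkeeping matches planted mismatch counts", {
  set.seed(13)
  site <- random_dna(20)
  p <- degenerate_primer("probe", site, "forward")
  planted <- c(0L, 1L, 2L, 3L, 0L)
  templates <- vapply(planted, function(k) {
    chars <- strsplit(site, "")[[1]]
    if (k > 0) {
      for (i in sample(3:18, k)) chars[i] <- setdiff(BASES, chars[i])[1]
    }
    paste0(random_dna(15), paste(chars, collapse = ""), random_dna(15))
  }, "")
  names(templates) <- paste0("t", seq_along(planted))
  sc <- screen_panel(list(p), templates)
  expect_identical(sc$results$mismatch_count, planted)
  expect_identical(unlist(sc$summary[paste0("le_", 0:6)], use.names = FALSE),
                   c(2L, 3L, 4L, 5L, 5L, 5L, 5L))
  expect_identical(sc$summary$no_site, 0L)

  # a scrambled template with no usable site is reported as such
  sc2 <- screen_panel(list(p), c(junk = paste(rep("A", 60), collapse = "")))
  expect_true(is.na(sc2$results$mismatch_count))
  expect_identical(sc2$summary$no_site, 1L)
})

test_that("primer Tm ranges are ordered and respond to GC content", {
  tm <- primer_tm_range("CGTTGRTTTATRTCTACWAATCATAARGA")
  expect_true(tm[1] <= tm[2])
  at <- primer_tm_range(paste(rep("AT", 10), collapse = ""))
  gc <- primer_tm_range(paste(rep("GC", 10), collapse = ""))
  expect_true(gc[1] > at[2])
})
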