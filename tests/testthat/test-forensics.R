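test_that("TSD calling recovers a planted TGT duplication", {
  set.seed(201)
  locus <- make_tsd_locus("TGT", rand_seq(80), locus_id = "fig9")
  call <- call_tsd(locus)
  expect_equal(call$length, 3L)
  expect_equal(call$sequence, "TGT")
  s <- locus$element_span[1]; e <- locus$element_span[2]
  expect_equal(call$left_span, c(s - 3L, s))
  expect_equal(call$right_span, c(e, e + 3L))
})

test_that("loci without flanking duplication return no TSD", {
  # flanks engineered with different alphabets around the element
  filled <- paste0(strrep("A", 30), strrep("G", 40), strrep("C", 30))
  locus <- locus_alleles("neg", filled, c(30, 70))
  expect_null(call_tsd(locus))
  edge <- locus_alleles("edge", filled, c(1, 70))
  expect_warning(res <- call_tsd(edge), "sequence end")
  expect_null(res)
})

test_that("TSD calls equal planted lengths on clean synthetic loci", {
  cons <- make_consensus(1)
  cfg <- sim_config(seed = 1)
  set.seed(202)
  n_checked <- 0L
  for (i in 1:100) {
    p <- plant_insertion(cons, cfg)
    call <- call_tsd(p$locus)
    # brute-force certification: the called length is always the longest
    # exact flank duplication, whether or not the plant was clean
    s <- p$locus$element_span[1]; e <- p$locus$element_span[2]
    brute <- 0L
    for (k in 2:31) {
      if (substr(p$locus$filled, s - k + 1, s) ==
          substr(p$locus$filled, e + 1, e + k)) brute <- k
    }
    expect_equal(call$length, brute)
    if (p$truth$tsd_clean) {
      expect_equal(call$length, p$truth$tsd_len)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 80)
})

test_that("TSD calling is invariant under reverse complement", {
  cons <- make_consensus(1)
  cfg <- sim_config(seed = 1)
  set.seed(203)
  for (i in 1:20) {
    p <- plant_insertion(cons, cfg)
    fwd <- call_tsd(p$locus)
    n <- nchar(p$locus$filled)
    rc <- locus_alleles(p$locus$locus_id, revcomp(p$locus$filled),
                        c(n - p$locus$element_span[2],
                          n - p$locus$element_span[1]))
    rev <- call_tsd(rc)
    expect_equal(rev$length, fwd$length)
    expect_equal(rev$sequence, revcomp(fwd$sequence))
  }
})

test_that("flank duplication census finds a planted 17-bp duplication", {
  set.seed(204)
  dup <- rand_seq(17)
  left <- paste0(rand_seq(30), dup, rand_seq(10))
  right <- rand_seq(60)
  elem <- rand_seq(80)
  # insertion creates a second copy of `dup` right of the original
  filled <- paste0(left, dup, elem, right)
  empty <- paste0(left, right)
  locus <- locus_alleles("dup17", filled, c(nchar(left) + 17, nchar(left) + 17 + 80),
                         empty = empty)
  calls <- find_flank_duplications(locus)
  expect_gte(nrow(calls), 1)
  expect_equal(calls$length[1], 17)
  expect_equal(calls$seq[1], dup)
  expect_equal(calls$side[1], "5p")
})

test_that("clean insertions yield no flank duplication calls", {
  cons <- make_consensus(1)
  w <- setNames(rep(0, 30), as.character(2:31)); w["4"] <- 1
  cfg <- sim_config(seed = 1, tsd_length_weights = w)
  set.seed(205)
  for (i in 1:10) {
    p <- plant_insertion(cons, cfg)
    if (!p$truth$tsd_clean) next
    calls <- find_flank_duplications(p$locus)
    expect_equal(nrow(calls), 0)
  }
})

test_that("tandem repeat finder matches printed rows and thresholds", {
  set.seed(206)
  # Ls69-style: (CA)14 embedded 48 nt upstream of the junction; the padding
  # is pinned at the array boundaries so the array cannot extend
  up <- paste0(random_dna_avoiding(32, 0.5, c("CACA", "ACAC")), "GG")
  arr <- strrep("CA", 14)
  between <- paste0("TT", random_dna_avoiding(18, 0.5, c("CACA", "ACAC")))
  elem <- rand_seq(60)
  filled <- paste0(up, arr, between, elem, rand_seq(60))
  locus <- locus_alleles("Ls69", filled, c(34 + 28 + 20, 34 + 28 + 20 + 60))
  reps <- locus_flank_repeats(locus)
  ca <- reps[reps$unit %in% c("CA", "AC") & reps$side == "5p", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$copies, 14)
  expect_equal(ca$offset, -48)

  # 2.5 copies are below the copy threshold
  expect_equal(nrow(find_tandem_repeats("ACGTACGTAC")), 0)
  # every Table-3-style array class is admitted
  expect_equal(find_tandem_repeats(paste0("GC", strrep("G", 38), "TC"))$copies, 38)
  expect_equal(find_tandem_repeats(paste0("GT", strrep("TTATTTAA", 3), "GC"))$copies[1], 3)
  long_unit <- "ACTAGGGAACTACCAGGGGG"
  expect_equal(find_tandem_repeats(strrep(long_unit, 14))$copies, 14)
})

test_that("tandem repeat calls equal the exhaustive oracle on short strings", {
  set.seed(207)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    s <- if (i %% 3 == 0) {
      paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")  # repeat-rich
    } else {
      rand_seq(n)
    }
    got <- find_tandem_repeats(s)
    want <- oracle_tandem(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = s)
  }
})

test_that("reported tandem arrays never overlap and decode to their source", {
  set.seed(208)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE,
                      prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    calls <- find_tandem_repeats(s)
    if (nrow(calls) < 1) next
    spans <- cbind(calls$start, calls$start + calls$length)
    if (nrow(calls) > 1) {
      for (a in 1:(nrow(calls) - 1)) {
        for (b in (a + 1):nrow(calls)) {
          expect_true(spans[a, 2] <= spans[b, 1] || spans[b, 2] <= spans[a, 1])
        }
      }
    }
    for (r in seq_len(nrow(calls))) {
      sub <- substr(s, calls$start[r] + 1, calls$start[r] + calls$length[r])
      full <- strrep(calls$unit[r], ceiling(calls$length[r] / nchar(calls$unit[r])))
      expect_equal(sub, substr(full, 1, nchar(sub)))
    }
  }
})

test_that("flank composition recovers planted AT enrichment", {
  mk_locus <- function(at, id) {
    left <- random_dna(60, at); right <- random_dna(60, at)
    elem <- rand_seq(40)
    locus_alleles(id, paste0(left, elem, right), c(60, 100))
  }
  # degenerate inputs
  all_at <- lapply(1:3, function(i) {
    locus_alleles(paste0("at", i),
                  paste0(strrep("AT", 30), strrep("G", 40), strrep("TA", 30)),
                  c(60, 100))
  })
  comp <- flank_composition(all_at)
  expect_equal(comp$mean_at_5p, 1.0)
  expect_lt(comp$test_5p$p, 1e-6)

  fifty <- lapply(1:3, function(i) {
    # period-2 flanks: every 50-nt window is exactly 50% AT
    locus_alleles(paste0("even", i),
                  paste0(strrep("AG", 30), strrep("G", 40), strrep("CT", 30)),
                  c(60, 100))
  })
  comp50 <- flank_composition(fifty)
  expect_equal(comp50$test_5p$t, 0)
  expect_equal(comp50$test_5p$p, 1)
  expect_error(flank_composition(all_at[1]), "2 loci")

  # sampling: mean of per-locus AT at planted probability 0.566, n = 71 loci
  set.seed(209)
  means <- replicate(200, {
    loci <- lapply(1:71, function(i) mk_locus(0.566, paste0("s", i)))
    flank_composition(loci)$mean_at_5p
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.566), 3 * se + 0.005)
})

test_that("flank duplication census matches a quadratic brute-force oracle", {
  brute_census <- function(wf, we, min_len = 10) {
    out <- list()
    nf <- nchar(wf)
    if (nf < min_len) return(out)
    for (len in seq(nf, min_len, by = -1)) {
      for (i in seq_len(nf - len + 1)) {
        p <- substr(wf, i, i + len - 1)
        cf <- sum(vapply(seq_len(nf - len + 1),
                         function(j) substr(wf, j, j + len - 1) == p, logical(1)))
        ce <- if (nchar(we) >= len) {
          sum(vapply(seq_len(nchar(we) - len + 1),
                     function(j) substr(we, j, j + len - 1) == p, logical(1)))
        } else 0
        if (cf >= 2 && cf > ce &&
            !any(vapply(out, function(o) grepl(p, o, fixed = TRUE),
                        logical(1)))) {
          out[[length(out) + 1]] <- p
        }
      }
    }
    out <- unique(unlist(out))
    if (is.null(out)) character(0) else out
  }
  set.seed(210)
  for (i in 1:15) {
    # small synthetic locus with an occasional planted duplication
    dup <- rand_seq(sample(10:14, 1))
    left <- if (i %% 2 == 0) paste0(rand_seq(20), dup, rand_seq(5)) else rand_seq(40)
    elem <- rand_seq(30)
    ins <- if (i %% 2 == 0) dup else ""
    filled <- paste0(left, ins, elem, rand_seq(40))
    empty <- paste0(left, rand_seq(0), rand_seq(40))
    # align empty's right flank with filled's
    empty <- paste0(left, substr(filled, nchar(left) + nchar(ins) + 30 + 1,
                                 nchar(filled)))
    locus <- locus_alleles("cmp", filled,
                           c(nchar(left) + nchar(ins),
                             nchar(left) + nchar(ins) + 30),
                           empty = empty)
    got <- find_flank_duplications(locus, min_len = 10, window = 40)
    s <- locus$element_span[1]
    wf5 <- substr(filled, max(1, s - 40 + 1), s)
    we5 <- substr(empty, max(1, s - 40 + 1), s)
    want5 <- brute_census(wf5, we5)
    expect_setequal(got$seq[got$side == "5p"], want5)
  }
})
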