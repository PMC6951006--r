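test_that("consensus has the canonical tripartite structure and is seeded", {
  cons <- make_consensus(1)
  expect_equal(nchar(cons$record$seq), 208)
  expect_equal(cons$trna_span, c(0L, 75L))
  expect_equal(cons$body_span, c(75L, 152L))
  expect_equal(cons$tail_span, c(152L, 208L))
  tail <- slice_seq(cons$record$seq, 152, 208)
  tc <- classify_tail(tail)
  expect_equal(tc$tgtaa_copies, 5L)
  expect_equal(tc$tail_motif, "TGTAA_polyA")
  expect_identical(make_consensus(1)$record$seq, cons$record$seq)
  expect_false(identical(make_consensus(2)$record$seq, cons$record$seq))
})

test_that("planted insertions carry the requested TSD and are recoverable", {
  cons <- make_consensus(1)
  w <- setNames(rep(0, 30), as.character(2:31)); w["3"] <- 1
  cfg <- sim_config(seed = 1, tsd_length_weights = w, body_indel_prob = 0)
  set.seed(11)
  p <- plant_insertion(cons, cfg, "fig9")
  expect_equal(p$truth$tsd_len, 3L)
  tsd <- call_tsd(p$locus)
  if (p$truth$tsd_clean) expect_equal(tsd$length, 3L)
  # filled = left + TSD + element + TSD + right; empty = left + TSD + right
  s <- p$locus$element_span[1]; e <- p$locus$element_span[2]
  expect_equal(paste0(slice_seq(p$locus$filled, 0, s),
                      slice_seq(p$locus$filled, e + 3, nchar(p$locus$filled))),
               p$locus$empty)
})

test_that("identity 1.0 with no indels plants the consensus verbatim", {
  cons <- make_consensus(1)
  cfg <- sim_config(seed = 1, identity_range = c(1, 1), body_indel_prob = 0,
                    tail_motif_mix = c(polyA = 0, TGTAA = 0, TGTAA_polyA = 1))
  set.seed(3)
  p <- plant_insertion(cons, cfg)
  expect_true(grepl(cons$record$seq, p$locus$filled, fixed = TRUE))
})

test_that("TSD lengths follow the configured multinomial distribution", {
  cons <- make_consensus(1)
  cfg <- sim_config(seed = 1)
  set.seed(99)
  n <- 1000L
  lens <- integer(n)
  for (i in seq_len(n)) {
    lens[i] <- plant_insertion(cons, cfg, sprintf("L%d", i))$truth$tsd_len
  }
  w <- cfg$tsd_length_weights
  counts <- table(factor(lens, levels = names(w)))
  for (k in names(w)) {
    expected <- n * w[[k]]
    sd_k <- sqrt(n * w[[k]] * (1 - w[[k]]))
    expect_lte(abs(counts[[k]] - expected), 3 * sd_k + 1e-9)
  }
  expect_true(all(lens >= 2 & lens <= 31))
  # mass concentrated on 3-8 by default
  expect_gt(mean(lens >= 3 & lens <= 8), 0.7)
})

test_that("planted excisions reconstruct cleanly and recover ground truth", {
  cons <- make_consensus(1)
  cfg <- sim_config(seed = 1, body_indel_prob = 0)
  set.seed(21)
  p <- plant_insertion(cons, cfg, "Ls29")
  # clean excision: no fill, no microhomology, no deletion -> empty allele
  ex0 <- plant_excision(p$locus, "TG", 0, 0, tsd_len = p$truth$tsd_len)
  expect_equal(ex0$excised$seq, p$locus$empty)

  # Ls29-style allele: (TG)x45 fill with an 8-bp microhomology
  ex <- plant_excision(p$locus, "TG", 45, 8, tsd_len = p$truth$tsd_len)
  expect_gte(ex$truth$fill_len, 90)

  # detector recovers (unit, copies, microhomology) on clean random plants
  set.seed(31)
  n_ok <- 0L
  for (i in 1:50) {
    pl <- plant_insertion(cons, cfg, sprintf("E%d", i))
    unit <- sample(c("TG", "CA", "A", "TTA"), 1)
    copies <- sample(8:45, 1)
    mh <- sample(0:8, 1)
    ex <- plant_excision(pl$locus, unit, copies, mh, tsd_len = pl$truth$tsd_len)
    if (!(ex$truth$left_clean && ex$truth$right_clean && ex$truth$mh_clean &&
          pl$truth$tsd_clean)) next
    fp <- call_footprint(pl$locus, ex$excised)
    expect_equal(fp$fill_len, ex$truth$fill_len)
    expect_equal(fp$microhomology_len, mh)
    n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 15)
})

test_that("excision errors on impossible microhomology", {
  cons <- make_consensus(1)
  cfg <- sim_config(seed = 1, flank_len = 40)
  set.seed(4)
  p <- plant_insertion(cons, cfg)
  expect_error(plant_excision(p$locus, "TG", 3, 10000), "microhomology")
})

test_that("genotype simulation respects frequencies and HWE sampling", {
  set.seed(5)
  m1 <- matrix(1, 1, 1, dimnames = list("P", "L"))
  expect_true(all(simulate_genotypes(m1, 20)$genotype == "II"))
  m0 <- matrix(0, 1, 1, dimnames = list("P", "L"))
  expect_true(all(simulate_genotypes(m0, 20)$genotype == "AA"))

  mh <- matrix(0.5, 1, 1, dimnames = list("P", "L"))
  g <- simulate_genotypes(mh, 1e4)
  st <- locus_stats(g)
  se_f <- sqrt(0.5 * 0.5 / (2 * 1e4))
  expect_lt(abs(st$f_sine - 0.5), 3 * se_f)
  se_het <- sqrt(0.5 * 0.5 / 1e4)
  expect_lt(abs(st$het_obs - 0.5), 3 * se_het)
})

test_that("table1_fixture reconstructs the printed survey exactly", {
  tab <- table1_fixture()
  expect_equal(nrow(tab), 300)
  xs40 <- tab[tab$population_id == "XS" & tab$locus_id == "Ls40", ]
  expect_equal(unname(c(sum(xs40$genotype == "II"), sum(xs40$genotype == "IA"),
                        sum(xs40$genotype == "AA"))), c(8, 2, 0))
  py60 <- tab[tab$population_id == "PY" & tab$locus_id == "Ls60", ]
  expect_equal(unname(c(sum(py60$genotype == "II"), sum(py60$genotype == "IA"),
                        sum(py60$genotype == "AA"))), c(0, 10, 0))
  # sampling-free: identical on every call
  expect_identical(table1_fixture(), tab)
})

test_that("simulated qPCR plates follow the log-linear model", {
  set.seed(6)
  plate <- simulate_qpcr(5, noise_sd = 0)
  unk <- plate[plate$role == "unknown", ]
  expect_equal(unique(unk$ct), -3.11 * 5 + 40.838, tolerance = 1e-12)
  expect_equal(unique(unk$ct), 25.288, tolerance = 1e-9)

  std <- plate[plate$role == "standard", ]
  refit <- fit_standard_curve(std$log10_copies, std$ct)
  expect_equal(refit$slope, -3.11, tolerance = 1e-9)
  expect_equal(refit$intercept, 40.838, tolerance = 1e-9)

  expect_error(simulate_qpcr(5, slope = 0.5), "negative")

  # noisy standards: fitted slope within 3 se of truth
  set.seed(7)
  fails <- 0L
  for (r in 1:200) {
    plate <- simulate_qpcr(numeric(0), noise_sd = 0.2, n_reps = 3,
                           standard_log10 = 3:7)
    std <- plate[plate$role == "standard", ]
    fit <- suppressWarnings(stats::lm(ct ~ log10_copies, data = std))
    se <- summary(fit)$coefficients[2, 2]
    if (abs(coef(fit)[2] - (-3.11)) > 3 * se) fails <- fails + 1L
  }
  expect_lt(fails / 200, 0.05)
})

test_that("simulated transcripts plant recoverable region copies", {
  cons <- make_consensus(1)
  set.seed(8)
  tr <- simulate_transcripts(cons, n_full = 3)
  sv <- survey_transcripts(tr, cons)
  expect_equal(sv$n_full_length, 3L)

  none <- simulate_transcripts(cons, n_full = 0)
  expect_equal(nrow(none), 0)
  sv0 <- survey_transcripts(none, cons)
  expect_equal(sv0$n_full_length, 0L)
  expect_equal(unname(sv0$hits_per_region), c(0L, 0L, 0L))

  # random configurations: reported counts equal planted counts
  set.seed(9)
  for (rep in 1:10) {
    nf <- sample(0:3, 1)
    np <- c(trna = sample(0:2, 1), body = sample(0:2, 1), tail = sample(0:3, 1))
    tr <- simulate_transcripts(cons, n_full = nf, n_partial_by_region = np)
    sv <- survey_transcripts(tr, cons)
    expect_equal(sv$n_full_length, nf)
    expect_equal(unname(sv$hits_per_region["trna"]), unname(np["trna"] + nf))
    expect_equal(unname(sv$hits_per_region["body"]), unname(np["body"] + nf))
    expect_equal(unname(sv$hits_per_region["tail"]), unname(np["tail"] + nf))
  }
})

test_that("same seed gives byte-identical synthetic outputs", {
  cons <- make_consensus(1)
  cfg <- sim_config(seed = 1)
  run <- function() {
    set.seed(123)
    p <- plant_insertion(cons, cfg)
    list(p$locus$filled, p$locus$empty, p$truth)
  }
  expect_identical(run(), run())
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(identity_range = c(0, 1.2)), "identity_range")
  expect_error(sim_config(tail_motif_mix = c(polyA = 0.5, TGTAA = 0.2,
                                             TGTAA_polyA = 0.2)), "summing to 1")
  w <- default_tsd_weights(); w[1] <- w[1] + 0.5
  expect_error(sim_config(tsd_length_weights = w), "sum to 1")
})
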