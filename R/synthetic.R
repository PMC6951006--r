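## Seeded synthetic-data generator. Every feature planted here is recorded in
## a ground-truth row and is recoverable by exact string inspection of the
## emitted sequences, so the annotation/forensics stages can be tested against
## known answers. All functions draw from R's current RNG stream; callers
## seed it (set.seed) for reproducibility.

#' Default TSD length weights
#'
#' Target-site duplications span 2-31 nt with most mass on 3-8 nt. The exact
#' length distribution is an artifact choice: weight 0.05 on length 2, 0.80
#' spread evenly over 3-8, and 0.15 decaying geometrically over 9-31.
#'
#' @return A named numeric vector over lengths 2..31 summing to 1.
#' @export
default_tsd_weights <- function() {
  w <- numeric(30)
  names(w) <- as.character(2:31)
  w["2"] <- 0.05
  w[as.character(3:8)] <- 0.80 / 6
  tailw <- 0.7^(0:22)
  w[as.character(9:31)] <- 0.15 * tailw / sum(tailw)
  w
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study. Defaults are
#' the conditions of the C. nasus survey: element identity 77-94% to the
#' 208-bp consensus, TSDs of 2-31 nt concentrated on 3-8 nt, the three tail
#' motif classes, and AT-enriched flanks (A and T at 0.283 each, giving the
#' reported ~56.6% flank AT content).
#'
#' @param seed Integer seed recorded in the config (callers pass it to
#'   `set.seed`).
#' @param n_loci,n_pops,n_ind_per_pop Study dimensions (defaults 20 loci, 6
#'   populations, 10 diploid individuals per population).
#' @param identity_range Fraction range for planted element identity.
#' @param tsd_length_weights Named weights over TSD lengths 2..31.
#' @param tail_motif_mix Probabilities over the tail classes
#'   `polyA`, `TGTAA`, `TGTAA_polyA`.
#' @param excision_fraction Fraction of loci given an excised allele.
#' @param ct_noise_sd Gaussian noise on simulated Ct values, in cycles.
#' @param body_indel_prob Probability that a planted element carries one
#'   3-31 bp body indel.
#' @param flank_len Flank length on each side of a planted insertion, nt.
#' @param flank_at Total A+T probability for random flank sequence.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 20L, n_pops = 6L,
                       n_ind_per_pop = 10L,
                       identity_range = c(0.77, 0.94),
                       tsd_length_weights = default_tsd_weights(),
                       tail_motif_mix = c(polyA = 0.25, TGTAA = 0.25,
                                          TGTAA_polyA = 0.50),
                       excision_fraction = 0.2,
                       ct_noise_sd = 0.2,
                       body_indel_prob = 0.2,
                       flank_len = 150L,
                       flank_at = 0.566) {
  stopifnot(length(identity_range) == 2, identity_range[1] <= identity_range[2])
  if (identity_range[1] <= 0 || identity_range[2] > 1) {
    stop("identity_range must lie within (0, 1]")
  }
  stopifnot(n_loci >= 1, n_pops >= 1, n_ind_per_pop >= 1, flank_len >= 31)
  if (!identical(names(tsd_length_weights), as.character(2:31))) {
    stop("tsd_length_weights must be named over lengths 2..31")
  }
  if (any(tsd_length_weights < 0) || abs(sum(tsd_length_weights) - 1) > 1e-9) {
    stop("tsd_length_weights must be non-negative and sum to 1")
  }
  if (!setequal(names(tail_motif_mix), c("polyA", "TGTAA", "TGTAA_polyA")) ||
      abs(sum(tail_motif_mix) - 1) > 1e-9 || any(tail_motif_mix < 0)) {
    stop("tail_motif_mix must be probabilities over polyA/TGTAA/TGTAA_polyA summing to 1")
  }
  stopifnot(excision_fraction >= 0, excision_fraction <= 1,
            ct_noise_sd >= 0, body_indel_prob >= 0, body_indel_prob <= 1,
            flank_at > 0, flank_at < 1)
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 n_pops = as.integer(n_pops),
                 n_ind_per_pop = as.integer(n_ind_per_pop),
                 identity_range = identity_range,
                 tsd_length_weights = tsd_length_weights,
                 tail_motif_mix = tail_motif_mix[c("polyA", "TGTAA", "TGTAA_polyA")],
                 excision_fraction = excision_fraction,
                 ct_noise_sd = ct_noise_sd,
                 body_indel_prob = body_indel_prob,
                 flank_len = as.integer(flank_len),
                 flank_at = flank_at),
            class = "sim_config")
}

#' Random DNA string
#' @param n Length.
#' @param at Total A+T probability (A and T equiprobable, C and G likewise).
#' @return A DNA string.
#' @export
random_dna <- function(n, at = 0.5) {
  if (n == 0) return("")
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# rejection-sample a random string containing none of the forbidden motifs
random_dna_avoiding <- function(n, at, forbidden, max_try = 1000L) {
  for (i in seq_len(max_try)) {
    s <- random_dna(n, at)
    if (!any(vapply(forbidden, function(f) grepl(f, s, fixed = TRUE), logical(1)))) {
      return(s)
    }
  }
  stop("could not generate sequence avoiding: ", paste(forbidden, collapse = ", "))
}

# concrete realizations of the pol III internal promoter boxes
# (A box consensus TRGCNNARYNNG, B box consensus GWTCRANNC)
ABOX_SEQ <- "TGGCTTAGCTTG"
BBOX_SEQ <- "GTTCGAACC"

#' Generate the 208-bp SINE family consensus
#'
#' Builds a seeded consensus with the canonical tripartite layout: a 75-bp
#' tRNA-related region carrying exact A-box and B-box promoter realizations,
#' a 77-bp body, and a 56-bp tail whose last 36 bp are five tandem TGTAA
#' copies followed by an 11-nt poly(A) run (so the tail classifies as
#' TGTAA-poly(A) with exactly five TGTAA copies).
#'
#' @param seed Integer seed; the same seed yields a byte-identical consensus.
#' @return A [sine_consensus()] object.
#' @export
make_consensus <- function(seed = 1L) {
  set.seed(seed)
  trna <- strsplit(random_dna(75), "")[[1]]
  trna[9:20] <- strsplit(ABOX_SEQ, "")[[1]]
  trna[56:64] <- strsplit(BBOX_SEQ, "")[[1]]
  trna <- paste(trna, collapse = "")
  body <- random_dna(77)
  tail_prefix <- random_dna_avoiding(20, 0.5, c("TGTAA", "AAAAA"))
  tail <- paste0(tail_prefix, strrep("TGTAA", 5), strrep("A", 11))
  seq <- paste0(trna, body, tail)
  stopifnot(nchar(seq) == 208)
  sine_consensus(seq, id = "SINE_consensus")
}

#' Locus allele container
#'
#' Pairs the insertion-bearing (filled) allele of a locus with its
#' insertion-free (empty) allele, when available, and the element span on the
#' filled allele.
#'
#' @param locus_id Locus identifier.
#' @param filled Filled-allele DNA string.
#' @param element_span 0-based half-open span `[s, e)` of the element on the
#'   filled allele (TSD copies lie outside the span).
#' @param empty Optional empty-allele DNA string.
#' @return A list of class `locus_alleles`.
#' @export
locus_alleles <- function(locus_id, filled, element_span, empty = NULL) {
  filled <- toupper(filled)
  s <- element_span[1]; e <- element_span[2]
  stopifnot(length(element_span) == 2, s >= 0, s < e, e <= nchar(filled))
  if (!is.null(empty)) empty <- toupper(empty)
  structure(list(locus_id = locus_id, filled = filled, empty = empty,
                 element_span = c(as.integer(s), as.integer(e))),
            class = "locus_alleles")
}

# mutate `m` positions of seq (1-based indices drawn from `mutable`),
# substitutions only, always to a different base
substitute_positions <- function(seq, mutable, m) {
  chars <- strsplit(seq, "")[[1]]
  pos <- if (m > 0) sample(mutable, m) else integer(0)
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- sample(alt, 1)
  }
  paste(chars, collapse = "")
}

# longest k in [2, 31] with exact N-free flank duplication around [s, e)
longest_flank_match <- function(filled, s, e) {
  kmax <- min(31L, s, nchar(filled) - e)
  best <- 0L
  k <- 2L
  while (k <= kmax) {
    a <- substr(filled, s - k + 1L, s)
    b <- substr(filled, e + 1L, e + k)
    if (a == b && !grepl("N", a, fixed = TRUE)) best <- k
    k <- k + 1L
  }
  best
}

#' Plant a SINE insertion at a synthetic locus
#'
#' Emits an empty allele (random AT-enriched flanks around a target site) and
#' a filled allele in which a mutated element copy is inserted with a
#' target-site duplication: `filled = left + TSD + element + TSD + right`,
#' `empty = left + TSD + right`. Element identity to the consensus is drawn
#' from `cfg$identity_range` (substitutions only, sparing the motif positions
#' that define the planted tail class); TSD length is drawn from
#' `cfg$tsd_length_weights`; one 3-31 bp body indel is added with probability
#' `cfg$body_indel_prob`.
#'
#' @param consensus A [sine_consensus()].
#' @param cfg A [sim_config()].
#' @param locus_id Identifier for the locus.
#' @return A list with elements `locus` (a [locus_alleles()]) and `truth`
#'   (one-row data.frame recording every planted feature, plus `tsd_clean`:
#'   whether the planted TSD is also the longest flank duplication, verified
#'   by brute force).
#' @export
plant_insertion <- function(consensus, cfg, locus_id = "locus1") {
  stopifnot(inherits(consensus, "sine_consensus"), inherits(cfg, "sim_config"))
  k <- as.integer(sample(names(cfg$tsd_length_weights), 1,
                         prob = cfg$tsd_length_weights))
  if (cfg$flank_len < k) stop("flanks shorter than requested TSD length ", k)
  cons <- consensus$record$seq
  n <- nchar(cons)
  tail0 <- consensus$tail_span[1]  # 0-based tail start (152)

  motif <- sample(names(cfg$tail_motif_mix), 1, prob = cfg$tail_motif_mix)
  # rebuild the element tail for the chosen motif class; regenerate until the
  # full tail (including replacement boundaries) carries exactly the class
  chars0 <- strsplit(cons, "")[[1]]
  tgtaa_pos <- (tail0 + 21L):(tail0 + 45L)      # 1-based positions of TGTAAx5
  polya_pos <- (tail0 + 46L):(tail0 + 50L)      # first 5 A's of the A-run
  class_ok <- function(s) {
    tail <- substr(s, tail0 + 1L, nchar(s))
    has_tgtaa <- grepl("TGTAA", tail, fixed = TRUE)
    has_polya <- grepl("AAAAA", tail, fixed = TRUE)
    switch(motif,
           TGTAA = has_tgtaa && !has_polya,
           polyA = !has_tgtaa && has_polya,
           TGTAA_polyA = has_tgtaa && has_polya)
  }
  for (try in 1:100) {
    chars <- chars0
    if (motif == "TGTAA") {
      # no poly(A): replace the 11-nt A-run with A-poor sequence
      repl <- random_dna_avoiding(11, 0.2, c("AAAAA", "TGTAA"))
      chars[(tail0 + 46L):(tail0 + 56L)] <- strsplit(repl, "")[[1]]
      protected <- tgtaa_pos
    } else if (motif == "polyA") {
      # no TGTAA copies: replace the TGTAA block, keep the A-run
      repl <- random_dna_avoiding(25, 0.5, c("TGTAA", "AAAAA"))
      chars[tgtaa_pos] <- strsplit(repl, "")[[1]]
      protected <- polya_pos
    } else {
      protected <- c(tgtaa_pos, polya_pos)
    }
    elem0 <- paste(chars, collapse = "")
    if (class_ok(elem0)) break
    if (try == 100) stop("could not construct tail motif class ", motif)
  }

  ident_target <- runif(1, cfg$identity_range[1], cfg$identity_range[2])
  target_mm <- round((1 - ident_target) * n)
  cons_ch <- strsplit(cons, "")[[1]]
  elem0_ch <- strsplit(elem0, "")[[1]]
  diffs0 <- sum(elem0_ch != cons_ch)   # divergence introduced by the tail class
  mutable <- setdiff(which(elem0_ch == cons_ch), protected)
  m <- min(max(0L, target_mm - diffs0), length(mutable))
  # resample mutations that disturb the planted tail-class signature
  elem <- substitute_positions(elem0, mutable, m)
  tries <- 0L
  while (!class_ok(elem) && tries < 50L) {
    elem <- substitute_positions(elem0, mutable, m)
    tries <- tries + 1L
  }
  if (!class_ok(elem)) stop("could not plant tail motif class ", motif)
  # identity actually planted (substitutions only, before any indel)
  ident <- 1 - sum(strsplit(elem, "")[[1]] != cons_ch) / n
  m <- m + diffs0

  indel_kind <- NA_character_; indel_len <- NA_integer_; indel_pos <- NA_integer_
  if (runif(1) < cfg$body_indel_prob) {
    indel_kind <- sample(c("ins", "del"), 1)
    indel_len <- sample(3:31, 1)
    b0 <- consensus$body_span[1]; b1 <- consensus$body_span[2]
    if (indel_kind == "ins") {
      indel_pos <- sample((b0 + 2L):(b1 - 2L), 1)  # 0-based insertion point
      elem <- paste0(substr(elem, 1, indel_pos), random_dna(indel_len),
                     substr(elem, indel_pos + 1L, nchar(elem)))
    } else {
      indel_pos <- sample((b0 + 2L):(b1 - indel_len - 2L), 1)
      elem <- paste0(substr(elem, 1, indel_pos),
                     substr(elem, indel_pos + indel_len + 1L, nchar(elem)))
    }
  }

  left <- random_dna(cfg$flank_len, cfg$flank_at)
  right <- random_dna(cfg$flank_len, cfg$flank_at)
  tsd <- random_dna(k, cfg$flank_at)
  filled <- paste0(left, tsd, elem, tsd, right)
  empty <- paste0(left, tsd, right)
  s <- nchar(left) + k
  e <- s + nchar(elem)
  locus <- locus_alleles(locus_id, filled, c(s, e), empty = empty)
  tsd_clean <- longest_flank_match(filled, s, e) == k
  truth <- data.frame(locus_id = locus_id, tsd_len = k, tsd_seq = tsd,
                      identity = ident, n_substitutions = m,
                      tail_motif = motif,
                      indel_kind = indel_kind, indel_len = indel_len,
                      indel_pos = indel_pos,
                      element_len = nchar(elem),
                      tsd_clean = tsd_clean, stringsAsFactors = FALSE)
  list(locus = locus, truth = truth)
}

# longest suffix of `fill` equal to a prefix of `after`, searched up to `cap`
longest_suffix_prefix <- function(fill, after, cap = 25L) {
  kmax <- min(cap, nchar(fill), nchar(after))
  best <- 0L
  for (k in seq_len(kmax)) {
    if (substr(fill, nchar(fill) - k + 1L, nchar(fill)) == substr(after, 1L, k)) {
      best <- k
    }
  }
  best
}

#' Plant an excision allele for an inserted locus
#'
#' Constructs the allele left by imperfect element removal: the element plus
#' one TSD copy is excised (optionally with small flank deletions) and the gap
#' is refilled with a tandem microsatellite plus a terminal microhomology
#' copied from the retained 3' junction:
#' `excised = left' + unit x copies + microhomology + retained-right`.
#' With `copies = 0`, `microhomology_len = 0` and no deletions the excised
#' allele equals the empty allele.
#'
#' @param locus A [locus_alleles()] with a planted element.
#' @param unit Microsatellite repeat unit (primitive, 1-20 nt).
#' @param copies Number of unit copies in the fill.
#' @param microhomology_len Length of the microhomology with the retained 3'
#'   flank (0-25 nt).
#' @param del_left,del_right Flank bases deleted beyond the element + TSD on
#'   each side.
#' @param tsd_len Planted TSD length; if `NULL` it is recomputed by brute
#'   force from the filled allele.
#' @return A list with `excised` (a one-row sequence record data.frame) and
#'   `truth` (planted values, the effective values a footprint caller should
#'   recover, and cleanliness flags computed by direct string inspection).
#' @export
plant_excision <- function(locus, unit, copies, microhomology_len,
                           del_left = 0L, del_right = 0L, tsd_len = NULL) {
  stopifnot(inherits(locus, "locus_alleles"), copies >= 0,
            microhomology_len >= 0, del_left >= 0, del_right >= 0)
  filled <- locus$filled
  s <- locus$element_span[1]; e <- locus$element_span[2]
  k <- if (is.null(tsd_len)) longest_flank_match(filled, s, e) else as.integer(tsd_len)
  if (s - k - del_left < 0) stop("left deletion exceeds available flank")
  retained_left <- slice_seq(filled, 0L, s - k - del_left)
  if (e + del_right > nchar(filled)) stop("right deletion exceeds available flank")
  retained_right <- slice_seq(filled, e + del_right, nchar(filled))
  if (microhomology_len > nchar(retained_right)) {
    stop("microhomology_len larger than retained flank")
  }
  fillcore <- strrep(unit, copies)
  mh <- substr(retained_right, 1L, microhomology_len)
  fill <- paste0(fillcore, mh)
  excised <- paste0(retained_left, fill, retained_right)

  # cleanliness: will exact end-anchoring recover exactly the planted values?
  after_left <- paste0(fill, retained_right)
  left_clean <- nchar(retained_left) == 0 || nchar(after_left) == 0 ||
    substr(filled, s - k - del_left + 1L, s - k - del_left + 1L) !=
    substr(after_left, 1L, 1L)
  before_right_x <- paste0(retained_left, fill)
  right_clean <- nchar(before_right_x) == 0 || (e + del_right) == 0 ||
    substr(filled, e + del_right, e + del_right) !=
    substr(before_right_x, nchar(before_right_x), nchar(before_right_x))
  mh_eff <- longest_suffix_prefix(fill, retained_right)
  # forward extension of the unit periodicity from the fill core into the
  # microhomology: the detected array is longer than planted when the copied
  # junction bases continue the repeat
  u <- nchar(unit)
  ext <- 0L
  if (copies > 0) {
    while (ext < nchar(mh) &&
           substr(fill, nchar(fillcore) + ext + 1L, nchar(fillcore) + ext + 1L) ==
           substr(fill, nchar(fillcore) + ext + 1L - u, nchar(fillcore) + ext + 1L - u)) {
      ext <- ext + 1L
    }
  }
  truth <- data.frame(locus_id = locus$locus_id,
                      unit = unit, copies = copies,
                      microhomology_len = microhomology_len,
                      del_left = del_left, del_right = del_right,
                      tsd_len = k,
                      fill_len = nchar(fill),
                      mh_effective = mh_eff,
                      left_clean = left_clean, right_clean = right_clean,
                      mh_clean = mh_eff == microhomology_len,
                      repeat_ext = ext,
                      repeat_clean = copies == 0 || 2L * ext < u,
                      stringsAsFactors = FALSE)
  list(excised = data.frame(id = paste0(locus$locus_id, ".excised"), desc = "",
                            seq = excised, stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate diploid presence/absence genotypes under HWE sampling
#'
#' For each individual, two alleles are drawn independently with the stated
#' insertion frequency (binomial sampling under Hardy-Weinberg equilibrium).
#'
#' @param freqs A matrix of insertion frequencies with populations as rows and
#'   loci as columns (dimnames required), or a data.frame with columns
#'   `population_id`, `locus_id`, `f`.
#' @param n_ind Diploid individuals per population.
#' @return A [locus_table()].
#' @export
simulate_genotypes <- function(freqs, n_ind) {
  if (is.matrix(freqs)) {
    stopifnot(!is.null(rownames(freqs)), !is.null(colnames(freqs)))
    freqs <- data.frame(population_id = rep(rownames(freqs), ncol(freqs)),
                        locus_id = rep(colnames(freqs), each = nrow(freqs)),
                        f = as.vector(freqs), stringsAsFactors = FALSE)
  }
  stopifnot(all(freqs$f >= 0), all(freqs$f <= 1), n_ind >= 1)
  rows <- lapply(seq_len(nrow(freqs)), function(i) {
    g <- rbinom(n_ind, 2L, freqs$f[i])
    data.frame(locus_id = freqs$locus_id[i],
               population_id = freqs$population_id[i],
               individual_id = sprintf("%s_%02d", freqs$population_id[i],
                                       seq_len(n_ind)),
               genotype = c("AA", "IA", "II")[g + 1L],
               stringsAsFactors = FALSE)
  })
  locus_table(do.call(rbind, rows))
}

#' Deterministic genotype table reproducing the published population survey
#'
#' Reconstructs, by exact integer arithmetic (no sampling), a genotype table
#' of 10 diploid individuals per population whose per-locus per-population
#' insertion frequency and observed heterozygosity equal the published values
#' in [cnasus_locus_reference()]. For each cell, heterozygote count
#' `het_n = round(Het * n)`, `n_II = round(f * n - het_n / 2)`,
#' `n_AA = n - n_II - het_n`; the construction is validated to reproduce the
#' printed (f, Het) pair exactly and errors naming the cell otherwise.
#'
#' @return A [locus_table()] with 6 populations x 10 individuals x 5 loci =
#'   300 rows.
#' @export
table1_fixture <- function() {
  ref <- cnasus_locus_reference()
  n <- 10L
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    f <- ref$f[i]; het <- ref$het[i]
    het_n <- as.integer(round(het * n))
    ii <- as.integer(round(f * n - het_n / 2))
    aa <- n - ii - het_n
    cell <- paste0(ref$population_id[i], "/", ref$locus_id[i])
    if (ii < 0 || aa < 0 ||
        abs((2 * ii + het_n) / (2 * n) - f) > 1e-9 ||
        abs(het_n / n - het) > 1e-9) {
      stop("printed (f, Het) pair not representable with n=10 diploids in cell ",
           cell)
    }
    data.frame(locus_id = ref$locus_id[i],
               population_id = ref$population_id[i],
               individual_id = sprintf("%s_%02d", ref$population_id[i], 1:n),
               genotype = rep(c("II", "IA", "AA"), times = c(ii, het_n, aa)),
               stringsAsFactors = FALSE)
  })
  locus_table(do.call(rbind, rows))
}

#' Simulate a qPCR plate with a log-linear dilution series
#'
#' Ct values follow `Ct = slope * log10(copies) + intercept + noise`, the
#' standard-curve model of absolute quantification. Standards are a dilution
#' series flagged `role = "standard"`; unknowns carry an input DNA mass so
#' copies per genome can be derived downstream.
#'
#' @param unknown_log10_copies Numeric vector of true log10 copy numbers in
#'   the unknown reactions.
#' @param slope,intercept Standard-curve parameters (slope must be negative).
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param n_reps Replicates per sample.
#' @param standard_log10 log10 copy numbers of the dilution series.
#' @param input_mass_pg Input DNA mass per unknown reaction, pg.
#' @param sample_ids Optional ids for the unknowns.
#' @return A plate data.frame with columns `sample_id`, `role`,
#'   `log10_copies`, `ct`, `input_mass_pg`, `replicate`.
#' @export
simulate_qpcr <- function(unknown_log10_copies, slope = -3.11,
                          intercept = 40.838, noise_sd = 0, n_reps = 3L,
                          standard_log10 = 3:7, input_mass_pg = 10000,
                          sample_ids = NULL) {
  if (slope >= 0) stop("standard-curve slope must be negative")
  stopifnot(all(is.finite(unknown_log10_copies)), noise_sd >= 0, n_reps >= 1)
  if (any(10^standard_log10 <= 0)) stop("non-positive standard copy numbers")
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample%02d", seq_along(unknown_log10_copies))
  }
  mk <- function(ids, role, x, mass) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      ct <- slope * x[i] + intercept + rnorm(n_reps, 0, noise_sd)
      data.frame(sample_id = ids[i], role = role,
                 log10_copies = if (role == "standard") x[i] else NA_real_,
                 ct = ct, input_mass_pg = mass,
                 replicate = seq_len(n_reps), stringsAsFactors = FALSE)
    }))
  }
  std <- mk(sprintf("std_1e%g", standard_log10), "standard", standard_log10,
            NA_real_)
  unk <- mk(sample_ids, "unknown", unknown_log10_copies, input_mass_pg)
  rbind(std, unk)
}

#' Simulate transcriptome contigs with embedded SINE copies
#'
#' Emits contigs of random sequence embedding either a full-length consensus
#' copy or a single region (tRNA-related, body or tail), on a random strand,
#' mirroring what a transcript survey should recover.
#'
#' @param consensus A [sine_consensus()].
#' @param n_full Number of contigs with a complete element copy.
#' @param n_partial_by_region Named counts over `trna`, `body`, `tail`.
#' @param contig_len Contig length, nt.
#' @return A sequence record data.frame (columns `id`, `desc`, `seq`).
#' @export
simulate_transcripts <- function(consensus, n_full,
                                 n_partial_by_region = c(trna = 0L, body = 0L,
                                                         tail = 0L),
                                 contig_len = 500L) {
  stopifnot(inherits(consensus, "sine_consensus"))
  miss <- setdiff(c("trna", "body", "tail"), names(n_partial_by_region))
  n_partial_by_region[miss] <- 0L
  cons <- consensus$record$seq
  inserts <- c(rep(list(cons), n_full),
               rep(list(slice_seq(cons, consensus$trna_span[1], consensus$trna_span[2])),
                   n_partial_by_region[["trna"]]),
               rep(list(slice_seq(cons, consensus$body_span[1], consensus$body_span[2])),
                   n_partial_by_region[["body"]]),
               rep(list(slice_seq(cons, consensus$tail_span[1], consensus$tail_span[2])),
                   n_partial_by_region[["tail"]]))
  kinds <- c(rep("full", n_full),
             rep("trna", n_partial_by_region[["trna"]]),
             rep("body", n_partial_by_region[["body"]]),
             rep("tail", n_partial_by_region[["tail"]]))
  if (length(inserts) == 0) {
    return(data.frame(id = character(0), desc = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_along(inserts), function(i) {
    ins <- inserts[[i]]
    pad <- max(contig_len - nchar(ins), 20L)
    left_n <- sample.int(pad, 1) - 1L
    seq <- paste0(random_dna(left_n), ins, random_dna(pad - left_n))
    if (runif(1) < 0.5) seq <- revcomp(seq)
    data.frame(id = sprintf("contig_%s_%02d", kinds[i], i), desc = kinds[i],
               seq = seq, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
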