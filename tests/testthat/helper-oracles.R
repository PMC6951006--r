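# Independent brute-force oracles used to certify the package's dynamic
# programming, exact-test and variance-partition routines on small inputs.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- global alignment: top-down recursion over all alignments -------------

oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0 && j == 0) 0
    else {
      opts <- c()
      if (i > 0 && j > 0) {
        s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
        opts <- c(opts, rec(i - 1, j - 1) + s)
      }
      if (i > 0) opts <- c(opts, rec(i - 1, j) + gap)
      if (j > 0) opts <- c(opts, rec(i, j - 1) + gap)
      max(opts)
    }
    memo[[key]] <- v
    v
  }
  rec(length(ca), length(cb))
}

# independent reference implementation (affine with zero opening = linear gap)
biostrings_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  mat <- matrix(mismatch, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                c("A", "C", "G", "T")))
  diag(mat) <- match
  as.numeric(Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 0,
                                           gapExtension = -gap,
                                           scoreOnly = TRUE))
}

# ---- maximum base pairing: recursive enumeration --------------------------

oracle_max_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ok <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AT", "TA", "GC", "CG") || (allow_gu && p %in% c("GT", "TG"))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (ok(ch[i], ch[k])) {
        inner <- if (k - i - 1 > min_loop) rec(i + 1, k - 1) else 0L
        right <- if (k < j) rec(k + 1, j) else 0L
        best <- max(best, 1L + inner + right)
      }
    }
    best
  }
  rec(1L, length(ch))
}

# ---- HWE exact test: polynomial-expansion enumeration ---------------------

# distribution of heterozygote counts given n individuals and nI insertion
# alleles, by expanding prod_i (1 + 2*z*x + x^2) where x marks an insertion
# allele and z a heterozygote; weight[a+1, h+1] = #ways to reach a alleles
# and h heterozygotes
oracle_hwe_p <- function(n_II, n_IA, n_AA) {
  n <- n_II + n_IA + n_AA
  nI <- 2 * n_II + n_IA
  if (nI == 0 || nI == 2 * n) return(1)
  nr <- 2 * n + 1; nc <- n + 1
  W <- matrix(0, nrow = nr, ncol = nc)
  W[1, 1] <- 1
  for (ind in seq_len(n)) {
    W2 <- W                                                    # AA: no change
    W2[2:nr, 2:nc] <- W2[2:nr, 2:nc] +
      2 * W[1:(nr - 1), 1:(nc - 1)]                            # IA: a+1, h+1
    W2[3:nr, ] <- W2[3:nr, ] + W[1:(nr - 2), ]                 # II: a+2
    W <- W2
  }
  w <- W[nI + 1, ]                   # weights over het counts 0..n
  probs <- w / sum(w)
  obs <- probs[n_IA + 1]
  sum(probs[probs <= obs + 1e-12])
}

# ---- tandem repeats: exhaustive (start, unit, end) enumeration ------------

oracle_tandem <- function(seq, max_unit = 20, min_copies = 3, min_len = 8) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  is_prim <- function(unit) {
    u <- nchar(unit)
    if (u == 1) return(TRUE)
    for (d in seq_len(u %/% 2)) {
      if (u %% d == 0 && strrep(substr(unit, 1, d), u / d) == unit) return(FALSE)
    }
    TRUE
  }
  decodes <- function(start, len, u) {
    unit <- substr(seq, start, start + u - 1)
    full <- strrep(unit, ceiling(len / u))
    substr(full, 1, len) == substr(seq, start, start + len - 1)
  }
  cand <- list()
  for (u in seq_len(min(max_unit, n %/% 2))) {
    for (start in seq_len(n - 2 * u + 1)) {
      unit <- substr(seq, start, start + u - 1)
      if (grepl("N", unit, fixed = TRUE) || !is_prim(unit)) next
      # longest decodable extension from this start
      len <- u
      while (start + len <= n &&
             ch[start + len] == ch[start + len - u] && ch[start + len] != "N") {
        len <- len + 1
      }
      # maximality to the left
      if (start > 1 && ch[start - 1] == ch[start - 1 + u] && ch[start - 1] != "N") next
      part <- len %% u
      if (part > 0 && part * 2 < u) len <- len - part
      copies <- len / u
      if (len < min_len || copies < min_copies) next
      if (!decodes(start, len, u)) next
      cand[[length(cand) + 1]] <- data.frame(unit = unit, copies = copies,
                                             start = start - 1, length = len,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) {
    return(data.frame(unit = character(0), copies = numeric(0),
                      start = integer(0), length = integer(0)))
  }
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(-cand$length, nchar(cand$unit), cand$start), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, ]
    if (!any(vapply(kept, function(b) a$start < b$start + b$length &&
                      b$start < a$start + a$length, logical(1)))) {
      kept[[length(kept) + 1]] <- a
    }
  }
  res <- do.call(rbind, kept)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- AMOVA: pairwise squared-distance sums of squares ---------------------

oracle_amova_ss <- function(X, pop, grp) {
  N <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  ss_among_set <- function(ix) sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
  ss_t <- ss_among_set(seq_len(N))
  ss_wp <- sum(vapply(split(seq_len(N), pop), ss_among_set, numeric(1)))
  ss_wg <- sum(vapply(split(seq_len(N), grp), ss_among_set, numeric(1)))
  c(among_groups = ss_t - ss_wg, among_pops = ss_wg - ss_wp, within = ss_wp)
}

# ---- misc builders --------------------------------------------------------

# a locus with an explicitly constructed TSD; flanks drawn until the planted
# TSD is the longest flank duplication
make_tsd_locus <- function(tsd, element, flank = 60, locus_id = "L",
                           with_empty = TRUE) {
  repeat {
    left <- rand_seq(flank); right <- rand_seq(flank)
    filled <- paste0(left, tsd, element, tsd, right)
    s <- nchar(left) + nchar(tsd); e <- s + nchar(element)
    k <- 0L
    for (kk in 2:min(31, s, nchar(filled) - e)) {
      if (substr(filled, s - kk + 1, s) == substr(filled, e + 1, e + kk)) k <- kk
    }
    if (k == nchar(tsd)) {
      empty <- if (with_empty) paste0(left, tsd, right) else NULL
      return(locus_alleles(locus_id, filled, c(s, e), empty = empty))
    }
  }
}

# random additive tree -> distance matrix + cherry structure, for NJ tests
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
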