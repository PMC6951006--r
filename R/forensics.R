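#' Call the target-site duplication at an inserted locus
#'
#' Reports the longest k in 2..31 for which the k bases immediately 5' of the
#' element equal the k bases immediately 3' of it (exact match; N never
#' matches). By convention the TSD copies flank the element and are not
#' counted inside the element span.
#'
#' @param locus A [locus_alleles()].
#' @return A list of class `tsd_call` with `length`, `sequence`, `left_span`,
#'   `right_span` (0-based half-open on the filled allele), or `NULL` when no
#'   flanking duplication of length >= 2 exists (with a warning when the
#'   element span touches a sequence end).
#' @export
call_tsd <- function(locus) {
  stopifnot(inherits(locus, "locus_alleles"))
  filled <- locus$filled
  s <- locus$element_span[1]; e <- locus$element_span[2]
  if (s < 2 || nchar(filled) - e < 2) {
    warning("element span touches a sequence end; no TSD call possible")
    return(NULL)
  }
  k <- longest_flank_match(filled, s, e)
  if (k < 2) return(NULL)
  structure(list(length = k,
                 sequence = slice_seq(filled, s - k, s),
                 left_span = c(s - k, s),
                 right_span = c(e, e + k)),
            class = "tsd_call")
}

# overlapping occurrence count of `pat` in `x` (exact, fixed)
count_occurrences <- function(x, pat) {
  if (nchar(pat) > nchar(x)) return(0L)
  hits <- gregexpr(paste0("(?=", gsub("([.\\\\+*?\\[^\\]$(){}=!<>|:-])", "\\\\\\1", pat), ")"),
                   x, perl = TRUE)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}

#' Find insertion-generated duplications in the flanks
#'
#' Compares the sequence windows flanking the element junctions on the filled
#' allele with the corresponding windows of the empty allele and reports
#' maximal exact segments of length >= `min_len` that are repeated in the
#' filled window (>= 2 occurrences) and occur more often there than in the
#' empty window - i.e. repeats created by the insertion event. Windows are
#' `window` nt on each side of the junctions;
#' the empty-allele windows are taken around the insertion point so that a
#' clean insertion (identical outside element + TSD) yields no calls.
#'
#' @param locus A [locus_alleles()] with an empty allele.
#' @param min_len Minimum duplication length (default 10).
#' @param window Window size in nt (default 100).
#' @return A data.frame with columns `side` ("5p"/"3p"), `length`, `seq`,
#'   `count_filled`, `count_empty`, sorted by decreasing length.
#' @export
find_flank_duplications <- function(locus, min_len = 10L, window = 100L) {
  stopifnot(inherits(locus, "locus_alleles"))
  if (is.null(locus$empty)) stop("empty allele required")
  filled <- locus$filled; empty <- locus$empty
  s <- locus$element_span[1]; e <- locus$element_span[2]
  tsd <- call_tsd(locus)
  k <- if (is.null(tsd)) 0L else tsd$length
  w5f <- slice_seq(filled, max(0L, s - window), s)
  w5e <- slice_seq(empty, max(0L, s - window), min(s, nchar(empty)))
  r3f <- min(nchar(filled), e + window)
  w3f <- slice_seq(filled, e, r3f)
  e3s <- max(0L, s - k)
  w3e <- slice_seq(empty, e3s, min(nchar(empty), e3s + window))
  census_side <- function(wf, we, side) {
    out <- list()
    nf <- nchar(wf); ne <- nchar(we)
    if (nf < min_len) return(out)
    for (len in seq(from = nf, to = min_len, by = -1L)) {
      sf <- substring(wf, 1L:(nf - len + 1L), len:nf)
      tf <- table(sf)
      te <- if (ne >= len) table(substring(we, 1L:(ne - len + 1L), len:ne))
            else table(character(0))
      for (p in names(tf)) {
        if (grepl("N", p, fixed = TRUE)) next
        cf <- as.integer(tf[[p]])
        ce <- if (p %in% names(te)) as.integer(te[[p]]) else 0L
        if (cf >= 2L && cf > ce) {
          covered <- any(vapply(out, function(o) grepl(p, o$seq, fixed = TRUE),
                                logical(1)))
          if (!covered) {
            out[[length(out) + 1L]] <- data.frame(side = side, length = len,
                                                  seq = p, count_filled = cf,
                                                  count_empty = ce,
                                                  stringsAsFactors = FALSE)
          }
        }
      }
    }
    out
  }
  res <- c(census_side(w5f, w5e, "5p"), census_side(w3f, w3e, "3p"))
  if (length(res) == 0) {
    return(data.frame(side = character(0), length = integer(0),
                      seq = character(0), count_filled = integer(0),
                      count_empty = integer(0)))
  }
  res <- do.call(rbind, res)
  res[order(-res$length, res$side, res$seq), , drop = FALSE]
}

# TRUE if unit is primitive (not itself a tandem repetition)
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u %/% 2)) {
    if (u %% d == 0L && strrep(substr(unit, 1L, d), u %/% d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find tandem microsatellite arrays
#'
#' Detects all maximal tandem arrays with a primitive unit of 1-20 nt, at
#' least 3 copies and total length >= 8 nt. A trailing partial copy is kept
#' only when it spans at least half the unit. Overlapping reports are
#' collapsed to the longest array (ties: smallest unit, then leftmost).
#'
#' @param seq DNA string.
#' @param max_unit Maximum unit length (default 20).
#' @param min_copies Minimum (possibly fractional) copy number (default 3).
#' @param min_len Minimum array length in nt (default 8).
#' @return A data.frame with columns `unit`, `copies`, `start` (0-based),
#'   `length`, sorted by position.
#' @export
find_tandem_repeats <- function(seq, max_unit = 20L, min_copies = 3,
                                min_len = 8L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < min_len) {
    return(data.frame(unit = character(0), copies = numeric(0),
                      start = integer(0), length = integer(0)))
  }
  chars <- strsplit(seq, "")[[1]]
  cand <- list()
  for (u in seq_len(min(max_unit, n %/% 2))) {
    m <- chars[seq_len(n - u)] == chars[(u + 1L):n] & chars[seq_len(n - u)] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      arr_start <- starts[i]            # 1-based
      arr_len <- r$lengths[i] + u
      # trim a trailing partial copy shorter than half the unit
      part <- arr_len %% u
      if (part > 0 && part * 2 < u) arr_len <- arr_len - part
      copies <- arr_len / u
      if (arr_len < min_len || copies < min_copies) next
      unit <- substr(seq, arr_start, arr_start + u - 1L)
      if (!is_primitive_unit(unit) || grepl("N", unit, fixed = TRUE)) next
      cand[[length(cand) + 1L]] <- data.frame(unit = unit, copies = copies,
                                              start = arr_start - 1L,
                                              length = arr_len,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) {
    return(data.frame(unit = character(0), copies = numeric(0),
                      start = integer(0), length = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$length, nchar(cand$unit), cand$start), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, ]
    overlaps <- any(vapply(kept, function(b) {
      a$start < b$start + b$length && b$start < a$start + a$length
    }, logical(1)))
    if (!overlaps) kept[[length(kept) + 1L]] <- a
  }
  res <- do.call(rbind, kept)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tandem repeats in the flanks of an inserted locus
#'
#' Runs [find_tandem_repeats()] on the flanking windows of the element (TSD
#' excluded) and reports array positions as signed offsets from the element
#' junction: negative upstream of the 5' junction, positive downstream of the
#' 3' junction (the offset of an array is the junction-proximal distance of
#' its start).
#'
#' @param locus A [locus_alleles()].
#' @param window Flank window length, nt.
#' @return A data.frame with columns `locus_id`, `side`, `unit`, `copies`,
#'   `offset`, `length`.
#' @export
locus_flank_repeats <- function(locus, window = 100L) {
  stopifnot(inherits(locus, "locus_alleles"))
  filled <- locus$filled
  s <- locus$element_span[1]; e <- locus$element_span[2]
  tsd <- call_tsd(locus)
  k <- if (is.null(tsd)) 0L else tsd$length
  w5_start <- max(0L, s - k - window)
  w5 <- slice_seq(filled, w5_start, s - k)
  w3_start <- min(e + k, nchar(filled))
  w3 <- slice_seq(filled, w3_start, min(nchar(filled), e + k + window))
  out <- list()
  if (nchar(w5) >= 8) {
    r5 <- find_tandem_repeats(w5)
    if (nrow(r5)) {
      r5$offset <- (w5_start + r5$start) - (s - k)  # negative upstream distance
      r5$side <- "5p"; r5$locus_id <- locus$locus_id
      out[[length(out) + 1L]] <- r5
    }
  }
  if (nchar(w3) >= 8) {
    r3 <- find_tandem_repeats(w3)
    if (nrow(r3)) {
      r3$offset <- r3$start  # distance downstream of the 3' junction
      r3$side <- "3p"; r3$locus_id <- locus$locus_id
      out[[length(out) + 1L]] <- r3
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus_id = character(0), side = character(0),
                      unit = character(0), copies = numeric(0),
                      offset = integer(0), length = integer(0)))
  }
  res <- do.call(rbind, out)
  res[, c("locus_id", "side", "unit", "copies", "offset", "length")]
}

#' Flank base composition around insertion sites
#'
#' Computes the AT fraction of the 50-bp windows immediately 5' and 3' of the
#' element (TSD copies excluded) for each locus and tests, per side, whether
#' the mean per-locus AT fraction differs from 0.5 (two-sided one-sample
#' t-test; a zero-variance degenerate input reports t = 0, p = 1).
#'
#' @param loci A list of [locus_alleles()].
#' @param window Window length, nt (shorter flanks are used in full and
#'   recorded).
#' @return A list of class `flank_composition`: `per_locus` (data.frame of AT
#'   fractions and window lengths), `mean_at_5p`, `mean_at_3p`, `test_5p`,
#'   `test_3p` (each a list with `t`, `p`, `df`).
#' @export
flank_composition <- function(loci, window = 50L) {
  if (length(loci) < 2) stop("at least 2 loci required")
  rows <- lapply(loci, function(locus) {
    stopifnot(inherits(locus, "locus_alleles"))
    filled <- locus$filled
    s <- locus$element_span[1]; e <- locus$element_span[2]
    tsd <- call_tsd(locus)
    k <- if (is.null(tsd)) 0L else tsd$length
    w5 <- slice_seq(filled, max(0L, s - k - window), max(0L, s - k))
    w3 <- slice_seq(filled, min(e + k, nchar(filled)),
                    min(nchar(filled), e + k + window))
    at_frac <- function(w) {
      if (nchar(w) == 0) return(NA_real_)
      ch <- strsplit(w, "")[[1]]
      sum(ch %in% c("A", "T")) / length(ch)
    }
    data.frame(locus_id = locus$locus_id,
               at_5p = at_frac(w5), at_3p = at_frac(w3),
               len_5p = nchar(w5), len_3p = nchar(w3),
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  one_sample <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(list(t = NA_real_, p = NA_real_, df = NA_real_))
    if (stats::sd(x) == 0) {
      # degenerate: identical fractions give an infinite t off the null and
      # an exact null otherwise
      if (abs(mean(x) - 0.5) < 1e-12) {
        return(list(t = 0, p = 1, df = length(x) - 1))
      }
      return(list(t = sign(mean(x) - 0.5) * Inf, p = 0, df = length(x) - 1))
    }
    tt <- stats::t.test(x, mu = 0.5)
    list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
  }
  structure(list(per_locus = per_locus,
                 mean_at_5p = mean(per_locus$at_5p, na.rm = TRUE),
                 mean_at_3p = mean(per_locus$at_3p, na.rm = TRUE),
                 test_5p = one_sample(per_locus$at_5p),
                 test_3p = one_sample(per_locus$at_3p)),
            class = "flank_composition")
}
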