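#' SINE family consensus with region boundaries
#'
#' The tripartite layout of a tRNA-derived SINE: a 75-bp tRNA-related region
#' carrying the pol III internal promoter, a body region, and a 56-bp
#' LINE-derived tail. For the 208-bp family consensus the body span is
#' `[75, 152)`.
#'
#' @param seq Consensus DNA string.
#' @param id Identifier.
#' @param trna_len,tail_len Lengths of the tRNA-related and tail regions.
#' @return A list of class `sine_consensus` with `record` and 0-based
#'   half-open `trna_span`, `body_span`, `tail_span`.
#' @export
sine_consensus <- function(seq, id = "consensus", trna_len = 75L,
                           tail_len = 56L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stopifnot(n > trna_len + tail_len)
  structure(list(record = list(id = id, desc = "", seq = seq),
                 trna_span = c(0L, trna_len),
                 body_span = c(trna_len, n - tail_len),
                 tail_span = c(n - tail_len, n)),
            class = "sine_consensus")
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under a simple linear scheme (default +1 match,
#' -1 mismatch, -2 gap). N never counts as a match. Traceback is
#' deterministic: ties prefer the diagonal, then the gap consuming `a`, then
#' the gap consuming `b`.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap Scores.
#' @return A list with `score`, aligned strings `a`/`b` (gap `-`), and
#'   `percent_identity` = matches / alignment columns.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence in align_global")
  res <- nw_align_cpp(a, b, match, mismatch, gap)
  ca <- strsplit(res$a, "")[[1]]
  cb <- strsplit(res$b, "")[[1]]
  matches <- sum(ca == cb & ca != "-" & ca != "N")
  res$percent_identity <- matches / length(ca)
  res
}

#' Local pairwise alignment (Smith-Waterman)
#'
#' Best local alignment under a linear scheme. Returned spans are 0-based
#' half-open on each input; `score` is 0 with `NA` spans when nothing aligns.
#'
#' @inheritParams align_global
#' @return A list with `score`, aligned strings, and spans `span_a`,
#'   `span_b`.
#' @export
align_local <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence in align_local")
  res <- sw_align_cpp(a, b, match, mismatch, gap)
  list(score = res$score, a = res$a, b = res$b,
       span_a = if (is.na(res$start_a)) c(NA_integer_, NA_integer_)
                else c(res$start_a - 1L, res$end_a),
       span_b = if (is.na(res$start_b)) c(NA_integer_, NA_integer_)
                else c(res$start_b - 1L, res$end_b))
}

#' Annotate a candidate element against the family consensus
#'
#' Globally aligns the element to the consensus, projects the consensus
#' region boundaries through the alignment onto element coordinates, computes
#' overall and body identity, classifies the tail motif, and lists body
#' indels of 3 bp or more. Family membership requires body identity >= 0.76,
#' the conservation threshold conventionally used to delimit a SINE family.
#' Elements aligning at under 50% overall identity are rejected.
#'
#' @param element A DNA string or one-row record data.frame (`id`, `seq`).
#' @param consensus A [sine_consensus()].
#' @param family_threshold Body-identity threshold for family membership.
#' @return A list of class `sine_annotation`: `element_id`,
#'   `percent_identity`, `body_identity`, `region_spans` (0-based half-open
#'   spans on the element), `tail_motif`, `tgtaa_copies`, `body_indels`
#'   (data.frame kind/length/span), `family_member`.
#' @export
annotate_element <- function(element, consensus, family_threshold = 0.76) {
  stopifnot(inherits(consensus, "sine_consensus"))
  if (is.data.frame(element)) {
    element_id <- element$id[1]; eseq <- toupper(element$seq[1])
  } else {
    element_id <- "element"; eseq <- toupper(element)
  }
  if (nchar(eseq) < 100) stop("element shorter than 100 nt")
  cons <- consensus$record$seq
  aln <- align_global(cons, eseq)
  if (aln$percent_identity < 0.5) {
    stop("element '", element_id, "' rejected as non-family: overall identity ",
         sprintf("%.3f", aln$percent_identity), " < 0.5")
  }
  ca <- strsplit(aln$a, "")[[1]]  # consensus row
  cb <- strsplit(aln$b, "")[[1]]  # element row
  ncol_aln <- length(ca)
  cpos <- cumsum(ca != "-")       # consensus position after each column
  epos <- cumsum(cb != "-")       # element position after each column
  b0 <- consensus$body_span[1]; b1 <- consensus$body_span[2]
  # element coordinate (0-based) at which consensus position `p` starts
  proj <- function(p) {
    if (p == 0) return(0L)
    col <- which(cpos == p & ca != "-")[1]
    as.integer(epos[col])
  }
  tr_end <- proj(b0); body_end <- proj(b1)
  region_spans <- list(trna = c(0L, tr_end),
                       body = c(tr_end, body_end),
                       tail = c(body_end, nchar(eseq)))
  body_cols <- which(cpos > b0 & cpos <= b1 | (ca == "-" & cpos >= b0 & cpos < b1))
  body_match <- sum(ca[body_cols] == cb[body_cols] & ca[body_cols] != "-" &
                      ca[body_cols] != "N")
  body_identity <- if (length(body_cols)) body_match / length(body_cols) else 0
  # body indels >= 3 bp: runs of gaps in either row within body columns
  indels <- list()
  r <- rle(ifelse(ca == "-", "ins", ifelse(cb == "-", "del", "m")))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] == "m" || r$lengths[i] < 3) next
    mid <- (starts[i] + ends[i]) / 2
    if (cpos[floor(mid)] >= b0 && cpos[floor(mid)] <= b1) {
      espan <- c(epos[starts[i]] - (cb[starts[i]] != "-"), epos[ends[i]])
      indels[[length(indels) + 1L]] <-
        data.frame(kind = r$values[i], length = r$lengths[i],
                   start = as.integer(espan[1]), end = as.integer(espan[2]))
    }
  }
  body_indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(kind = character(0), length = integer(0),
               start = integer(0), end = integer(0))
  tail_seq <- slice_seq(eseq, region_spans$tail[1], region_spans$tail[2])
  tail_call <- if (nchar(tail_seq) >= 10) classify_tail(tail_seq) else
    list(tail_motif = "none", tgtaa_copies = 0L)
  structure(list(element_id = element_id,
                 percent_identity = aln$percent_identity,
                 body_identity = body_identity,
                 region_spans = region_spans,
                 tail_motif = tail_call$tail_motif,
                 tgtaa_copies = tail_call$tgtaa_copies,
                 body_indels = body_indels,
                 family_member = body_identity >= family_threshold),
            class = "sine_annotation")
}

#' Classify a SINE tail motif
#'
#' Counts TGTAA copies as the longest tandem (non-overlapping, contiguous)
#' run of TGTAA, and detects a poly(A) tract as a run of >= 5 A's at or after
#' the end of that run (anywhere in the tail if there is no TGTAA). The class
#' is `TGTAA_polyA` when both motifs are present, else whichever is present,
#' else `none`.
#'
#' @param tail Tail DNA string (>= 10 nt).
#' @return A list with `tail_motif` and `tgtaa_copies`.
#' @export
classify_tail <- function(tail) {
  tail <- toupper(tail)
  stopifnot(nchar(tail) >= 10)
  hits <- gregexpr("(?=TGTAA)", tail, perl = TRUE)[[1]]
  copies <- 0L; run_end <- 0L
  if (hits[1] != -1) {
    starts <- as.integer(hits)
    # chains of occurrences spaced exactly 5 apart = tandem runs
    runs <- split(starts, cumsum(c(1L, diff(starts) != 5L)))
    lens <- vapply(runs, length, integer(1))
    best <- runs[[which.max(lens)]]
    copies <- length(best)
    run_end <- best[copies] + 4L   # 1-based end of the last copy
  }
  search_from <- if (copies > 0) run_end + 1L else 1L
  rest <- substr(tail, search_from, nchar(tail))
  has_polya <- grepl("AAAAA", rest, fixed = TRUE)
  motif <- if (copies > 0 && has_polya) "TGTAA_polyA"
           else if (copies > 0) "TGTAA"
           else if (has_polya) "polyA"
           else "none"
  list(tail_motif = motif, tgtaa_copies = copies)
}

# IUPAC degenerate match with N-in-sequence never matching
iupac_mismatches <- function(seq_chars, pattern_chars) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
                S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
                N = c("A", "C", "G", "T"))
  sum(!mapply(function(s, p) s %in% iupac[[p]], seq_chars, pattern_chars))
}

#' Scan a tRNA-related region for pol III A- and B-box promoter motifs
#'
#' Scans the canonical internal promoter consensus motifs, A box
#' `TRGCNNARYNNG` and B box `GWTCRANNC`, allowing up to `max_mismatch`
#' mismatches. The A box is only reported when it starts within the first
#' 40 nt; the B box only downstream of the A box. The best hit per box is the
#' one with fewest mismatches, ties broken leftmost.
#'
#' @param trna_region DNA string (>= 50 nt).
#' @param max_mismatch Maximum mismatches per box (default 2).
#' @return A data.frame with columns `box`, `start`, `end` (0-based
#'   half-open), `mismatches`; zero rows when neither box is found.
#' @export
scan_ab_boxes <- function(trna_region, max_mismatch = 2L) {
  trna_region <- toupper(trna_region)
  stopifnot(nchar(trna_region) >= 50)
  chars <- strsplit(trna_region, "")[[1]]
  scan <- function(pattern, from, to) {
    pc <- strsplit(pattern, "")[[1]]
    w <- length(pc)
    best <- NULL
    for (i in from:min(to, length(chars) - w + 1L)) {
      mm <- iupac_mismatches(chars[i:(i + w - 1L)], pc)
      if (mm <= max_mismatch && (is.null(best) || mm < best$mismatches)) {
        best <- data.frame(start = i - 1L, end = i + w - 1L, mismatches = mm)
        if (mm == 0L) break
      }
    }
    best
  }
  out <- list()
  a <- scan("TRGCNNARYNNG", 1L, 40L)
  if (!is.null(a)) out$A <- cbind(box = "A", a)
  b_from <- if (!is.null(a)) a$end + 1L else 13L
  if (b_from <= nchar(trna_region) - 8L) {
    b <- scan("GWTCRANNC", b_from, nchar(trna_region))
    if (!is.null(b)) out$B <- cbind(box = "B", b)
  }
  if (length(out) == 0) {
    return(data.frame(box = character(0), start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold a tail sequence by maximum base pairing
#'
#' Nussinov maximum-pairing fold (A-T, G-C and optionally G-T wobble pairs
#' each score 1; minimum hairpin loop 3 nt). This is a combinatorial stand-in
#' for thermodynamic folding: it reports the single longest helical stem
#' (maximal run of consecutively nested pairs) and its loop. Traceback is
#' deterministic (pairing preferred, outermost partner first).
#'
#' @param seq DNA string, length 10-400.
#' @param allow_gu Allow G-T (G-U in RNA) wobble pairs (default TRUE). Note
#'   that wobble pairing is not symmetric under reverse complement; disable it
#'   for strand-symmetric folding.
#' @param min_loop Minimum unpaired loop length.
#' @return A list of class `hairpin_call`: `stem_length` (bp in the longest
#'   stem), `loop_span` (0-based half-open), `pairs` (2-column 1-based
#'   matrix), `n_pairs` (total pairs in the fold).
#' @export
fold_hairpin <- function(seq, allow_gu = TRUE, min_loop = 3L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stopifnot(n >= 10, n <= 400)
  partner <- nussinov_cpp(seq, as.integer(min_loop), allow_gu)
  paired_i <- which(partner > seq_along(partner))
  pairs <- cbind(i = paired_i, j = partner[paired_i])
  n_pairs <- nrow(pairs)
  if (n_pairs == 0) {
    return(structure(list(stem_length = 0L, loop_span = c(NA_integer_, NA_integer_),
                          pairs = pairs, n_pairs = 0L), class = "hairpin_call"))
  }
  # longest run of consecutively nested pairs (i, j), (i+1, j-1), ...
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  partner <- as.integer(partner)
  stem_len <- 0L; ii <- NA_integer_; jj <- NA_integer_
  for (r in seq_len(n_pairs)) {
    i <- unname(pairs[r, 1]); j <- unname(pairs[r, 2])
    # only start a stem at its outermost pair
    if (i > 1L && partner[i - 1L] == j + 1L) next
    len <- 1L
    while (i + len < j - len && partner[i + len] == j - len) len <- len + 1L
    if (len > stem_len) { stem_len <- len; ii <- i; jj <- j }
  }
  loop_span <- c(ii + stem_len - 1L, jj - stem_len) # 0-based half-open interior
  structure(list(stem_length = stem_len, loop_span = loop_span,
                 pairs = pairs, n_pairs = as.integer(n_pairs)),
            class = "hairpin_call")
}

#' Survey transcriptome contigs for SINE-derived copies
#'
#' Aligns the consensus locally against every contig on both strands and
#' counts, for each contig whose best local score exceeds `min_score`, the
#' consensus regions covered at >= `min_coverage` of their length by the
#' alignment. A contig covering all three regions in one hit counts as a
#' full-length transcript copy. The default scoring (+2 match, -3 mismatch,
#' -5 gap) and the score gate of 80 mirror a blastn-style screen, on whose
#' scale even a perfect tail-only fragment (56 nt, score 112) clears the
#' gate.
#'
#' @param contigs A sequence record data.frame (`id`, `seq`).
#' @param consensus A [sine_consensus()].
#' @param min_score Local score a hit must exceed.
#' @param min_coverage Fraction of a region's consensus span that must be
#'   covered to count the region.
#' @param match,mismatch,gap Local alignment scores.
#' @return A list of class `region_hit_counts`: `n_full_length`,
#'   `hits_per_region` (named counts over trna/body/tail), and `per_contig`
#'   (data.frame of score, strand and covered regions).
#' @export
survey_transcripts <- function(contigs, consensus, min_score = 80,
                               min_coverage = 0.9, match = 2, mismatch = -3,
                               gap = -5) {
  stopifnot(inherits(consensus, "sine_consensus"))
  cons <- consensus$record$seq
  spans <- list(trna = consensus$trna_span, body = consensus$body_span,
                tail = consensus$tail_span)
  counts <- c(trna = 0L, body = 0L, tail = 0L)
  n_full <- 0L
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    fwd <- align_local(cons, contigs$seq[i], match, mismatch, gap)
    rev <- align_local(cons, revcomp(contigs$seq[i]), match, mismatch, gap)
    best <- if (fwd$score >= rev$score) fwd else rev
    strand <- if (fwd$score >= rev$score) "+" else "-"
    covered <- c(trna = FALSE, body = FALSE, tail = FALSE)
    if (best$score > min_score && !is.na(best$span_a[1])) {
      for (rg in names(spans)) {
        sp <- spans[[rg]]
        ov <- max(0, min(sp[2], best$span_a[2]) - max(sp[1], best$span_a[1]))
        covered[rg] <- ov >= min_coverage * (sp[2] - sp[1])
      }
      counts <- counts + covered
      if (all(covered)) n_full <- n_full + 1L
    }
    rows[[i]] <- data.frame(contig_id = contigs$id[i], score = best$score,
                            strand = strand, trna = covered[["trna"]],
                            body = covered[["body"]], tail = covered[["tail"]],
                            stringsAsFactors = FALSE)
  }
  per_contig <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), score = numeric(0),
               strand = character(0), trna = logical(0), body = logical(0),
               tail = logical(0))
  structure(list(n_full_length = n_full, hits_per_region = counts,
                 per_contig = per_contig),
            class = "region_hit_counts")
}
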