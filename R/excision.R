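# longest common prefix / suffix lengths of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- strsplit(a, "")[[1]][seq_len(n)]
  cb <- strsplit(b, "")[[1]][seq_len(n)]
  neq <- which(ca != cb)
  if (length(neq) == 0) n else neq[1] - 1L
}

lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  cb <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  neq <- which(ca != cb)
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Characterize the excision footprint at a locus
#'
#' Anchors the excised allele to the filled allele by maximal exact
#' end-blocks: the left anchor is the longest shared prefix, the right anchor
#' the longest shared suffix of the remainders (so the two anchors never
#' overlap). Everything between the anchors on the excised side is the fill;
#' the microhomology is the longest exact suffix of the fill equal to the
#' excised-side bases immediately following it (searched up to
#' `mh_window` nt); flank bases of the filled allele lost beyond the element
#' and one TSD copy are the flank deletion. The fill's microsatellite content
#' is taken from [find_tandem_repeats()] when a single array covers at least
#' half the fill.
#'
#' @param locus A [locus_alleles()] for the filled allele (element span set).
#' @param excised The excised-allele DNA string, or a one-row record
#'   data.frame.
#' @param min_anchor Minimum shared end-block length (default 30 nt); shorter
#'   anchors raise an "alleles not comparable" error.
#' @param mh_window Microhomology search window (default 25 nt).
#' @return A list of class `excision_footprint` with fields `locus_id`,
#'   `left_breakpoint`, `right_breakpoint` (0-based on the filled allele),
#'   `deleted_flank_nt`, `fill_seq`, `fill_len`, `fill_repeat` (list
#'   `unit`/`copies` or `NULL`), `microhomology_len`, `microhomology_seq`.
#' @export
call_footprint <- function(locus, excised, min_anchor = 30L, mh_window = 25L) {
  stopifnot(inherits(locus, "locus_alleles"))
  if (is.data.frame(excised)) excised <- excised$seq[1]
  excised <- toupper(excised)
  filled <- locus$filled
  s <- locus$element_span[1]; e <- locus$element_span[2]
  la <- lcp_len(filled, excised)
  ra <- lcs_len(substr(filled, la + 1L, nchar(filled)),
                substr(excised, la + 1L, nchar(excised)))
  if (la < min_anchor || ra < min_anchor) {
    stop("alleles not comparable: shared end-blocks of ", la, " and ", ra,
         " nt (need >= ", min_anchor, ")")
  }
  fill_seq <- substr(excised, la + 1L, nchar(excised) - ra)
  fill_len <- nchar(fill_seq)
  after_fill <- substr(excised, nchar(excised) - ra + 1L, nchar(excised))
  mh_len <- longest_suffix_prefix(fill_seq, after_fill, cap = mh_window)
  mh_seq <- if (mh_len > 0) substr(fill_seq, fill_len - mh_len + 1L, fill_len)
            else ""
  tsd <- suppressWarnings(call_tsd(locus))
  k <- if (is.null(tsd)) 0L else tsd$length
  gap_len <- (nchar(filled) - ra) - la
  deleted <- gap_len - (e - s) - k
  fill_repeat <- NULL
  if (fill_len >= 8) {
    arrays <- find_tandem_repeats(fill_seq)
    if (nrow(arrays) > 0) {
      best <- arrays[which.max(arrays$length), ]
      if (best$length >= 0.5 * fill_len) {
        fill_repeat <- list(unit = best$unit, copies = best$copies)
      }
    }
  }
  structure(list(locus_id = locus$locus_id,
                 left_breakpoint = la,
                 right_breakpoint = nchar(filled) - ra,
                 deleted_flank_nt = max(0L, as.integer(deleted)),
                 fill_seq = fill_seq, fill_len = fill_len,
                 fill_repeat = fill_repeat,
                 microhomology_len = mh_len,
                 microhomology_seq = mh_seq),
            class = "excision_footprint")
}

#' Summarize excision footprints across loci
#'
#' @param footprints A list of [call_footprint()] results.
#' @return A list of class `footprint_summary`: `per_locus` (one row per
#'   footprint, sorted by locus id), and aggregates `n`, `n_with_fill`,
#'   `n_mh_ge2` (microhomology >= 2 nt), `max_fill_len`, `mh_distribution`
#'   (table of microhomology lengths).
#' @export
summarize_footprints <- function(footprints) {
  if (length(footprints) < 1) stop("at least one footprint required")
  rows <- lapply(footprints, function(fp) {
    stopifnot(inherits(fp, "excision_footprint"))
    data.frame(locus_id = fp$locus_id,
               deleted_flank_nt = fp$deleted_flank_nt,
               fill_len = fp$fill_len,
               fill_unit = if (is.null(fp$fill_repeat)) NA_character_
                           else fp$fill_repeat$unit,
               fill_copies = if (is.null(fp$fill_repeat)) NA_real_
                             else fp$fill_repeat$copies,
               microhomology_len = fp$microhomology_len,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  per_locus <- per_locus[order(per_locus$locus_id), , drop = FALSE]
  rownames(per_locus) <- NULL
  structure(list(per_locus = per_locus,
                 n = nrow(per_locus),
                 n_with_fill = sum(per_locus$fill_len > 0),
                 n_mh_ge2 = sum(per_locus$microhomology_len >= 2),
                 max_fill_len = max(per_locus$fill_len),
                 mh_distribution = table(per_locus$microhomology_len)),
            class = "footprint_summary")
}
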