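#' Read a FASTA file into a sequence record table
#'
#' Wraps [Biostrings::readDNAStringSet()] and enforces the pipeline's sequence
#' contract: ids are non-empty and unique within a file, sequences are
#' non-empty, and the alphabet is restricted to A/C/G/T/N (lower case is
#' normalized to upper case on input).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return A data.frame with columns `id` (first whitespace-delimited token of
#'   the header), `desc` (remainder of the header, possibly `""`) and `seq`
#'   (upper-case DNA string).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    stop("FASTA parse error in '", path, "': record with empty header")
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    stop("FASTA parse error in '", path, "': duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA parse error in '", path, "': empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA parse error in '", path, "': illegal characters (outside ACGTN) ",
         "in record(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, desc = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write a sequence record table to FASTA
#'
#' @param records A data.frame with columns `id`, `desc`, `seq` (as returned
#'   by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate record ids")
  set <- Biostrings::DNAStringSet(toupper(records$seq))
  desc <- if ("desc" %in% names(records)) records$desc else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

GENOTYPE_LEVELS <- c("II", "IA", "AA", "missing")

#' Read a presence/absence genotype table
#'
#' Reads a TSV with columns `locus_id`, `population_id`, `individual_id`,
#' `genotype` where genotype is one of `II` (two insertion-bearing alleles),
#' `IA` (heterozygote), `AA` (two insertion-free alleles) or `missing`.
#'
#' @param path Path to a TSV file.
#' @return A validated `locus_table` data.frame.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  locus_table(tab)
}

#' Construct and validate a locus genotype table
#'
#' @param tab A data.frame with columns `locus_id`, `population_id`,
#'   `individual_id`, `genotype`.
#' @return The same data.frame, validated, with class `locus_table`.
#' @export
locus_table <- function(tab) {
  req <- c("locus_id", "population_id", "individual_id", "genotype")
  if (!all(req %in% names(tab))) {
    stop("genotype table must have columns: ", paste(req, collapse = ", "))
  }
  tab <- as.data.frame(tab[, req], stringsAsFactors = FALSE)
  if (nrow(tab) > 0) {
    bad <- !(tab$genotype %in% GENOTYPE_LEVELS)
    if (any(bad)) {
      stop("unknown genotype symbol(s) in rows: ",
           paste(utils::head(which(bad), 10L), collapse = ", "),
           " (values: ", paste(unique(tab$genotype[bad]), collapse = ", "), ")")
    }
    key <- paste(tab$population_id, tab$individual_id, tab$locus_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicated (population, individual, locus) triples in rows: ",
           paste(utils::head(which(duplicated(key)), 10L), collapse = ", "))
    }
  }
  class(tab) <- c("locus_table", "data.frame")
  tab
}

#' Write a genotype table to TSV
#' @param tab A `locus_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Thin wrapper over [ape::write.tree()] that rejects duplicate leaf labels.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

## ---- shared sequence primitives (0-based, half-open coordinates) ----

#' Extract a subsequence using 0-based half-open coordinates
#' @param seq A DNA string.
#' @param start,end 0-based half-open span `[start, end)`.
#' @return The subsequence.
#' @export
slice_seq <- function(seq, start, end) {
  stopifnot(start >= 0, end >= start, end <= nchar(seq))
  if (end == start) return("")
  substr(seq, start + 1L, end)
}

#' Reverse complement of a DNA string (N maps to N)
#' @param seq A DNA string over ACGTN.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
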