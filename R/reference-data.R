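#' Reported per-population SINE insertion frequencies and heterozygosities
#'
#' The published survey of five SINE insertion loci (Ls40, Ls5, Ls58, Ls60,
#' Ls29) genotyped in ten diploid individuals from each of six Coilia nasus
#' populations: Xiangshan (XS), Chongming (CM), Jingjiang (JJ), Taihu Lake
#' (TH), Poyang Lake (PY) and Dongting Lake (DT). `f` is the insertion-allele
#' frequency and `het` the observed heterozygosity, both printed to two
#' decimals. These values are the input for [table1_fixture()], which
#' reconstructs an exact genotype table from them.
#'
#' @return A data.frame with columns `locus_id`, `population_id`, `f`, `het`
#'   (30 rows: 5 loci x 6 populations).
#' @export
cnasus_locus_reference <- function() {
  loci <- c("Ls40", "Ls5", "Ls58", "Ls60", "Ls29")
  pops <- c("XS", "CM", "JJ", "TH", "PY", "DT")
  f <- rbind(
    Ls40 = c(0.90, 0.65, 0.50, 0.45, 1.00, 1.00),
    Ls5  = c(0.60, 0.80, 0.60, 0.50, 0.00, 0.20),
    Ls58 = c(1.00, 1.00, 1.00, 1.00, 0.10, 0.00),
    Ls60 = c(0.00, 0.00, 0.00, 0.00, 0.50, 0.50),
    Ls29 = c(1.00, 1.00, 1.00, 1.00, 0.00, 0.00))
  het <- rbind(
    Ls40 = c(0.20, 0.50, 0.80, 0.30, 0.00, 0.00),
    Ls5  = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    Ls58 = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    Ls60 = c(0.00, 0.00, 0.00, 0.00, 1.00, 1.00),
    Ls29 = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00))
  data.frame(
    locus_id = rep(loci, times = length(pops)),
    population_id = rep(pops, each = length(loci)),
    f = as.vector(f[loci, ]),
    het = as.vector(het[loci, ]),
    stringsAsFactors = FALSE)
}

#' Reported per-locus ecotype frequencies and heterozygosities
#'
#' The published per-locus insertion frequencies and heterozygosities of the
#' two C. nasus ecotypes (migratory vs freshwater-resident), as printed. The
#' published across-locus means (migratory f 0.65, Het 0.13; resident f 0.33,
#' Het 0.20) are the unweighted column means of these rows.
#'
#' @return A data.frame with columns `locus_id`, `f_migratory`,
#'   `het_migratory`, `f_resident`, `het_resident`.
#' @export
cnasus_ecotype_reference <- function() {
  data.frame(
    locus_id = c("Ls40", "Ls5", "Ls58", "Ls60", "Ls29"),
    f_migratory = c(0.57, 0.70, 1.00, 0.00, 1.00),
    het_migratory = c(0.65, 0.00, 0.00, 0.00, 0.00),
    f_resident = c(1.00, 0.10, 0.05, 0.50, 0.00),
    het_resident = c(0.00, 0.00, 0.00, 1.00, 0.00),
    stringsAsFactors = FALSE)
}

#' Default population-to-ecotype grouping
#'
#' XS, CM and JJ are river/coastal migratory populations and PY and DT are
#' lake-resident populations. TH (Taihu Lake) clusters with the migratory
#' lineage in the frequency-based tree but is lake-dwelling by habitat, so its
#' assignment is a parameter.
#'
#' @param th One of "migratory" or "resident": where to place the TH
#'   population.
#' @return A named character vector mapping population id to ecotype.
#' @export
default_ecotype_grouping <- function(th = c("migratory", "resident")) {
  th <- match.arg(th)
  c(XS = "migratory", CM = "migratory", JJ = "migratory",
    TH = th, PY = "resident", DT = "resident")
}
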