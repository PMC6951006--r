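#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template copies. A valid
#' quantification curve has a negative slope; slopes outside the PCR
#' efficiency sanity band [-3.6, -3.1] trigger a warning (never an error: a
#' slope of -3.11 sits right at the band edge).
#'
#' @param log10_copies Numeric vector of log10 copy numbers (>= 3 points
#'   spanning >= 2 log10 units).
#' @param ct Matching Ct values.
#' @return A list of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `n_points`.
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  stopifnot(length(log10_copies) == length(ct), length(ct) >= 3)
  if (length(unique(log10_copies)) < 2) {
    stop("all standards have the same copy number; cannot fit a curve")
  }
  if (diff(range(log10_copies)) < 2) {
    warning("standards span less than 2 log10 units")
  }
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # silence perfect-fit notice
  if (slope < -3.6 || slope > -3.1) {
    warning(sprintf("slope %.3f outside efficiency sanity band [-3.6, -3.1]",
                    slope))
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 n_points = length(ct)), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.4g * log10(copies) + %.4f (R2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n_points))
  invisible(x)
}

#' Absolute quantification from a Ct value
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept) / slope)`.
#'
#' @param ct Ct value(s).
#' @param curve A [fit_standard_curve()] result (or any list with `slope`
#'   and `intercept`).
#' @return Copies in the reaction.
#' @export
quantify <- function(ct, curve) {
  if (curve$slope >= 0) stop("invalid standard curve: slope must be negative")
  10^((ct - curve$intercept) / curve$slope)
}

#' Copies per haploid genome
#'
#' Normalizes a reaction copy number by the number of genome equivalents in
#' the input DNA: `copies_per_genome = copies * genome_size_pg / mass_pg`.
#' The default genome size is the C. nasus value of 3.534 pg.
#'
#' @param copies_in_reaction Copies measured in the reaction.
#' @param input_mass_pg Input DNA mass, pg.
#' @param genome_size_pg Haploid genome size, pg.
#' @return Copies per genome.
#' @export
per_genome <- function(copies_in_reaction, input_mass_pg,
                       genome_size_pg = 3.534) {
  stopifnot(all(copies_in_reaction > 0), all(genome_size_pg > 0))
  if (any(input_mass_pg <= 0)) stop("input mass must be positive")
  copies_in_reaction * genome_size_pg / input_mass_pg
}

#' Estimate per-genome copy numbers from a qPCR plate
#'
#' Averages replicate Ct values per sample on the Ct scale, fits the
#' standard curve from the rows flagged `standard` (unless a curve is
#' supplied), quantifies the unknowns and normalizes by genome equivalents.
#'
#' @param plate A plate data.frame as produced by [simulate_qpcr()]
#'   (columns `sample_id`, `role`, `log10_copies`, `ct`, `input_mass_pg`).
#' @param curve Optional pre-fitted [fit_standard_curve()] result.
#' @param genome_size_pg Haploid genome size, pg.
#' @return A list with `curve` and `estimates` (data.frame: `sample_id`,
#'   `mean_ct`, `replicate_cv`, `copies_in_reaction`, `input_mass_pg`,
#'   `genomes_in_reaction`, `copies_per_genome`).
#' @export
estimate_copy_numbers <- function(plate, curve = NULL, genome_size_pg = 3.534) {
  req <- c("sample_id", "role", "log10_copies", "ct", "input_mass_pg")
  stopifnot(all(req %in% names(plate)))
  if (is.null(curve)) {
    std <- plate[plate$role == "standard", ]
    if (nrow(std) < 3) stop("no usable standards on plate")
    curve <- fit_standard_curve(std$log10_copies, std$ct)
  }
  unk <- plate[plate$role == "unknown", ]
  rows <- lapply(split(unk, unk$sample_id), function(d) {
    mean_ct <- mean(d$ct)
    copies <- quantify(mean_ct, curve)
    mass <- d$input_mass_pg[1]
    genomes <- mass / genome_size_pg
    data.frame(sample_id = d$sample_id[1], mean_ct = mean_ct,
               replicate_cv = if (nrow(d) > 1) stats::sd(d$ct) / mean_ct else NA_real_,
               copies_in_reaction = copies, input_mass_pg = mass,
               genomes_in_reaction = genomes,
               copies_per_genome = copies / genomes,
               stringsAsFactors = FALSE)
  })
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  list(curve = curve, estimates = estimates)
}

#' Compare copy numbers between ecotypes and among populations
#'
#' Per-population and per-ecotype means plus standard one-way ANOVA:
#' between ecotypes over all samples, and among populations within each
#' ecotype.
#'
#' @param estimates A data.frame with columns `copies_per_genome` and
#'   `population_id`.
#' @param grouping Named character vector mapping population ids to ecotypes.
#' @return A list with `population_means`, `ecotype_means`,
#'   `between_ecotypes` (list `F`, `p`, `df`), and `within_ecotype` (named
#'   list of the same per ecotype; `NULL` when an ecotype has a single
#'   population).
#' @export
compare_groups <- function(estimates, grouping) {
  stopifnot(all(c("copies_per_genome", "population_id") %in% names(estimates)))
  miss <- setdiff(unique(estimates$population_id), names(grouping))
  if (length(miss) > 0) {
    stop("populations missing from grouping: ", paste(miss, collapse = ", "))
  }
  d <- estimates
  d$ecotype <- unname(grouping[d$population_id])
  if (any(table(d$ecotype) < 2)) stop("every ecotype needs >= 2 estimates")
  pm <- stats::aggregate(copies_per_genome ~ population_id, d, mean)
  em <- stats::aggregate(copies_per_genome ~ ecotype, d, mean)
  aov_stats <- function(formula, data) {
    if (length(unique(data[[all.vars(formula)[2]]])) < 2) return(NULL)
    if (any(table(data[[all.vars(formula)[2]]]) < 2)) {
      stop("a group of size 1 in ANOVA")
    }
    a <- summary(stats::aov(formula, data = data))[[1]]
    list(F = a$`F value`[1], p = a$`Pr(>F)`[1], df = a$Df[1:2])
  }
  between <- aov_stats(copies_per_genome ~ ecotype, d)
  within <- lapply(split(d, d$ecotype), function(sub) {
    aov_stats(copies_per_genome ~ population_id, sub)
  })
  list(population_means = pm, ecotype_means = em,
       between_ecotypes = between, within_ecotype = within)
}
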