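#' Pipeline configuration
#'
#' Bundles the seed, synthetic-study parameters and per-stage toggles for
#' [run_pipeline()].
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param sim A [sim_config()]; defaults to `sim_config(seed)`.
#' @param grouping Population-to-ecotype mapping for popgen and copy-number
#'   stages.
#' @param genotypes_source "table1" (the deterministic published-survey
#'   fixture) or "simulated" (genotypes drawn from random frequencies).
#' @param distance Genetic distance method for the tree ("nei1972" or "da").
#' @param n_perm AMOVA permutations.
#' @param stages Named logical toggles over `simulate`, `annotate`,
#'   `forensics`, `excision`, `popgen`, `copynumber`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            grouping = default_ecotype_grouping(),
                            genotypes_source = c("table1", "simulated"),
                            distance = "nei1972", n_perm = 199L,
                            stages = c(simulate = TRUE, annotate = TRUE,
                                       forensics = TRUE, excision = TRUE,
                                       popgen = TRUE, copynumber = TRUE)) {
  genotypes_source <- match.arg(genotypes_source)
  all_stages <- c("simulate", "annotate", "forensics", "excision", "popgen",
                  "copynumber")
  st <- setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  structure(list(seed = as.integer(seed), sim = sim, grouping = grouping,
                 genotypes_source = genotypes_source, distance = distance,
                 n_perm = as.integer(n_perm), stages = st),
            class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate, annotate, forensics (TSD/flanks), excision, popgen and
#' copy-number stages in order, writing every artifact under `outdir` and
#' returning a checksummed manifest. Identical seed and config yield
#' byte-identical artifacts. A stage whose inputs were produced by a
#' disabled stage fails fast naming both stages.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return A data.frame manifest (`stage`, `artifact`, `path`, `md5`) with
#'   attribute `seed`; also written to `manifest.tsv` in `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("sinepop_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list()
  add <- function(stage, artifact, path) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, artifact = artifact, path = path,
                 md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  need <- function(path, stage, producer) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' requires ", basename(path),
           " produced by stage '", producer, "', which did not run")
    }
    path
  }
  fp <- function(...) file.path(outdir, ...)
  cfg <- config$sim

  if (config$stages[["simulate"]]) {
    consensus <- make_consensus(cfg$seed)
    set.seed(cfg$seed + 1L)
    plants <- lapply(seq_len(cfg$n_loci), function(i) {
      plant_insertion(consensus, cfg, locus_id = sprintf("locus%03d", i))
    })
    truth <- do.call(rbind, lapply(plants, `[[`, "truth"))
    loci_recs <- do.call(rbind, lapply(plants, function(p) {
      l <- p$locus
      data.frame(id = c(paste0(l$locus_id, ".filled"), paste0(l$locus_id, ".empty")),
                 desc = "", seq = c(l$filled, l$empty), stringsAsFactors = FALSE)
    }))
    spans <- do.call(rbind, lapply(plants, function(p) {
      data.frame(locus_id = p$locus$locus_id,
                 start = p$locus$element_span[1], end = p$locus$element_span[2],
                 stringsAsFactors = FALSE)
    }))
    write_fasta(data.frame(id = consensus$record$id, desc = "",
                           seq = consensus$record$seq), fp("consensus.fasta"))
    write_fasta(loci_recs, fp("loci.fasta"))
    utils::write.table(spans, fp("element_spans.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, fp("ground_truth_insertions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    n_exc <- max(1L, round(cfg$excision_fraction * cfg$n_loci))
    exc <- lapply(plants[seq_len(n_exc)], function(p) {
      plant_excision(p$locus, unit = "TG", copies = sample(10:45, 1),
                     microhomology_len = sample(2:8, 1),
                     tsd_len = p$truth$tsd_len)
    })
    write_fasta(do.call(rbind, lapply(exc, `[[`, "excised")),
                fp("excised.fasta"))
    utils::write.table(do.call(rbind, lapply(exc, `[[`, "truth")),
                       fp("ground_truth_excisions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    geno <- if (config$genotypes_source == "table1") table1_fixture() else {
      freqs <- matrix(runif(cfg$n_pops * 5), cfg$n_pops, 5,
                      dimnames = list(sprintf("pop%02d", seq_len(cfg$n_pops)),
                                      sprintf("locus%02d", 1:5)))
      simulate_genotypes(freqs, cfg$n_ind_per_pop)
    }
    write_genotypes(geno, fp("genotypes.tsv"))
    plate <- simulate_qpcr(unknown_log10_copies = runif(6, 4.5, 5.5),
                           noise_sd = cfg$ct_noise_sd,
                           sample_ids = sprintf("pop%02d", 1:6))
    utils::write.table(plate, fp("qpcr_plate.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    contigs <- simulate_transcripts(consensus, n_full = 3,
                                    n_partial_by_region = c(trna = 2, body = 2,
                                                            tail = 4))
    write_fasta(contigs, fp("transcripts.fasta"))
    for (f in c("consensus.fasta", "loci.fasta", "element_spans.tsv",
                "ground_truth_insertions.tsv", "excised.fasta",
                "ground_truth_excisions.tsv", "genotypes.tsv",
                "qpcr_plate.tsv", "transcripts.fasta")) {
      add("simulate", f, fp(f))
    }
  }

  read_loci <- function(stage) {
    recs <- read_fasta(need(fp("loci.fasta"), stage, "simulate"))
    spans <- utils::read.delim(need(fp("element_spans.tsv"), stage, "simulate"))
    lapply(seq_len(nrow(spans)), function(i) {
      id <- spans$locus_id[i]
      locus_alleles(id,
                    filled = recs$seq[recs$id == paste0(id, ".filled")],
                    element_span = c(spans$start[i], spans$end[i]),
                    empty = recs$seq[recs$id == paste0(id, ".empty")])
    })
  }

  if (config$stages[["annotate"]]) {
    cons_rec <- read_fasta(need(fp("consensus.fasta"), "annotate", "simulate"))
    consensus <- sine_consensus(cons_rec$seq[1], id = cons_rec$id[1])
    loci <- read_loci("annotate")
    ann <- lapply(loci, function(l) {
      elem <- slice_seq(l$filled, l$element_span[1], l$element_span[2])
      a <- annotate_element(data.frame(id = l$locus_id, seq = elem), consensus)
      hp <- fold_hairpin(slice_seq(elem, a$region_spans$tail[1],
                                   a$region_spans$tail[2]))
      data.frame(locus_id = l$locus_id, percent_identity = a$percent_identity,
                 body_identity = a$body_identity, tail_motif = a$tail_motif,
                 tgtaa_copies = a$tgtaa_copies,
                 family_member = a$family_member,
                 n_body_indels = nrow(a$body_indels),
                 tail_stem_bp = hp$stem_length, stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, ann), fp("annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    contigs <- read_fasta(need(fp("transcripts.fasta"), "annotate", "simulate"))
    sv <- survey_transcripts(contigs, consensus)
    utils::write.table(data.frame(n_full_length = sv$n_full_length,
                                  t(sv$hits_per_region)),
                       fp("transcript_survey.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add("annotate", "annotations.tsv", fp("annotations.tsv"))
    add("annotate", "transcript_survey.tsv", fp("transcript_survey.tsv"))
  }

  if (config$stages[["forensics"]]) {
    loci <- read_loci("forensics")
    tsd <- do.call(rbind, lapply(loci, function(l) {
      call <- call_tsd(l)
      data.frame(locus_id = l$locus_id,
                 tsd_len = if (is.null(call)) NA_integer_ else call$length,
                 tsd_seq = if (is.null(call)) NA_character_ else call$sequence,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(tsd, fp("tsd_calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    reps <- do.call(rbind, lapply(loci, locus_flank_repeats))
    utils::write.table(reps, fp("flank_repeats.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    comp <- flank_composition(loci)
    utils::write.table(comp$per_locus, fp("flank_composition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (f in c("tsd_calls.tsv", "flank_repeats.tsv", "flank_composition.tsv")) {
      add("forensics", f, fp(f))
    }
  }

  if (config$stages[["excision"]]) {
    loci <- read_loci("excision")
    exc <- read_fasta(need(fp("excised.fasta"), "excision", "simulate"))
    ids <- sub("\\.excised$", "", exc$id)
    fps <- lapply(seq_len(nrow(exc)), function(i) {
      l <- loci[[which(vapply(loci, `[[`, character(1), "locus_id") == ids[i])]]
      call_footprint(l, exc$seq[i])
    })
    sm <- summarize_footprints(fps)
    utils::write.table(sm$per_locus, fp("footprints.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("excision", "footprints.tsv", fp("footprints.tsv"))
  }

  if (config$stages[["popgen"]]) {
    geno <- read_genotypes(need(fp("genotypes.tsv"), "popgen", "simulate"))
    stats <- locus_stats(geno)
    utils::write.table(stats, fp("locus_stats.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    grouping <- config$grouping
    pops <- unique(geno$population_id)
    if (!all(pops %in% names(grouping))) {
      grouping <- setNames(rep(c("g1", "g2"), length.out = length(pops)), pops)
    }
    eco <- ecotype_stats(geno, grouping)
    utils::write.table(eco$per_locus, fp("ecotype_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    freqs <- with(stats, tapply(f_sine, list(population_id, locus_id), mean))
    d <- nei_distance(freqs, method = config$distance)
    utils::write.table(round(d, 10), fp("nei_distances.tsv"), sep = "\t",
                       quote = FALSE)
    tree <- nj_tree(d)
    write_newick(tree, fp("nj_tree.nwk"))
    am <- amova(geno, grouping, n_perm = config$n_perm, seed = config$seed)
    amtab <- data.frame(component = names(am$sigma2), sigma2 = am$sigma2,
                        percent = am$percent,
                        phi = am$phi, p = am$p)
    utils::write.table(amtab, fp("amova.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (f in c("locus_stats.tsv", "ecotype_stats.tsv", "nei_distances.tsv",
                "nj_tree.nwk", "amova.tsv")) {
      add("popgen", f, fp(f))
    }
  }

  if (config$stages[["copynumber"]]) {
    plate <- utils::read.delim(need(fp("qpcr_plate.tsv"), "copynumber",
                                    "simulate"))
    est <- estimate_copy_numbers(plate)
    utils::write.table(est$estimates, fp("copy_numbers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("copynumber", "copy_numbers.tsv", fp("copy_numbers.tsv"))
  }

  manifest <- do.call(rbind, manifest)
  manifest <- cbind(seed = config$seed, manifest)
  utils::write.table(manifest, fp("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(manifest, "seed") <- config$seed
  manifest
}
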