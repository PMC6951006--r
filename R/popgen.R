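#' Per-locus per-population insertion statistics
#'
#' Counts genotypes per (locus, population) cell, excluding missing calls,
#' and derives the insertion-allele frequency `f_sine = (2 n_II + n_IA) /
#' (2n)`, the observed heterozygosity `het_obs = n_IA / n`, and the exact
#' Hardy-Weinberg p-value from [hwe_exact()].
#'
#' @param table A [locus_table()].
#' @return A data.frame with columns `locus_id`, `population_id`, `n`,
#'   `n_II`, `n_IA`, `n_AA`, `f_sine`, `het_obs`, `hwe_p`. Cells with only
#'   missing genotypes get `n = 0` and `NA` statistics.
#' @export
locus_stats <- function(table) {
  stopifnot(inherits(table, "locus_table"))
  cells <- unique(table[, c("locus_id", "population_id")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$locus_id == cells$locus_id[i] &
                   table$population_id == cells$population_id[i], ]
    g <- sub$genotype[sub$genotype != "missing"]
    n_ii <- sum(g == "II"); n_ia <- sum(g == "IA"); n_aa <- sum(g == "AA")
    n <- n_ii + n_ia + n_aa
    if (n == 0) {
      return(data.frame(locus_id = cells$locus_id[i],
                        population_id = cells$population_id[i],
                        n = 0L, n_II = 0L, n_IA = 0L, n_AA = 0L,
                        f_sine = NA_real_, het_obs = NA_real_,
                        hwe_p = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(locus_id = cells$locus_id[i],
               population_id = cells$population_id[i],
               n = n, n_II = n_ii, n_IA = n_ia, n_AA = n_aa,
               f_sine = (2 * n_ii + n_ia) / (2 * n),
               het_obs = n_ia / n,
               hwe_p = hwe_exact(n_ii, n_ia, n_aa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact test of Hardy-Weinberg equilibrium for a biallelic locus
#'
#' Conditional exact test: given the observed allele counts, every
#' heterozygote count of the same parity is enumerated, its probability
#' computed from the standard hypergeometric-type formula
#' `P(n_IA | n, n_I) = n! / (n_II! n_IA! n_AA!) * 2^n_IA * n_I! n_A! / (2n)!`,
#' and the p-value is the total probability of configurations no more
#' probable than the observed one. Monomorphic samples return p = 1.
#'
#' @param n_II,n_IA,n_AA Genotype counts (non-negative, total >= 1).
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact <- function(n_II, n_IA, n_AA) {
  stopifnot(n_II >= 0, n_IA >= 0, n_AA >= 0)
  n <- n_II + n_IA + n_AA
  stopifnot(n >= 1)
  nI <- 2 * n_II + n_IA
  nA <- 2 * n_AA + n_IA
  if (nI == 0 || nA == 0) return(1)
  log_prob <- function(h) {
    ii <- (nI - h) / 2; aa <- (nA - h) / 2
    lfactorial(n) - lfactorial(ii) - lfactorial(h) - lfactorial(aa) +
      h * log(2) + lfactorial(nI) + lfactorial(nA) - lfactorial(2 * n)
  }
  hs <- seq(nI %% 2, min(nI, nA), by = 2)
  lp <- vapply(hs, log_prob, numeric(1))
  obs <- lp[hs == n_IA]
  p <- sum(exp(lp[lp <= obs + 1e-12]))
  min(1, p)
}

#' Per-locus ecotype statistics from pooled populations
#'
#' Pools all individuals of each ecotype and recomputes [locus_stats()] and
#' the HWE exact test per locus per ecotype, plus unweighted across-locus
#' means.
#'
#' @param table A [locus_table()].
#' @param grouping Named character vector mapping every population id in the
#'   table to an ecotype (see [default_ecotype_grouping()]).
#' @return A list with `per_locus` (pooled locus stats with `ecotype`
#'   column) and `means` (across-locus unweighted mean `f_sine` and `het_obs`
#'   per ecotype).
#' @export
ecotype_stats <- function(table, grouping) {
  stopifnot(inherits(table, "locus_table"))
  pops <- unique(table$population_id)
  miss <- setdiff(pops, names(grouping))
  if (length(miss) > 0) {
    stop("populations missing from grouping: ", paste(miss, collapse = ", "))
  }
  pooled <- as.data.frame(table)
  pooled$individual_id <- paste(pooled$population_id, pooled$individual_id,
                                sep = ":")
  pooled$population_id <- unname(grouping[pooled$population_id])
  per_locus <- locus_stats(locus_table(pooled))
  names(per_locus)[names(per_locus) == "population_id"] <- "ecotype"
  means <- do.call(rbind, lapply(split(per_locus, per_locus$ecotype),
                                 function(d) {
    data.frame(ecotype = d$ecotype[1],
               mean_f_sine = mean(d$f_sine, na.rm = TRUE),
               mean_het_obs = mean(d$het_obs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  list(per_locus = per_locus, means = means)
}

#' Genetic distances between populations from insertion frequencies
#'
#' Treats each locus as biallelic with frequency vectors `(f, 1 - f)` and
#' computes Nei's (1972) standard genetic distance
#' `D = -ln( J_xy / sqrt(J_x J_y) )` with the identity sums taken over loci
#' and alleles, or Nei's DA (1983) distance. The ratio is clamped to <= 1,
#' and a zero between-population identity (completely disjoint alleles) is
#' reported as the cap `inf_cap` with a flag.
#'
#' @param freqs Matrix of insertion frequencies, populations x loci, with
#'   dimnames.
#' @param method "nei1972" (default) or "da".
#' @param inf_cap Value reported for infinite Nei distances.
#' @return A symmetric distance matrix with attributes `method` and
#'   `capped` (logical matrix of capped entries).
#' @export
nei_distance <- function(freqs, method = c("nei1972", "da"), inf_cap = 10) {
  method <- match.arg(method)
  stopifnot(is.matrix(freqs), !is.null(rownames(freqs)),
            all(freqs >= 0), all(freqs <= 1))
  pops <- rownames(freqs)
  P <- length(pops); L <- ncol(freqs)
  d <- matrix(0, P, P, dimnames = list(pops, pops))
  capped <- matrix(FALSE, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (j <= i) next
      fx <- freqs[i, ]; fy <- freqs[j, ]
      if (method == "nei1972") {
        jxy <- sum(fx * fy + (1 - fx) * (1 - fy))
        jx <- sum(fx^2 + (1 - fx)^2)
        jy <- sum(fy^2 + (1 - fy)^2)
        if (jxy <= 0) {
          v <- inf_cap; capped[i, j] <- capped[j, i] <- TRUE
        } else {
          v <- -log(min(1, jxy / sqrt(jx * jy)))
        }
      } else {
        v <- 1 - sum(sqrt(fx * fy) + sqrt((1 - fx) * (1 - fy))) / L
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  attr(d, "method") <- method
  attr(d, "capped") <- capped
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch lengths are
#' clamped to zero (flagged in the `clamped` attribute). The input must be a
#' symmetric matrix with at least three labelled populations.
#'
#' @param d A symmetric distance matrix with dimnames.
#' @return An unrooted [ape::phylo] tree with attribute `clamped`.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3, !is.null(rownames(d)))
  if (!isSymmetric(unname(d), tol = 1e-12)) {
    stop("distance matrix is not symmetric")
  }
  tree <- ape::nj(d)
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Do two leaves form a cherry?
#'
#' TRUE when the two named tips attach to the same internal node of an
#' unrooted tree (i.e. they are joined as neighbors).
#'
#' @param tree An [ape::phylo] tree.
#' @param a,b Tip labels.
#' @return Logical.
#' @export
is_cherry <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("tip label not in tree")
  pa <- tree$edge[tree$edge[, 2] == ia, 1]
  pb <- tree$edge[tree$edge[, 2] == ib, 1]
  pa == pb
}

#' Two-level AMOVA on presence/absence genotypes
#'
#' Analysis of molecular variance in the Excoffier framework: individuals
#' are encoded as per-locus insertion-allele dosage vectors (0/1/2) so that
#' squared Euclidean distances between individuals drive the sums of
#' squares, which are partitioned among groups (ecotypes), among populations
#' within groups, and within populations. Variance components follow the
#' standard nested ANOVA expectations; Phi statistics are derived from the
#' (untruncated) components, while the reported percentages truncate
#' negative components to zero (recorded in `truncated`). Permutation
#' p-values are computed for Phi_ST (individuals permuted across
#' populations), Phi_SC (individuals permuted among populations within
#' groups) and Phi_CT (whole populations permuted across groups).
#'
#' @param table A [locus_table()] (individuals with any missing genotype are
#'   dropped).
#' @param grouping Named character vector mapping population ids to groups.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return A list of class `amova_result`: `df`, `SS`, `MS`, `sigma2`
#'   (named components a/b/c), `percent`, `phi` (`Phi_CT`, `Phi_SC`,
#'   `Phi_ST`), `p` (permutation p per Phi), `n_perm`, `seed`, `truncated`.
#' @export
amova <- function(table, grouping, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(table, "locus_table"))
  if (!is.null(seed)) set.seed(seed)
  tab <- as.data.frame(table)
  miss <- setdiff(unique(tab$population_id), names(grouping))
  if (length(miss) > 0) {
    stop("populations missing from grouping: ", paste(miss, collapse = ", "))
  }
  dosage <- c(AA = 0, IA = 1, II = 2)
  tab$key <- paste(tab$population_id, tab$individual_id, sep = ":")
  drop <- unique(tab$key[tab$genotype == "missing"])
  tab <- tab[!(tab$key %in% drop), ]
  loci <- sort(unique(tab$locus_id))
  keys <- unique(tab[, c("key", "population_id")])
  X <- matrix(NA_real_, nrow(keys), length(loci),
              dimnames = list(keys$key, loci))
  idx <- cbind(match(tab$key, keys$key), match(tab$locus_id, loci))
  X[idx] <- dosage[tab$genotype]
  if (anyNA(X)) stop("incomplete genotype matrix after dropping missing")
  pop <- keys$population_id
  grp <- unname(grouping[pop])
  if (length(unique(grp)) < 2) stop("at least 2 groups required")
  if (length(unique(pop)) < 2) stop("at least 2 populations required")
  if (any(table(pop) < 2)) stop("every population needs >= 2 individuals")

  components <- function(X, pop, grp) {
    N <- nrow(X); P <- length(unique(pop)); G <- length(unique(grp))
    grand <- colMeans(X)
    ss_dev <- function(M, center) sum(sweep(M, 2, center)^2)
    ss_t <- ss_dev(X, grand)
    pops <- split(seq_len(N), pop)
    ss_wp <- sum(vapply(pops, function(ix) {
      ss_dev(X[ix, , drop = FALSE], colMeans(X[ix, , drop = FALSE]))
    }, numeric(1)))
    grps <- split(seq_len(N), grp)
    ss_wg <- sum(vapply(grps, function(ix) {
      ss_dev(X[ix, , drop = FALSE], colMeans(X[ix, , drop = FALSE]))
    }, numeric(1)))
    ss_ag <- ss_t - ss_wg
    ss_ap <- ss_wg - ss_wp
    n_p <- tapply(rep(1, N), pop, sum)
    pop2grp <- tapply(grp, pop, function(g) g[1])
    N_g <- tapply(rep(1, N), grp, sum)
    sum_np2_by_g <- tapply(n_p^2, pop2grp[names(n_p)], sum)
    A <- sum(sum_np2_by_g / N_g[names(sum_np2_by_g)])
    n1 <- (N - A) / (P - G)
    n2 <- (A - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(N_g^2) / N) / (G - 1)
    ms_wp <- ss_wp / (N - P)
    ms_ap <- ss_ap / (P - G)
    ms_ag <- ss_ag / (G - 1)
    sc <- ms_wp
    sb <- (ms_ap - sc) / n1
    sa <- (ms_ag - sc - n2 * sb) / n3
    tot <- sa + sb + sc
    list(df = c(among_groups = G - 1, among_pops = P - G, within = N - P),
         SS = c(among_groups = ss_ag, among_pops = ss_ap, within = ss_wp),
         MS = c(among_groups = ms_ag, among_pops = ms_ap, within = ms_wp),
         sigma2 = c(a = sa, b = sb, c = sc),
         phi = c(Phi_CT = sa / tot, Phi_SC = sb / (sb + sc),
                 Phi_ST = (sa + sb) / tot))
  }
  obs <- components(X, pop, grp)

  perm_count <- c(Phi_CT = 0L, Phi_SC = 0L, Phi_ST = 0L)
  pop_levels <- unique(pop)
  pop2grp_vec <- unname(grouping[pop_levels])
  for (b in seq_len(n_perm)) {
    # Phi_ST: individuals permuted across everything
    p1 <- sample(pop)
    g1 <- unname(grouping[p1])
    phi <- components(X, p1, g1)$phi
    if (phi["Phi_ST"] >= obs$phi["Phi_ST"] - 1e-12) {
      perm_count["Phi_ST"] <- perm_count["Phi_ST"] + 1L
    }
    # Phi_SC: individuals permuted among populations within groups
    p2 <- pop
    for (g in unique(grp)) {
      ix <- which(grp == g)
      p2[ix] <- sample(pop[ix])
    }
    phi2 <- components(X, p2, grp)$phi
    if (phi2["Phi_SC"] >= obs$phi["Phi_SC"] - 1e-12) {
      perm_count["Phi_SC"] <- perm_count["Phi_SC"] + 1L
    }
    # Phi_CT: whole populations permuted across groups
    g3map <- setNames(sample(pop2grp_vec), pop_levels)
    g3 <- unname(g3map[pop])
    phi3 <- components(X, pop, g3)$phi
    if (phi3["Phi_CT"] >= obs$phi["Phi_CT"] - 1e-12) {
      perm_count["Phi_CT"] <- perm_count["Phi_CT"] + 1L
    }
  }
  p <- (perm_count + 1) / (n_perm + 1)

  sig <- obs$sigma2
  truncated <- any(sig < 0)
  sig_t <- pmax(sig, 0)
  percent <- 100 * sig_t / sum(sig_t)
  structure(list(df = obs$df, SS = obs$SS, MS = obs$MS, sigma2 = obs$sigma2,
                 percent = percent, phi = obs$phi, p = p,
                 n_perm = as.integer(n_perm), seed = seed,
                 truncated = truncated),
            class = "amova_result")
}
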