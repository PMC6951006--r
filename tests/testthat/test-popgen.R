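test_that("locus statistics reproduce the published survey cells", {
  st <- locus_stats(table1_fixture())
  ref <- cnasus_locus_reference()
  m <- merge(st, ref, by = c("locus_id", "population_id"))
  expect_equal(nrow(m), 30)
  expect_equal(m$f_sine, m$f, tolerance = 1e-12)
  expect_equal(m$het_obs, m$het, tolerance = 1e-12)
  xs40 <- st[st$locus_id == "Ls40" & st$population_id == "XS", ]
  expect_equal(xs40$f_sine, 0.90)
  expect_equal(xs40$het_obs, 0.20)
})

test_that("locus statistics agree with a direct recount on random tables", {
  set.seed(401)
  for (i in 1:10) {
    freqs <- matrix(runif(6), 2, 3,
                    dimnames = list(c("P1", "P2"), c("L1", "L2", "L3")))
    tab <- simulate_genotypes(freqs, 15)
    st <- locus_stats(tab)
    for (r in seq_len(nrow(st))) {
      sub <- tab[tab$locus_id == st$locus_id[r] &
                   tab$population_id == st$population_id[r], ]
      n_ii <- sum(sub$genotype == "II"); n_ia <- sum(sub$genotype == "IA")
      n <- nrow(sub)
      expect_equal(st$f_sine[r], (2 * n_ii + n_ia) / (2 * n))
      expect_equal(st$het_obs[r], n_ia / n)
    }
  }
  mono <- locus_table(data.frame(locus_id = "L", population_id = "P",
                                 individual_id = as.character(1:5),
                                 genotype = "II"))
  st <- locus_stats(mono)
  expect_equal(st$f_sine, 1)
  expect_equal(st$het_obs, 0)
  expect_equal(st$hwe_p, 1)
})

test_that("missing genotypes are excluded, all-missing cells flagged", {
  tab <- locus_table(data.frame(locus_id = "L", population_id = "P",
                                individual_id = as.character(1:4),
                                genotype = c("II", "IA", "missing", "missing")))
  st <- locus_stats(tab)
  expect_equal(st$n, 2)
  expect_equal(st$f_sine, 0.75)
  allmiss <- locus_table(data.frame(locus_id = "L", population_id = "P",
                                    individual_id = as.character(1:2),
                                    genotype = "missing"))
  st0 <- locus_stats(allmiss)
  expect_equal(st0$n, 0)
  expect_true(is.na(st0$f_sine))
})

test_that("HWE exact p equals exhaustive enumeration", {
  expect_equal(hwe_exact(10, 0, 0), 1)
  expect_equal(hwe_exact(0, 10, 0), oracle_hwe_p(0, 10, 0), tolerance = 1e-12)
  set.seed(402)
  for (i in 1:60) {
    n <- sample(1:25, 1)
    ii <- sample(0:n, 1); ia <- sample(0:(n - ii), 1); aa <- n - ii - ia
    expect_equal(hwe_exact(ii, ia, aa), oracle_hwe_p(ii, ia, aa),
                 tolerance = 1e-12, info = paste(ii, ia, aa))
  }
})

test_that("ecotype pooling behaves like weighted locus statistics", {
  tab <- table1_fixture()
  single <- setNames(unique(tab$population_id), unique(tab$population_id))
  eco1 <- ecotype_stats(tab, single)
  st <- locus_stats(tab)
  m <- merge(eco1$per_locus, st,
             by.x = c("locus_id", "ecotype"), by.y = c("locus_id", "population_id"))
  expect_equal(m$f_sine.x, m$f_sine.y)
  expect_equal(m$het_obs.x, m$het_obs.y)

  # pooling two identical populations doubles n and preserves f
  half <- tab[tab$population_id == "XS", ]
  twin <- half; twin$population_id <- "XS2"
  both <- locus_table(rbind(as.data.frame(half), as.data.frame(twin)))
  pooled <- ecotype_stats(both, c(XS = "eco", XS2 = "eco"))
  stx <- locus_stats(locus_table(as.data.frame(half)))
  m2 <- merge(pooled$per_locus, stx, by = "locus_id")
  expect_equal(m2$n.x, 2 * m2$n.y)
  expect_equal(m2$f_sine.x, m2$f_sine.y)

  expect_error(ecotype_stats(tab, c(XS = "a")), "missing from grouping")
})

test_that("Nei distance matches the closed form and handles edge cases", {
  f_same <- matrix(c(0.3, 0.8, 0.3, 0.8), 2, 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("L1", "L2")))
  d <- nei_distance(f_same)
  expect_equal(unname(d["A", "B"]), 0)
  expect_equal(unname(diag(d)), c(0, 0))

  f_hand <- matrix(c(0.9, 0.1), 2, 1, dimnames = list(c("A", "B"), "L1"))
  d2 <- nei_distance(f_hand)
  expect_equal(unname(d2["A", "B"]), -log(0.18 / 0.82), tolerance = 1e-12)
  expect_equal(unname(d2["A", "B"]), 1.5163, tolerance = 1e-4)

  f_disj <- matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "L1"))
  d3 <- nei_distance(f_disj)
  expect_equal(unname(d3["A", "B"]), 10)
  expect_true(attr(d3, "capped")["A", "B"])

  # monotone in |f1 - f2| for a single biallelic locus
  gaps <- seq(0, 0.4, by = 0.1)
  ds <- vapply(gaps, function(g) {
    f <- matrix(c(0.5 - g, 0.5 + g), 2, 1, dimnames = list(c("A", "B"), "L"))
    unname(nei_distance(f)["A", "B"])
  }, numeric(1))
  expect_true(all(diff(ds) > -1e-12))

  da <- nei_distance(f_hand, method = "da")
  expect_equal(unname(da["A", "B"]), 1 - (sqrt(0.09) + sqrt(0.09)),
               tolerance = 1e-12)
})

test_that("NJ recovers additive trees exactly", {
  # 4-taxon additive matrix with known topology ((A,B),(C,D))
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  d <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(d)
  expect_true(is_cherry(nj, "A", "B"))
  expect_true(is_cherry(nj, "C", "D"))
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)

  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- nj_tree(d3)
  lens <- setNames(nj3$edge.length[match(1:3, nj3$edge[, 2])], nj3$tip.label)
  expect_equal(unname(lens["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(lens["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(lens["C"]), (4 + 5 - 3) / 2)

  # random additive metrics over 50 seeds reproduce the generating topology
  set.seed(403)
  for (i in 1:50) {
    ra <- random_additive_matrix(sample(4:8, 1))
    nj <- nj_tree(ra$d)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("A", "B"), c("A", "B")))),
               "3")
})

test_that("the published frequencies join PY and DT as a cherry", {
  ref <- cnasus_locus_reference()
  freqs <- with(ref, tapply(f, list(population_id, locus_id), mean))
  tree <- nj_tree(nei_distance(freqs))
  expect_true(is_cherry(tree, "PY", "DT"))
})

test_that("AMOVA components match the pairwise-distance oracle", {
  set.seed(404)
  for (i in 1:5) {
    freqs <- matrix(runif(20, 0.1, 0.9), 4, 5,
                    dimnames = list(paste0("P", 1:4), paste0("L", 1:5)))
    tab <- simulate_genotypes(freqs, 3)
    grouping <- c(P1 = "g1", P2 = "g1", P3 = "g2", P4 = "g2")
    am <- amova(tab, grouping, n_perm = 9, seed = 1)
    dosage <- c(AA = 0, IA = 1, II = 2)
    X <- with(as.data.frame(tab),
              tapply(dosage[genotype],
                     list(paste(population_id, individual_id), locus_id), sum))
    pop <- substr(rownames(X), 1, 2)
    grp <- unname(grouping[pop])
    want <- oracle_amova_ss(X, pop, grp)
    expect_equal(am$SS[names(want)], want, tolerance = 1e-9)
  }
})

test_that("AMOVA detects planted divergence and respects the null", {
  set.seed(405)
  # strong divergence between groups
  freqs <- rbind(P1 = rep(0.95, 5), P2 = rep(0.95, 5),
                 P3 = rep(0.05, 5), P4 = rep(0.05, 5))
  colnames(freqs) <- paste0("L", 1:5)
  tab <- simulate_genotypes(freqs, 10)
  grouping <- c(P1 = "mig", P2 = "mig", P3 = "res", P4 = "res")
  am <- amova(tab, grouping, n_perm = 199, seed = 2)
  expect_gt(am$phi[["Phi_CT"]], 0.5)
  expect_lte(am$p[["Phi_ST"]], 0.01)
  expect_equal(sum(am$percent), 100, tolerance = 1e-6)

  # identical composition: among-group component vanishes
  base <- simulate_genotypes(matrix(0.5, 1, 5,
                                    dimnames = list("P1", paste0("L", 1:5))),
                             10)
  clones <- lapply(c("P2", "P3", "P4"), function(p) {
    d <- as.data.frame(base); d$population_id <- p
    d$individual_id <- sub("P1", p, d$individual_id); d
  })
  null_tab <- locus_table(do.call(rbind, c(list(as.data.frame(base)), clones)))
  am0 <- amova(null_tab, grouping, n_perm = 99, seed = 3)
  expect_lte(am0$phi[["Phi_CT"]], 1e-9)
  expect_equal(unname(am0$percent["a"]), 0)

  expect_error(amova(tab, c(P1 = "g")), "missing from grouping")
  one_ind <- locus_table(data.frame(locus_id = "L", population_id = c("P", "P", "Q"),
                                    individual_id = c("1", "2", "1"),
                                    genotype = "II"))
  expect_error(amova(one_ind, c(P = "a", Q = "b")), ">= 2 individuals")
})
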