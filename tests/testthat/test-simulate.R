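test_that("simulated pedigrees are deterministic and promiscuous", {
  cfg <- sim_config(seed = 51, n_founders = 60, n_generations = 4,
                    n_per_generation = 150)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  pc <- pedigree_pair_counts(p1)
  expect_gt(pc[["half_sib"]] / max(pc[["full_sib"]], 1), 10)
  # zero offspring generations -> founders only
  p0 <- simulate_pedigree(sim_config(seed = 52, n_founders = 10,
                                     n_generations = 0))
  expect_true(all(is.na(p0$sire)))
  expect_equal(sum(pedigree_pair_counts(p0)), 0)
})

test_that("infeasible mating pools are an explicit error", {
  # founders all one sex makes generation 1 impossible
  cfg <- sim_config(seed = 53, n_founders = 3, n_generations = 1,
                    n_per_generation = 5)
  ped <- simulate_pedigree(cfg)   # 3 founders: F, M, F -> feasible
  expect_equal(nrow(ped), 8)
  cfg2 <- sim_config(seed = 53, n_founders = 2, n_generations = 2,
                     n_per_generation = 2, parent_window = 1)
  # generation 2 parents must come from generation 1 only; if all
  # generation-1 children are one sex this must error, so try seeds
  errs <- vapply(1:30, function(s) {
    cfg3 <- sim_config(seed = s, n_founders = 2, n_generations = 2,
                       n_per_generation = 2, parent_window = 1)
    inherits(tryCatch(simulate_pedigree(cfg3), error = function(e) e),
             "error")
  }, TRUE)
  expect_true(any(errs))
})

test_that("gene dropping obeys Mendel and Hardy-Weinberg", {
  cfg <- sim_config(seed = 54, n_founders = 200, n_generations = 1,
                    n_per_generation = 200, n_snps = 2500)
  ped <- simulate_pedigree(cfg)
  g <- drop_genotypes(ped, cfg)
  # child of 2 x 2 parents is always 2 (rows indexed by id: the
  # generator orders genotype rows by pedigree toposort)
  dos <- g$dosages
  kids <- ped$id[!is.na(ped$sire)]
  sire_of <- setNames(ped$sire, ped$id)
  dam_of <- setNames(ped$dam, ped$id)
  viol <- 0
  for (k in kids[1:50]) {
    both2 <- dos[sire_of[k], ] == 2 & dos[dam_of[k], ] == 2
    viol <- viol + sum(dos[k, both2] != 2)
  }
  expect_equal(viol, 0)
  # founder inbreeding centred at zero under HWE
  founders <- ped$id[is.na(ped$sire)]
  f3 <- fhat3(subset_genotypes(g, individuals = founders))
  expect_lt(abs(mean(f3)), 0.02)
  # parent-offspring realized relatedness ~ 0.5
  G <- build_grm(g)
  po <- vapply(kids, function(k) G$values[k, sire_of[k]], 0)
  expect_equal(mean(po), 0.5, tolerance = 0.03)
})

test_that("half-sib pairs average ~0.25 realized relatedness", {
  cfg <- sim_config(seed = 55, n_founders = 120, n_generations = 1,
                    n_per_generation = 250, n_snps = 2500)
  ped <- simulate_pedigree(cfg)
  g <- drop_genotypes(ped, cfg)
  G <- build_grm(g)
  si <- ped$sire; di <- ped$dam
  idx <- which(!is.na(si))
  hs <- combn(idx, 2)
  share_sire <- si[hs[1, ]] == si[hs[2, ]]
  share_dam <- di[hs[1, ]] == di[hs[2, ]]
  hs_pairs <- hs[, xor(share_sire, share_dam), drop = FALSE]
  unrel <- hs[, !share_sire & !share_dam, drop = FALSE]
  # map pedigree rows to GRM positions by id
  gix <- function(rows) match(ped$id[rows], G$ids)
  vals <- G$values[cbind(gix(hs_pairs[1, ]), gix(hs_pairs[2, ]))]
  expect_lt(abs(mean(vals) - 0.25), 0.02)
  expect_lt(abs(mean(G$values[cbind(gix(unrel[1, ]),
                                    gix(unrel[2, ]))])), 0.02)
})

test_that("polygenic phenotypes realize their target variance structure", {
  cfg <- sim_config(seed = 56, n_founders = 150, n_generations = 3,
                    n_per_generation = 220, n_snps = 1500,
                    h2_additive = 0.4, family_fraction = 0)
  st <- simulate_study(cfg)
  tr <- st$truth
  ph <- st$phenotypes
  bv <- tr$breeding_values[ph$id]
  fit <- lm(ph$y ~ bv + factor(ph$sex))
  expect_equal(unname(coef(fit)["bv"]), 1, tolerance = 0.1)
  r2 <- var(bv) / var(ph$y - (ph$sex == "M") * cfg$beta_sex)
  expect_equal(r2, 0.4, tolerance = 0.05)
})

test_that("repeated measures realize the intended repeatability", {
  cfg <- sim_config(seed = 57, n_founders = 100, n_generations = 2,
                    n_per_generation = 200, n_snps = 600,
                    h2_additive = 0.3, family_fraction = 0,
                    perm_env_fraction = 0.2, records_per_adult = 3)
  st <- simulate_study(cfg)
  ph <- st$phenotypes
  # intra-individual correlation ~ individual-level / total variance
  ph$yc <- ph$y - (ph$sex == "M") * cfg$beta_sex
  ind_means <- tapply(ph$yc, ph$id, mean)
  within <- tapply(ph$yc, ph$id, var)
  rep_target <- 0.5   # (0.3 + 0.2) / 1
  vw <- mean(within)
  vb <- var(ind_means) - vw / 3
  expect_lt(abs(vb / (vb + vw) - rep_target), 0.06)
})

test_that("all-residual traits leave sibs uncorrelated", {
  cfg <- sim_config(seed = 58, n_founders = 100, n_generations = 2,
                    n_per_generation = 250, n_snps = 400,
                    h2_additive = 0, family_fraction = 0)
  st <- simulate_study(cfg)
  ph <- st$phenotypes
  ped <- st$pedigree
  dam <- ped$dam[match(ph$id, ped$id)]
  sibs <- split(ph$y, dam)
  sibs <- sibs[lengths(sibs) >= 2]
  pair1 <- vapply(sibs, `[`, 0, 1)
  pair2 <- vapply(sibs, `[`, 0, 2)
  expect_lt(abs(cor(pair1, pair2)), 0.12)
})

test_that("variance fractions summing above one are rejected", {
  expect_error(sim_config(seed = 1, h2_additive = 0.7,
                          family_fraction = 0.4), "sum to at most 1")
  expect_error(sim_config(seed = 1, h2_additive = -0.1), "sum to at most 1")
})

test_that("monogenic patterns map genotype classes correctly", {
  cfg <- sim_config(seed = 59, n_founders = 300, n_generations = 1,
                    n_per_generation = 400, n_snps = 50,
                    founder_freq_range = c(0.4, 0.4))
  ped <- simulate_pedigree(cfg)
  g <- drop_genotypes(ped, cfg)
  dom <- simulate_monogenic_trait(ped, g, "snp00001", "dominant",
                                  seed = 2)
  dos <- g$dosages[, "snp00001"]
  expect_setequal(unique(dom$phenotypes$class), c("a", "A"))
  expect_true(all(dom$phenotypes$class[dos > 0] == "A"))
  cod <- simulate_monogenic_trait(ped, g, "snp00001", "codominant",
                                  seed = 2)
  expect_setequal(unique(cod$phenotypes$class), c("a", "Aa", "A"))
  expect_true(all(cod$phenotypes$y %in% 0:2))
  # sex-limited: two classes in males, three in females
  sexlim <- simulate_monogenic_trait(
    ped, g, "snp00001",
    pattern = list(M = "dominant", F = "codominant"), seed = 2)
  phM <- sexlim$phenotypes[sexlim$phenotypes$sex == "M", ]
  phF <- sexlim$phenotypes[sexlim$phenotypes$sex == "F", ]
  expect_equal(length(unique(phM$class)), 2)
  expect_equal(length(unique(phF$class)), 3)
  # class proportions follow Hardy-Weinberg at the causal frequency
  p <- mean(dos) / 2
  prop_A <- mean(dom$phenotypes$class == "A")
  expect_equal(prop_A, p^2 + 2 * p * (1 - p), tolerance = 0.05)
  expect_error(simulate_monogenic_trait(ped, g, "nope", "dominant"),
               "not in the panel")
})

test_that("identical configs give identical studies end to end", {
  cfg <- sim_config(seed = 60, n_founders = 40, n_generations = 2,
                    n_per_generation = 60, n_snps = 200)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotypes, s2$phenotypes)
})
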