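#' Configuration of a synthetic wild-pedigree study
#'
#' Defaults emulate the structure of a multigenerational wild ungulate
#' study population: overlapping generations, promiscuous mating in both
#' sexes (so half-sibling pairs vastly outnumber full-sibling pairs, in
#' expectation by more than an order of magnitude), low mean pairwise
#' relatedness, mild inbreeding arising from finite population size, and
#' quantitative traits with additive, family-associated, maternal, cohort
#' and permanent-environment variance.
#'
#' @param seed mandatory integer seed; identical configs give identical
#'   studies.
#' @param n_founders founder individuals (generation 0).
#' @param n_generations number of offspring generations.
#' @param n_per_generation individuals born per generation.
#' @param parent_window how many preceding generations supply parents
#'   (overlapping generations when > 1).
#' @param n_snps unlinked biallelic SNPs, spread uniformly over
#'   `n_chromosomes`.
#' @param n_chromosomes autosome count for the SNP map.
#' @param founder_freq_range counted-allele frequency range for founder
#'   SNPs (uniform draw).
#' @param h2_additive target additive (population-level) variance
#'   fraction of the polygenic trait.
#' @param family_fraction target family-associated variance fraction.
#' @param family_mode how family-associated variance is generated:
#'   `"kinship"` draws it with the covariance of the
#'   relatedness-thresholded GRM (within-family genetic variance --- the
#'   structure the two-GRM model fits, so the fraction is recoverable);
#'   `"common_env"` gives maternal sibships a shared environmental
#'   deviate; `"dominance"` sums per-SNP dominance deviations.
#' @param kin_threshold relatedness threshold used by the `"kinship"`
#'   family mode.
#' @param maternal_fraction,year_fraction,perm_env_fraction further
#'   variance fractions (maternal identity, birth-year cohort, permanent
#'   environment across repeated records).
#' @param records_per_adult measurement records per phenotyped
#'   individual (> 1 gives repeated measures).
#' @param n_causal causal SNPs behind the polygenic trait.
#' @param beta_sex fixed sex difference in phenotypic SD units.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed, n_founders = 80, n_generations = 5,
                       n_per_generation = 200, parent_window = 2,
                       n_snps = 2000, n_chromosomes = 26,
                       founder_freq_range = c(0.05, 0.5),
                       h2_additive = 0.3, family_fraction = 0.15,
                       family_mode = c("kinship", "common_env",
                                       "dominance"),
                       kin_threshold = 0.1, maternal_fraction = 0,
                       year_fraction = 0, perm_env_fraction = 0,
                       records_per_adult = 1, n_causal = 200,
                       beta_sex = 0.25) {
  if (missing(seed)) stop("a seed is mandatory")
  family_mode <- match.arg(family_mode)
  fr <- c(h2_additive, family_fraction, maternal_fraction, year_fraction,
          perm_env_fraction)
  if (any(fr < 0) || sum(fr) > 1)
    stop("variance fractions must be >= 0 and sum to at most 1")
  if (n_founders < 2 || n_generations < 0)
    stop("need n_founders >= 2 and n_generations >= 0")
  structure(list(seed = as.integer(seed), n_founders = n_founders,
                 n_generations = n_generations,
                 n_per_generation = n_per_generation,
                 parent_window = parent_window, n_snps = n_snps,
                 n_chromosomes = n_chromosomes,
                 founder_freq_range = founder_freq_range,
                 h2_additive = h2_additive,
                 family_fraction = family_fraction,
                 family_mode = family_mode,
                 kin_threshold = kin_threshold,
                 maternal_fraction = maternal_fraction,
                 year_fraction = year_fraction,
                 perm_env_fraction = perm_env_fraction,
                 records_per_adult = records_per_adult,
                 n_causal = n_causal, beta_sex = beta_sex),
            class = "sim_config")
}

#' Simulate an overlapping-generation promiscuous pedigree
#'
#' Each new individual draws its dam and sire independently and uniformly
#' from the females/males of the preceding `parent_window` generations.
#' Independent parent draws per offspring make a repeated (sire, dam)
#' pairing — a full-sib pair — rare relative to a shared single parent,
#' matching wild promiscuous mating systems.
#'
#' @param cfg a [sim_config()].
#' @return pedigree data frame with columns `id`, `sire`, `dam`, `sex`
#'   (`"F"`/`"M"`), `birth_year` (generation index).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n0 <- cfg$n_founders
  total <- n0 + cfg$n_generations * cfg$n_per_generation
  wid <- nchar(as.character(total))
  mkid <- function(i) sprintf(paste0("i%0", wid, "d"), i)
  id <- mkid(seq_len(n0))
  sex <- rep(c("F", "M"), length.out = n0)
  sire <- dam <- rep(NA_character_, n0)
  byear <- rep(0L, n0)
  nxt <- n0 + 1L
  for (g in seq_len(cfg$n_generations)) {
    window <- byear >= (g - cfg$parent_window) & byear <= (g - 1L)
    females <- id[window & sex == "F"]
    males <- id[window & sex == "M"]
    if (!length(females) || !length(males))
      stop("no available mates in generation ", g,
           "; enlarge n_founders or parent_window")
    k <- cfg$n_per_generation
    new_id <- mkid(seq(nxt, length.out = k))
    id <- c(id, new_id)
    dam <- c(dam, sample(females, k, replace = TRUE))
    sire <- c(sire, sample(males, k, replace = TRUE))
    sex <- c(sex, sample(c("F", "M"), k, replace = TRUE))
    byear <- c(byear, rep(g, k))
    nxt <- nxt + k
  }
  data.frame(id = id, sire = sire, dam = dam, sex = sex,
             birth_year = byear, stringsAsFactors = FALSE)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders draw genotypes from Hardy-Weinberg proportions at per-SNP
#' counted-allele frequencies; each descendant receives one Mendelian
#' gamete per parent, SNPs segregating independently (unlinked loci).  A
#' missing parent's gamete is drawn from the founder frequencies.  The
#' realized GRM of such a panel converges to the pedigree expectation A
#' as the SNP count grows.
#'
#' @param ped pedigree data frame (id, sire, dam; extra columns ignored).
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] over all pedigree members, with SNPs
#'   spread evenly across `cfg$n_chromosomes`.
#' @export
drop_genotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- validate_pedigree(ped)
  set.seed(cfg$seed + 1L)
  m <- cfg$n_snps
  p <- stats::runif(m, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  ord <- pedigree_toposort(ped)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  dos <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    gam_s <- if (is.na(si[i])) stats::rbinom(m, 1L, p)
             else stats::rbinom(m, 1L, dos[si[i], ] / 2)
    gam_d <- if (is.na(di[i])) stats::rbinom(m, 1L, p)
             else stats::rbinom(m, 1L, dos[di[i], ] / 2)
    dos[i, ] <- gam_s + gam_d
  }
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    seq_len(length(ix)) * 50000L), use.names = FALSE)
  snps <- snp_table(sprintf("snp%05d", seq_len(m)), chrom, pos,
                    counted_allele = "A", other_allele = "B")
  genotype_matrix(dos, ped$id, snps)
}

#' Simulate a polygenic quantitative trait on a simulated study
#'
#' Phenotypes are built as fixed sex effect + additive breeding values
#' (centered causal dosages times normal effects) + family-associated
#' deviation + maternal + cohort + permanent-environment effects +
#' record-level residual.  Each realized component is rescaled to its
#' exact target variance fraction among phenotyped individuals, so the
#' truth record reproduces the generating fractions without Monte-Carlo
#' drift in the component sizes themselves.
#'
#' @param ped pedigree as from [simulate_pedigree()] (needs `sex`,
#'   `birth_year`).
#' @param genotypes matching [genotype_matrix()].
#' @param cfg a [sim_config()].
#' @param phenotyped ids to phenotype; default all non-founders.
#' @param grm_full optional precomputed full-panel [grm()] of
#'   `genotypes` (reused by the `"kinship"` family mode instead of
#'   rebuilding it).
#' @return list with `phenotypes` (record data frame: `id`, `y`, `sex`,
#'   `birth_year`, `dam`) and `truth` (target fractions, causal SNP ids,
#'   effect sizes, per-individual component vectors).
#' @export
simulate_polygenic_trait <- function(ped, genotypes, cfg,
                                     phenotyped = NULL,
                                     grm_full = NULL) {
  stopifnot(inherits(cfg, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  set.seed(cfg$seed + 2L)
  if (is.null(phenotyped))
    phenotyped <- ped$id[!is.na(ped$sire) | !is.na(ped$dam)]
  phenotyped <- intersect(phenotyped, genotypes$sample_ids)
  n <- length(phenotyped)
  if (n < 2) stop("need at least two phenotyped individuals")
  pinfo <- ped[match(phenotyped, ped$id), ]

  scale_to <- function(x, frac) {
    if (frac <= 0) return(numeric(length(x)))
    s <- stats::sd(x)
    if (s < 1e-12) return(numeric(length(x)))
    x / s * sqrt(frac)
  }

  g <- subset_genotypes(genotypes, individuals = phenotyped)
  causal <- sample(g$snps$snp_id, min(cfg$n_causal, nrow(g$snps)))
  beta <- stats::rnorm(length(causal))
  dosc <- g$dosages[, causal, drop = FALSE]
  pc <- colMeans(dosc) / 2
  dosc <- sweep(dosc, 2, 2 * pc, "-")
  # standardized per-allele effects: effect variance proportional to
  # 1/(2p(1-p)), the architecture the MAF-weighted GRM models
  dosc <- sweep(dosc, 2, sqrt(pmax(2 * pc * (1 - pc), 1e-12)), "/")
  a <- scale_to(drop(dosc %*% beta), cfg$h2_additive)

  fam <- numeric(n)
  if (cfg$family_fraction > 0) {
    fam <- switch(cfg$family_mode,
      kinship = {
        full <- if (is.null(grm_full)) build_grm(genotypes) else grm_full
        ix <- match(phenotyped, full$ids)
        kin <- threshold_grm(full, cfg$kin_threshold)$values[ix, ix]
        ei <- eigen(kin, symmetric = TRUE)
        lam <- pmax(ei$values, 0)
        raw <- drop(ei$vectors %*% (sqrt(lam) * stats::rnorm(n)))
        scale_to(raw, cfg$family_fraction)
      },
      common_env = {
        famfac <- factor(ifelse(is.na(pinfo$dam), pinfo$id, pinfo$dam))
        dev <- stats::rnorm(nlevels(famfac))
        scale_to(dev[as.integer(famfac)], cfg$family_fraction)
      },
      dominance = {
        dd <- stats::rnorm(length(causal))
        het <- (g$dosages[, causal, drop = FALSE] == 1) * 1
        het <- sweep(het, 2, colMeans(het), "-")
        scale_to(drop(het %*% dd), cfg$family_fraction)
      })
  }

  mat <- numeric(n)
  if (cfg$maternal_fraction > 0) {
    mfac <- factor(ifelse(is.na(pinfo$dam), pinfo$id, pinfo$dam))
    mat <- scale_to(stats::rnorm(nlevels(mfac))[as.integer(mfac)],
                    cfg$maternal_fraction)
  }
  yr <- numeric(n)
  if (cfg$year_fraction > 0) {
    yfac <- factor(pinfo$birth_year)
    yr <- scale_to(stats::rnorm(nlevels(yfac))[as.integer(yfac)],
                   cfg$year_fraction)
  }
  pe <- numeric(n)
  if (cfg$perm_env_fraction > 0)
    pe <- scale_to(stats::rnorm(n), cfg$perm_env_fraction)

  resid_frac <- 1 - cfg$h2_additive - cfg$family_fraction -
    cfg$maternal_fraction - cfg$year_fraction - cfg$perm_env_fraction
  indiv_value <- a + fam + mat + yr + pe +
    cfg$beta_sex * (pinfo$sex == "M")

  k <- max(1L, as.integer(cfg$records_per_adult))
  rec_id <- rep(phenotyped, each = k)
  rec_ix <- rep(seq_len(n), each = k)
  eps <- scale_to(stats::rnorm(n * k), resid_frac)
  phen <- data.frame(id = rec_id,
                     y = indiv_value[rec_ix] + eps,
                     sex = pinfo$sex[rec_ix],
                     birth_year = pinfo$birth_year[rec_ix],
                     dam = ifelse(is.na(pinfo$dam[rec_ix]),
                                  pinfo$id[rec_ix], pinfo$dam[rec_ix]),
                     stringsAsFactors = FALSE)
  truth <- list(fractions = c(additive = cfg$h2_additive,
                              family = cfg$family_fraction,
                              maternal = cfg$maternal_fraction,
                              year = cfg$year_fraction,
                              perm_env = cfg$perm_env_fraction,
                              residual = resid_frac),
                family_mode = cfg$family_mode,
                kin_threshold = cfg$kin_threshold,
                causal_snps = causal, beta = beta,
                breeding_values = stats::setNames(a, phenotyped),
                family_effects = stats::setNames(fam, phenotyped))
  list(phenotypes = phen, truth = truth)
}

#' Simulate a monogenic categorical trait
#'
#' Assigns phenotype classes from the genotype at one causal SNP.
#' Patterns: `"dominant"` (any copy of the counted allele gives the
#' dominant class; two classes) and `"codominant"` (three classes, one
#' per genotype).  A sex-limited architecture may use a different pattern
#' per sex, as for horn morphology where the wildtype allele is dominant
#' in males but codominant in females.
#'
#' @param ped pedigree with `sex` column.
#' @param genotypes [genotype_matrix()] containing the causal SNP.
#' @param causal_snp SNP id of the causal locus.
#' @param pattern `"dominant"`, `"codominant"`, or a named list
#'   `list(F = ..., M = ...)` for sex-limited patterns.
#' @param misclassification probability a phenotype is replaced by a
#'   uniformly drawn different class.
#' @param seed integer seed.
#' @return list with `phenotypes` (data frame `id`, `class`, `y`
#'   (numeric coding via [code_categorical_trait()] per sex), `sex`) and
#'   `truth` (causal genotypes and pattern).
#' @export
simulate_monogenic_trait <- function(ped, genotypes, causal_snp,
                                     pattern = "dominant",
                                     misclassification = 0, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!causal_snp %in% genotypes$snps$snp_id)
    stop("causal SNP '", causal_snp, "' is not in the panel")
  set.seed(seed)
  dos <- genotypes$dosages[, causal_snp]
  sex <- ped$sex[match(genotypes$sample_ids, ped$id)]
  classify <- function(d, pat) {
    switch(pat,
           dominant = ifelse(d > 0, "A", "a"),
           codominant = c("a", "Aa", "A")[d + 1],
           stop("unknown pattern: ", pat))
  }
  cls <- if (is.list(pattern)) {
    out <- character(length(dos))
    for (sx in names(pattern))
      out[sex == sx] <- classify(dos[sex == sx], pattern[[sx]])
    out
  } else classify(dos, pattern)
  if (misclassification > 0) {
    flip <- stats::runif(length(cls)) < misclassification
    for (i in which(flip)) {
      pool <- setdiff(unique(cls[if (is.list(pattern)) sex == sex[i]
                                 else TRUE]), cls[i])
      if (length(pool)) cls[i] <- sample(pool, 1)
    }
  }
  keep <- !is.na(dos) & !is.na(cls) & cls != ""
  y <- numeric(sum(keep))
  sexk <- sex[keep]
  clsk <- cls[keep]
  for (sx in unique(sexk)) {
    ix <- sexk == sx
    y[ix] <- code_categorical_trait(clsk[ix])
  }
  list(phenotypes = data.frame(id = genotypes$sample_ids[keep],
                               class = clsk, y = y, sex = sexk,
                               stringsAsFactors = FALSE),
       truth = list(causal_snp = causal_snp, pattern = pattern,
                    causal_dosage = stats::setNames(
                      dos[keep], genotypes$sample_ids[keep])))
}

#' Simulate a complete study (pedigree, genotypes, polygenic trait)
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [drop_genotypes()] and [simulate_polygenic_trait()] under one config.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_study`: list with `pedigree`,
#'   `genotypes`, `grm` (full-panel [grm()]), `phenotypes`, `truth`,
#'   `config`.
#' @export
simulate_study <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  g <- drop_genotypes(ped, cfg)
  # drift can fix alleles; the analysis panel is the polymorphic subset
  # (the QC step any real pipeline applies)
  p <- colMeans(g$dosages) / 2
  poly <- which(p > 0 & p < 1)
  if (length(poly) < ncol(g$dosages))
    g <- subset_genotypes(g, snps = poly)
  gf <- build_grm(g)
  tr <- simulate_polygenic_trait(ped, g, cfg, grm_full = gf)
  structure(list(pedigree = ped, genotypes = g, grm = gf,
                 phenotypes = tr$phenotypes, truth = tr$truth,
                 config = cfg),
            class = "sim_study")
}
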