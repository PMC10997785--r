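# Fixture builders and independent oracles shared across the test files.

# small genotype fixture with explicit dosages
make_geno <- function(dos, ids = NULL, chrom = 1, pos = NULL) {
  dos <- as.matrix(dos)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(nrow(dos)))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 1000L
  genotype_matrix(dos, ids,
                  snp_table(sprintf("s%03d", seq_len(ncol(dos))),
                            chrom, pos))
}

# brute-force per-pair, per-SNP evaluation of the printed IBS estimator
# (complete panels; N = number of SNPs)
naive_grm <- function(dos, p) {
  n <- nrow(dos)
  m <- ncol(dos)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (z in seq_len(m)) {
        den <- 2 * p[z] * (1 - p[z])
        if (i == j) {
          acc <- acc + (dos[i, z]^2 - (1 + 2 * p[z]) * dos[i, z] +
                          2 * p[z]^2) / den
        } else {
          acc <- acc + (dos[i, z] - 2 * p[z]) * (dos[j, z] - 2 * p[z]) / den
        }
      }
      A[i, j] <- if (i == j) 1 + acc / m else acc / m
    }
  }
  A
}

# independent recursive coancestry oracle; A = 2 * kinship
kinship_oracle <- function(ped) {
  ped <- ped[, c("id", "sire", "dam")]
  # ensure parents precede children
  ord <- heritpart:::pedigree_toposort(heritpart:::validate_pedigree(ped))
  ped <- ped[ord, ]
  n <- nrow(ped)
  id <- ped$id
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fs <- if (is.na(si[i]) || is.na(di[i])) 0 else f[si[i], di[i]]
    f[i, i] <- 0.5 * (1 + fs)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        v <- 0.5 * ((if (is.na(si[i])) 0 else f[si[i], j]) +
                    (if (is.na(di[i])) 0 else f[di[i], j]))
        f[i, j] <- f[j, i] <- v
      }
    }
  }
  dimnames(f) <- list(id, id)
  2 * f
}

# random valid pedigree: founders plus children drawing parents from
# earlier individuals
random_pedigree <- function(n, n_founders = 10, seed = 1) {
  set.seed(seed)
  id <- sprintf("p%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  sex[1:2] <- c("F", "M")
  for (i in (n_founders + 1):n) {
    prev <- seq_len(i - 1)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males)) sire[i] <- id[sample(males, 1)]
    if (length(females)) dam[i] <- id[sample(females, 1)]
  }
  data.frame(id = id, sire = sire, dam = dam, sex = sex,
             stringsAsFactors = FALSE)
}

# dense from-first-principles REML criterion using generic solve/det
reml_oracle <- function(y, X, Vcs, sigma2) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(rep(sigma2[["residual"]], n))
  for (lab in names(Vcs)) V <- V + sigma2[[lab]] * Vcs[[lab]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(y) %*% P %*% y + (n - p) * log(2 * pi)))
}

# construct a vc_fit by hand (for ratio / partition arithmetic tests)
fake_fit <- function(sigma2, sampling_cov = NULL, loglik = 0,
                     n_records = 100) {
  labs <- names(sigma2)
  if (is.null(sampling_cov))
    sampling_cov <- diag(1e-4, length(labs))
  dimnames(sampling_cov) <- list(labs, labs)
  structure(list(sigma2 = sigma2, loglik = loglik,
                 sampling_cov = sampling_cov, converged = TRUE,
                 n_iterations = 1L,
                 constraint_flags = stats::setNames(
                   rep(FALSE, length(labs)), labs),
                 n_records = n_records, n_fixed = 1L, labels = labs),
            class = "vc_fit")
}

# tiny study used by several pipeline tests (cheap: ~350 individuals)
tiny_study <- function(seed = 11, ...) {
  cfg <- sim_config(seed = seed, n_founders = 60, n_generations = 3,
                    n_per_generation = 100, n_snps = 400,
                    h2_additive = 0.35, family_fraction = 0, ...)
  simulate_study(cfg)
}
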