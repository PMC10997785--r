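#' Genomic relationship matrix container
#'
#' @param values n x n symmetric numeric matrix of realized relatedness.
#' @param ids sample ids in matrix order.
#' @param n_snps number of SNPs the matrix was averaged over.
#' @param provenance list describing how the matrix was derived; `kind` is
#'   one of `"full"`, `"thresholded"`, `"maf"`, `"region"`, `"chromosome"`,
#'   `"pedigree"` with rule parameters alongside.
#' @param n_snps_pair optional matrix of per-pair SNP counts (per-pair
#'   missingness mode).
#' @return an object of class `grm`.
#' @export
grm <- function(values, ids, n_snps, provenance = list(kind = "full"),
                n_snps_pair = NULL) {
  values <- as.matrix(values)
  ids <- as.character(ids)
  if (nrow(values) != ncol(values) || nrow(values) != length(ids))
    stop("GRM must be square with one id per row")
  if (max(abs(values - t(values))) > 1e-10)
    stop("GRM must be symmetric")
  if (n_snps < 1) stop("n_snps_used must be >= 1")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, n_snps = as.integer(n_snps),
                 provenance = provenance, n_snps_pair = n_snps_pair),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  pv <- x$provenance
  extra <- pv[setdiff(names(pv), "kind")]
  cat("grm: ", length(x$ids), " individuals, ", x$n_snps, " SNPs, kind=",
      pv$kind,
      if (length(extra)) paste0(" (", paste(names(extra), unlist(extra),
                                            sep = "=", collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Counted-allele frequencies of a genotype panel
#'
#' Per-SNP frequency of the counted allele, computed over non-missing
#' calls: `p_z = sum(dosages at z) / (2 * n_obs_z)`.
#'
#' @param g a [genotype_matrix()].
#' @return an object of class `allele_freqs`: list with `p`, `n_obs` and
#'   `snp_id`.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_obs <- colSums(!is.na(g$dosages))
  if (any(n_obs == 0))
    stop("SNP(s) with no non-missing calls: ",
         paste(g$snps$snp_id[n_obs == 0], collapse = ", "))
  p <- colSums(g$dosages, na.rm = TRUE) / (2 * n_obs)
  structure(list(p = unname(p), n_obs = unname(n_obs),
                 snp_id = g$snps$snp_id),
            class = "allele_freqs")
}

# shared core: standardized dosages and the diagonal accumulator of the
# IBS relationship estimator.  Missing dosages contribute 0 to both the
# off-diagonal and the diagonal sums.
grm_core <- function(dos, p) {
  het <- 2 * p * (1 - p)
  obs <- !is.na(dos)
  centered <- sweep(dos, 2, 2 * p, "-")
  centered[!obs] <- 0
  D <- sweep(centered, 2, sqrt(het), "/")
  # per-SNP diagonal term (s^2 - (1+2p)s + 2p^2) / (2p(1-p)), 0 if missing
  s <- dos
  s[!obs] <- 0
  dterm <- s * s - sweep(s, 2, 1 + 2 * p, "*") +
    matrix(2 * p^2, nrow(dos), ncol(dos), byrow = TRUE)
  dterm <- sweep(dterm, 2, het, "/")
  dterm[!obs] <- 0
  list(D = D, diag_terms = dterm, obs = obs)
}

#' Build the identity-by-state genomic relationship matrix
#'
#' Implements the MAF-weighted IBS relationship estimator of Yang et al.
#' (the GCTA estimator): for individuals i != j the average over SNPs of
#' `(s_i - 2p)(s_j - 2p) / (2p(1-p))`, and for the diagonal
#' `1 + mean((s^2 - (1+2p)s + 2p^2) / (2p(1-p)))`, where `s` is the
#' counted-allele dosage and `p` the counted-allele frequency.  Sharing a
#' rare allele thus contributes more relatedness than sharing a common one.
#'
#' Missing dosages contribute zero to the sums.  By default the averaging
#' denominator stays at the panel SNP count `N`; with `per_pair_n = TRUE`
#' each pair (and each diagonal entry) is averaged over its own count of
#' jointly non-missing SNPs instead.
#'
#' @param g a [genotype_matrix()].
#' @param snp_subset optional character vector of SNP ids to use.
#' @param freqs optional [allele_frequencies()] for the full panel of `g`;
#'   computed from `g` when absent.  Supplying them fixes `p` (e.g. from a
#'   larger reference sample).
#' @param per_pair_n use per-pair non-missing SNP counts as denominators.
#' @param provenance provenance record for the result.
#' @return a [grm()].
#' @export
build_grm <- function(g, snp_subset = NULL, freqs = NULL,
                      per_pair_n = FALSE,
                      provenance = list(kind = "full")) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  sel <- seq_len(nrow(g$snps))
  if (!is.null(snp_subset)) {
    if (!length(snp_subset)) stop("snp_subset is empty")
    sel <- match(snp_subset, g$snps$snp_id)
    if (anyNA(sel))
      stop("unknown SNP ids in subset: ",
           paste(snp_subset[is.na(sel)], collapse = ", "))
  }
  p <- freqs$p[match(g$snps$snp_id[sel], freqs$snp_id)]
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop("monomorphic SNP(s) in GRM panel (2p(1-p) = 0): ",
         paste(utils::head(g$snps$snp_id[sel][mono], 5), collapse = ", "))
  dos <- g$dosages[, sel, drop = FALSE]
  N <- length(sel)
  core <- grm_core(dos, p)

  if (per_pair_n) {
    pairN <- tcrossprod(core$obs * 1)
    A <- tcrossprod(core$D) / pmax(pairN, 1)
    diag(A) <- 1 + rowSums(core$diag_terms) / pmax(diag(pairN), 1)
  } else {
    pairN <- NULL
    A <- tcrossprod(core$D) / N
    diag(A) <- 1 + rowSums(core$diag_terms) / N
  }
  grm(A, g$sample_ids, N, provenance, n_snps_pair = pairN)
}

#' SNP-based inbreeding coefficients (Fhat3)
#'
#' The excess-homozygosity inbreeding estimator equal to the IBS
#' relationship matrix diagonal minus one:
#' `Fhat3_i = mean_z (s^2 - (1+2p)s + 2p^2) / (2p(1-p))`.
#' Zero in expectation under Hardy-Weinberg random mating.
#'
#' @inheritParams build_grm
#' @return named numeric vector, one value per individual.
#' @export
fhat3 <- function(g, freqs = NULL, snp_subset = NULL, per_pair_n = FALSE) {
  A <- build_grm(g, snp_subset = snp_subset, freqs = freqs,
                 per_pair_n = per_pair_n)
  diag(A$values) - 1
}

#' Threshold a GRM into a kinship (close-relative) GRM
#'
#' Copies the input matrix with every off-diagonal relatedness estimate
#' equal to or less than `t` set to 0; entries above `t` and the whole
#' diagonal are untouched.  Fitting this matrix alongside the full GRM
#' separates family-associated (identity-by-descent) variance from
#' population-level identity-by-state variance.
#'
#' @param x a [grm()] (typically `kind = "full"`).
#' @param t relatedness threshold, `t >= 0`.
#' @return a `grm` with provenance `kind = "thresholded"`, `t = t`.
#' @export
threshold_grm <- function(x, t) {
  stopifnot(inherits(x, "grm"))
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("threshold t must be a single number >= 0")
  v <- x$values
  d <- diag(v)
  v[v <= t] <- 0
  diag(v) <- d
  prov <- list(kind = "thresholded", t = t,
               from = x$provenance$kind)
  grm(v, x$ids, x$n_snps, prov, n_snps_pair = x$n_snps_pair)
}

#' Select SNPs with minor allele frequency below a threshold
#'
#' Rare-allele panel selection: returns the SNPs whose minor allele
#' frequency `min(p, 1-p)` is strictly under `maf_threshold`.
#'
#' @param freqs an [allele_frequencies()].
#' @param snps the matching [snp_table()].
#' @param maf_threshold threshold in (0, 0.5].
#' @return character vector of SNP ids.
#' @export
maf_subset <- function(freqs, snps, maf_threshold) {
  stopifnot(inherits(freqs, "allele_freqs"))
  snps <- validate_snp_table(snps)
  if (maf_threshold <= 0 || maf_threshold > 0.5)
    stop("maf_threshold must lie in (0, 0.5]")
  p <- freqs$p[match(snps$snp_id, freqs$snp_id)]
  maf <- pmin(p, 1 - p)
  out <- snps$snp_id[!is.na(maf) & maf < maf_threshold]
  if (!length(out))
    stop("no SNPs below MAF threshold ", maf_threshold)
  out
}

#' Select SNPs in a genomic region around a causal gene
#'
#' Returns SNP ids on `chromosome` with position inside
#' `[center_start_bp - flank_bp, center_end_bp + flank_bp]` (1-based,
#' inclusive).  With `flank_bp = Inf` the whole chromosome is taken.
#' Refuses to return a panel smaller than `min_snps`: relationship
#' matrices averaged over a handful of SNPs are too noisy to fit.
#'
#' @param snps a [snp_table()].
#' @param chromosome chromosome label.
#' @param center_start_bp,center_end_bp gene span (1-based inclusive).
#' @param flank_bp flank added on each side; `Inf` = whole chromosome.
#' @param min_snps refusal floor (default 10); use 1 to disable.
#' @return character vector of SNP ids.
#' @export
region_subset <- function(snps, chromosome, center_start_bp = 1,
                          center_end_bp = .Machine$integer.max,
                          flank_bp = 1e6, min_snps = 10) {
  snps <- validate_snp_table(snps)
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  on_chr <- snps$chromosome == as.character(chromosome)
  if (is.finite(flank_bp)) {
    lo <- center_start_bp - flank_bp
    hi <- center_end_bp + flank_bp
    keep <- on_chr & snps$position_bp >= lo & snps$position_bp <= hi
  } else {
    keep <- on_chr
  }
  out <- snps$snp_id[keep]
  if (length(out) < min_snps)
    stop(too_few_snps_error(length(out), min_snps))
  out
}

too_few_snps_error <- function(found, min_snps) {
  structure(class = c("heritpart_too_few_snps", "error", "condition"),
            list(message = paste0(
              "refusing to build a GRM from ", found, " SNP(s): fewer ",
              "than the minimum of ", min_snps),
              call = NULL))
}

#' Summarize the off-diagonal relatedness distribution
#'
#' Bins the upper-triangle off-diagonal entries of a relationship matrix
#' into `(-Inf, e1], (e1, e2], ..., (e_{k-1}, e_k]` plus an open top bin
#' `> e_k`, and reports the proportion in each.
#'
#' @param x a [grm()] or [build_A()] result.
#' @param bin_edges strictly increasing numeric vector of edges.
#' @return named numeric vector of proportions summing to 1.
#' @export
relatedness_summary <- function(x, bin_edges = c(0.05, 0.1, 0.2, 0.4)) {
  v <- if (inherits(x, "grm") || inherits(x, "amatrix")) x$values
       else as.matrix(x)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  off <- v[upper.tri(v)]
  edges <- c(-Inf, bin_edges, Inf)
  counts <- table(cut(off, edges, right = TRUE))
  labs <- c(paste0("<=", bin_edges[1]),
            if (length(bin_edges) > 1)
              paste0("(", bin_edges[-length(bin_edges)], ",",
                     bin_edges[-1], "]"),
            paste0(">", bin_edges[length(bin_edges)]))
  stats::setNames(as.numeric(counts) / length(off), labs)
}
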