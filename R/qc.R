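#' Quality-control filtering of a genotype panel
#'
#' Applies the marker- and individual-level filters used for SNP-array data
#' from wild pedigreed populations, in this order:
#'
#' 1. drop SNPs with minor allele frequency `<= maf_min` (monomorphic SNPs
#'    always fail) or call rate `<= snp_call_min`;
#' 2. drop individuals with call rate `<= ind_call_min` over the retained
#'    SNPs;
#' 3. for every pair of remaining individuals whose pairwise identity-by-
#'    state proportion (share of identical non-missing genotype calls) is
#'    `>= ibs_max`, drop the later-listed member.
#'
#' All comparisons are strict, i.e. a sample is kept only if MAF
#' `> maf_min`, call rates `>` their thresholds and IBS `<` `ibs_max`.
#' Missing dosages survive filtering untouched; nothing is imputed here.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minor-allele-frequency threshold (keep if MAF is above
#'   it); default 0.001.
#' @param snp_call_min minimum SNP call rate (exclusive); default 0.99.
#' @param ind_call_min minimum individual call rate (exclusive);
#'   default 0.95.
#' @param ibs_max pairwise identity-by-state ceiling (exclusive);
#'   default 0.9.
#' @return the filtered `genotype_matrix` with an attribute `qc_report`, a
#'   list of counts removed per rule (`n_snps_maf`, `n_snps_call`,
#'   `n_ind_call`, `n_ind_ibs`) plus the removed ids.
#' @export
qc_filter <- function(g, maf_min = 0.001, snp_call_min = 0.99,
                      ind_call_min = 0.95, ibs_max = 0.9) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(maf_min, snp_call_min, ind_call_min, ibs_max)
  if (any(thr < 0 | thr > 1))
    stop("all QC thresholds must lie in [0, 1]")
  dos <- g$dosages
  n <- nrow(dos)

  n_obs <- colSums(!is.na(dos))
  p <- colSums(dos, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf <= maf_min
  fail_call <- (n_obs / n) <= snp_call_min
  keep_snp <- !(fail_maf | fail_call)
  if (!any(keep_snp))
    stop("empty panel: all SNPs removed by QC")

  dos2 <- dos[, keep_snp, drop = FALSE]
  ind_call <- rowSums(!is.na(dos2)) / ncol(dos2)
  keep_ind <- ind_call > ind_call_min
  removed_call <- g$sample_ids[!keep_ind]

  dos3 <- dos2[keep_ind, , drop = FALSE]
  ids3 <- g$sample_ids[keep_ind]
  drop_ibs <- rep(FALSE, nrow(dos3))
  if (nrow(dos3) >= 2) {
    ibs <- pairwise_ibs(dos3)
    for (j in 2:nrow(dos3)) {
      earlier <- which(!drop_ibs[seq_len(j - 1)])
      if (length(earlier) && any(ibs[earlier, j] >= ibs_max))
        drop_ibs[j] <- TRUE   # later-listed member of the pair goes
    }
  }

  out <- genotype_matrix(dos3[!drop_ibs, , drop = FALSE],
                         ids3[!drop_ibs],
                         g$snps[keep_snp, , drop = FALSE])
  attr(out, "qc_report") <- list(
    n_snps_maf = sum(fail_maf),
    n_snps_call = sum(fail_call & !fail_maf),
    n_ind_call = sum(!keep_ind),
    n_ind_ibs = sum(drop_ibs),
    removed_snps = g$snps$snp_id[!keep_snp],
    removed_individuals_call = removed_call,
    removed_individuals_ibs = ids3[drop_ibs])
  out
}

# proportion of identical non-missing calls for every individual pair
pairwise_ibs <- function(dos) {
  n <- nrow(dos)
  obs <- !is.na(dos)
  x <- dos
  x[!obs] <- 0
  # identical calls among jointly observed SNPs:
  #   match <- sum over z of 1[x_i == x_j], computed from indicator stacks
  eq <- matrix(0, n, n)
  for (v in c(0, 1, 2)) {
    iv <- (x == v & obs) * 1
    eq <- eq + tcrossprod(iv)
  }
  both <- tcrossprod(obs * 1)
  ibs <- eq / pmax(both, 1)
  ibs[both == 0] <- 0
  diag(ibs) <- 1
  ibs
}
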