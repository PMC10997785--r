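#' Trait configuration for the model suite
#'
#' @param trait response column name.
#' @param age_class optional label (e.g. "lamb", "adult").
#' @param fixed,poly_degree,random passed to [model_spec()].
#' @param type `"polygenic"` or `"monogenic"`.
#' @param causal_chromosome,causal_start,causal_end causal-gene location
#'   (monogenic traits only); used for the chromosome- and
#'   region-restricted GRM scopes.
#' @return an object of class `trait_config`.
#' @export
trait_config <- function(trait, age_class = NA_character_,
                         fixed = character(), poly_degree = NULL,
                         random = character(),
                         type = c("polygenic", "monogenic"),
                         causal_chromosome = NULL, causal_start = NULL,
                         causal_end = NULL) {
  type <- match.arg(type)
  if (type == "monogenic" && is.null(causal_chromosome))
    stop("monogenic trait configs must carry a causal locus")
  if (type == "polygenic" && !is.null(causal_chromosome))
    stop("polygenic trait configs must not carry a causal locus")
  structure(list(trait = trait, age_class = age_class, fixed = fixed,
                 poly_degree = poly_degree, random = random, type = type,
                 causal_chromosome = causal_chromosome,
                 causal_start = causal_start, causal_end = causal_end),
            class = "trait_config")
}

#' Likelihood-ratio test between nested variance-component fits
#'
#' `Lambda = max(0, 2 * (logL_full - logL_reduced))`.  The default null
#' is a central chi-square with 1 df; `"mixture_50_50"` uses the
#' boundary-correct equal mixture of a point mass at zero and chi-square
#' with 1 df (a variance tested against zero sits on the boundary of its
#' parameter space).
#'
#' @param fit_full,fit_reduced [reml_fit()] results on the same records;
#'   the reduced model must be nested in the full one.
#' @param null_mode `"chi2_df1"` or `"mixture_50_50"`.
#' @return an object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value`, `null_mode`, `full_label`, `reduced_label`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced,
                                  null_mode = c("chi2_df1",
                                                "mixture_50_50")) {
  null_mode <- match.arg(null_mode)
  stopifnot(inherits(fit_full, "vc_fit"), inherits(fit_reduced, "vc_fit"))
  if (fit_full$n_records != fit_reduced$n_records)
    stop("fits use different record counts (", fit_full$n_records,
         " vs ", fit_reduced$n_records, "); LRT requires identical data")
  lambda <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (null_mode == "chi2_df1")
    stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  else if (lambda <= 0) 1
  else 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  structure(list(statistic = lambda, df = 1, p_value = p,
                 null_mode = null_mode,
                 full_label = paste(fit_full$labels, collapse = "+"),
                 reduced_label = paste(fit_reduced$labels, collapse = "+")),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: Lambda = %.4f, p = %.4g (%s)\n",
              x$full_label, x$reduced_label, x$statistic, x$p_value,
              x$null_mode))
  invisible(x)
}

#' Heritability partition from a two-GRM fit
#'
#' From a fit carrying a population-level genetic component and a second
#' genetic component (relatedness-thresholded or MAF-restricted GRM),
#' returns the population heritability, the kinship/rare-allele
#' heritability, and their sum, each as a fraction of total phenotypic
#' variance with delta-method standard errors.  The sum is exact by
#' construction: `h2_pk = h2_pop + h2_kin`.
#'
#' @param fit a [reml_fit()] result.
#' @param pop_label label of the full-GRM component (default `"pop"`).
#' @param kin_label label of the second genetic component; default picks
#'   `"kin"` then `"maf"` if present.
#' @param scope scope qualifier carried through (`"whole_genome"`,
#'   `"chromosome"`, `"region"`).
#' @param require_converged passed to [h2_from_fit()].
#' @return an object of class `h2_partition`: list with `h2_pop`,
#'   `se_pop`, `h2_kin`, `se_kin`, `h2_pk`, `se_pk`, `scope`,
#'   `kin_label`.
#' @export
partition_heritability <- function(fit, pop_label = "pop",
                                   kin_label = NULL,
                                   scope = "whole_genome",
                                   require_converged = TRUE) {
  stopifnot(inherits(fit, "vc_fit"))
  if (is.null(kin_label))
    kin_label <- intersect(c("kin", "maf"), fit$labels)[1]
  if (is.na(kin_label) || !kin_label %in% fit$labels)
    stop("fit has no kinship/MAF component")
  if (!pop_label %in% fit$labels)
    stop("fit has no component labelled '", pop_label, "'")
  hp <- h2_from_fit(fit, pop_label, require_converged)
  hk <- h2_from_fit(fit, kin_label, require_converged)
  hpk <- h2_from_fit(fit, c(pop_label, kin_label), require_converged)
  structure(list(h2_pop = unname(hp["estimate"]), se_pop = unname(hp["se"]),
                 h2_kin = unname(hk["estimate"]), se_kin = unname(hk["se"]),
                 h2_pk = unname(hpk["estimate"]), se_pk = unname(hpk["se"]),
                 scope = scope, kin_label = kin_label),
            class = "h2_partition")
}

#' @export
print.h2_partition <- function(x, ...) {
  cat(sprintf(
    "h2_pop = %.3f (%.3f)  h2_%s = %.3f (%.3f)  h2_pk = %.3f  [%s]\n",
    x$h2_pop, x$se_pop, x$kin_label, x$h2_kin, x$se_kin, x$h2_pk,
    x$scope))
  invisible(x)
}

#' Compare a heritability partition with single-matrix estimates
#'
#' Flags the standard-error relationships used to judge a partition:
#' whether `h2_pk` falls within one standard error of the pedigree
#' estimate `h2_ped`, and whether the one-standard-error intervals of
#' `h2_pop` and the GRM-only estimate `h2_GRM` overlap.
#'
#' @param partition a [partition_heritability()] result.
#' @param fit_ped single-component fit on the pedigree A matrix
#'   (component label `"ped"`).
#' @param fit_grm single-component fit on the full GRM (label `"pop"`).
#' @param require_converged passed to [h2_from_fit()].
#' @return list with the estimates and logical flags `pk_within_ped_se`
#'   and `pop_grm_se_overlap`.
#' @export
compare_partitions <- function(partition, fit_ped, fit_grm,
                               require_converged = TRUE) {
  stopifnot(inherits(partition, "h2_partition"))
  if (fit_ped$n_records != fit_grm$n_records)
    stop("pedigree and GRM fits use different record counts")
  hped <- h2_from_fit(fit_ped, "ped", require_converged)
  hgrm <- h2_from_fit(fit_grm, "pop", require_converged)
  pk_flag <- abs(partition$h2_pk - hped["estimate"]) <= hped["se"]
  lo1 <- partition$h2_pop - partition$se_pop
  hi1 <- partition$h2_pop + partition$se_pop
  lo2 <- hgrm["estimate"] - hgrm["se"]
  hi2 <- hgrm["estimate"] + hgrm["se"]
  overlap <- lo1 <= hi2 && lo2 <= hi1
  list(h2_pk = partition$h2_pk,
       h2_ped = unname(hped["estimate"]), se_ped = unname(hped["se"]),
       h2_pop = partition$h2_pop, se_pop = partition$se_pop,
       h2_grm = unname(hgrm["estimate"]), se_grm = unname(hgrm["se"]),
       pk_within_ped_se = unname(pk_flag),
       pop_grm_se_overlap = unname(overlap))
}

#' Run the full model suite for one trait
#'
#' Fits, for one trait and one record set: the GRM-only model; the
#' two-GRM model at each relatedness threshold; the GRM + rare-allele-GRM
#' model at each MAF threshold; and the pedigree model.  For monogenic
#' traits the GRM models are additionally re-run with both matrices
#' restricted to the causal chromosome and to the causal gene +/- a 1 Mb
#' flank.  Variants whose SNP panel falls under `min_snps` are recorded
#' as skipped rows, and non-convergence is recorded, never fatal.  All
#' fits of a trait use the identical record set.
#'
#' @param cfg a [trait_config()].
#' @param genotypes QC-passed [genotype_matrix()].
#' @param pedigree pedigree data frame (`id`, `sire`, `dam`).
#' @param phenotypes record data frame with an `id` column.
#' @param thresholds relatedness thresholds for the kinship GRM.
#' @param maf_thresholds MAF ceilings for the rare-allele GRM.
#' @param flank_bp region flank around the causal gene.
#' @param min_snps smallest SNP panel a GRM may be built from.
#' @param null_mode LRT null passed to [likelihood_ratio_test()].
#' @return a data frame, one row per model variant, with columns `model`,
#'   `scope`, `variant`, `status`, `converged`, `loglik`, `n_snps`,
#'   `h2_pop`, `se_pop`, `h2_kin`, `se_kin`, `h2_pk`, `h2_single`,
#'   `se_single`, `lrt_p`; attribute `fits` holds the underlying
#'   `vc_fit` objects keyed by row label.
#' @export
run_model_suite <- function(cfg, genotypes, pedigree, phenotypes,
                            thresholds = c(0.05, 0.1),
                            maf_thresholds = c(0.1, 0.05, 0.01, 0.005,
                                               0.001),
                            flank_bp = 1e6, min_snps = 10,
                            null_mode = "chi2_df1") {
  stopifnot(inherits(cfg, "trait_config"),
            inherits(genotypes, "genotype_matrix"))
  ids <- genotypes$sample_ids
  spec0 <- model_spec(cfg$trait, fixed = cfg$fixed,
                      poly_degree = cfg$poly_degree, random = cfg$random,
                      genetic = list(pop = diag(length(ids))))
  d <- build_design(spec0, phenotypes, ids)
  freqs <- allele_frequencies(genotypes)
  A <- build_A(pedigree, extra_ids = ids)

  scopes <- list(whole_genome = genotypes$snps$snp_id)
  if (cfg$type == "monogenic") {
    scopes$chromosome <- tryCatch(
      region_subset(genotypes$snps, cfg$causal_chromosome,
                    flank_bp = Inf, min_snps = min_snps),
      heritpart_too_few_snps = function(e) e)
    scopes$region <- tryCatch(
      region_subset(genotypes$snps, cfg$causal_chromosome,
                    cfg$causal_start, cfg$causal_end,
                    flank_bp = flank_bp, min_snps = min_snps),
      heritpart_too_few_snps = function(e) e)
  }

  rows <- list()
  fits <- list()
  add_row <- function(model, scope, variant, status, fit = NULL,
                      n_snps = NA, part = NULL, single = NULL,
                      lrt_p = NA) {
    key <- paste(model, scope, variant, sep = "|")
    fits[[key]] <<- fit
    rows[[key]] <<- data.frame(
      model = model, scope = scope, variant = variant, status = status,
      converged = if (is.null(fit)) NA else fit$converged,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      n_snps = n_snps,
      h2_pop = if (is.null(part)) NA_real_ else part$h2_pop,
      se_pop = if (is.null(part)) NA_real_ else part$se_pop,
      h2_kin = if (is.null(part)) NA_real_ else part$h2_kin,
      se_kin = if (is.null(part)) NA_real_ else part$se_kin,
      h2_pk = if (is.null(part)) NA_real_ else part$h2_pk,
      h2_single = if (is.null(single)) NA_real_ else
        unname(single["estimate"]),
      se_single = if (is.null(single)) NA_real_ else unname(single["se"]),
      lrt_p = lrt_p, stringsAsFactors = FALSE)
  }

  for (scope in names(scopes)) {
    panel <- scopes[[scope]]
    if (inherits(panel, "condition")) {
      add_row("grm_only", scope, "-", "skipped_too_few_snps")
      for (t in thresholds)
        add_row("grm_plus_kin", scope, paste0("t=", t),
                "skipped_too_few_snps")
      for (mt in maf_thresholds)
        add_row("grm_plus_maf", scope, paste0("maf<", mt),
                "skipped_too_few_snps")
      next
    }
    g_full <- build_grm(genotypes, snp_subset = panel, freqs = freqs,
                        provenance = list(kind = if (scope ==
                          "whole_genome") "full" else scope))
    fit1 <- reml_fit_quiet(d, list(pop = g_full))
    if (is.null(fit1)) {
      add_row("grm_only", scope, "-", "failed")
      next
    }
    h1 <- h2_from_fit(fit1, "pop", require_converged = FALSE)
    add_row("grm_only", scope, "-",
            if (fit1$converged) "ok" else "not_converged", fit1,
            length(panel), single = h1)

    for (t in thresholds) {
      g_kin <- threshold_grm(g_full, t)
      fit2 <- reml_fit_quiet(d, list(pop = g_full, kin = g_kin))
      if (is.null(fit2)) {
        add_row("grm_plus_kin", scope, paste0("t=", t), "failed")
        next
      }
      part <- partition_heritability(fit2, scope = scope,
                                     require_converged = FALSE)
      lrt <- likelihood_ratio_test(fit2, fit1, null_mode)
      add_row("grm_plus_kin", scope, paste0("t=", t),
              if (fit2$converged) "ok" else "not_converged", fit2,
              length(panel), part = part, lrt_p = lrt$p_value)
    }

    for (mt in maf_thresholds) {
      g_maf <- tryCatch({
        sub <- maf_subset(freqs, genotypes$snps[
          match(panel, genotypes$snps$snp_id), , drop = FALSE], mt)
        if (length(sub) < min_snps) stop(too_few_snps_error(length(sub),
                                                            min_snps))
        build_grm(genotypes, snp_subset = sub, freqs = freqs,
                  provenance = list(kind = "maf", threshold = mt))
      }, error = function(e) e)
      if (inherits(g_maf, "error")) {
        add_row("grm_plus_maf", scope, paste0("maf<", mt),
                "skipped_too_few_snps")
        next
      }
      fit3 <- reml_fit_quiet(d, list(pop = g_full, maf = g_maf))
      if (is.null(fit3)) {
        add_row("grm_plus_maf", scope, paste0("maf<", mt), "failed")
        next
      }
      part <- partition_heritability(fit3, scope = scope,
                                     require_converged = FALSE)
      lrt <- likelihood_ratio_test(fit3, fit1, null_mode)
      add_row("grm_plus_maf", scope, paste0("maf<", mt),
              if (fit3$converged) "ok" else "not_converged", fit3,
              g_maf$n_snps, part = part, lrt_p = lrt$p_value)
    }
  }

  fit4 <- reml_fit_quiet(d, list(ped = A))
  if (is.null(fit4)) {
    add_row("pedigree", "whole_genome", "-", "failed")
  } else {
    h4 <- h2_from_fit(fit4, "ped", require_converged = FALSE)
    add_row("pedigree", "whole_genome", "-",
            if (fit4$converged) "ok" else "not_converged", fit4,
            NA, single = h4)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "record_key") <- c(n = length(d$y),
                               sum_y = sum(d$y), sum_y2 = sum(d$y^2))
  out
}

# reml_fit that degrades to NULL instead of erroring (suite robustness)
reml_fit_quiet <- function(d, genetic) {
  tryCatch(reml_fit(d, genetic), error = function(e) NULL)
}
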