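#' Genotype matrix container
#'
#' Bundles a dosage matrix (individuals x SNPs, counted-allele copies in
#' \{0, 1, 2\}, `NA` for missing) with its sample identifiers and SNP map.
#' The counted allele is the allele whose copies are counted in the dosage
#' (PLINK/GCTA "A1" convention); all downstream allele-frequency and
#' relationship calculations refer to it.
#'
#' @param dosages numeric or integer matrix, one row per individual, one
#'   column per SNP; entries must be 0, 1, 2 or `NA`.
#' @param sample_ids character vector of unique individual identifiers,
#'   one per row of `dosages`.
#' @param snps a data frame as returned by [snp_table()], one row per
#'   column of `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (with row/column names set), `sample_ids` and `snps`.
#' @seealso [read_plink()], [qc_filter()], [build_grm()]
#' @export
genotype_matrix <- function(dosages, sample_ids, snps) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (nrow(dosages) != length(sample_ids))
    stop("dosages has ", nrow(dosages), " rows but ", length(sample_ids),
         " sample ids")
  snps <- validate_snp_table(snps)
  if (ncol(dosages) != nrow(snps))
    stop("dosages has ", ncol(dosages), " columns but the SNP table has ",
         nrow(snps), " rows")
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(utils::head(unique(dosages[bad]), 3), collapse = ", "))
  dimnames(dosages) <- list(sample_ids, snps$snp_id)
  structure(list(dosages = dosages, sample_ids = sample_ids, snps = snps),
            class = "genotype_matrix")
}

#' SNP map table
#'
#' @param snp_id unique SNP identifiers.
#' @param chromosome chromosome labels (coerced to character).
#' @param position_bp 1-based physical positions (non-negative integers).
#' @param counted_allele,other_allele allele labels; the counted allele is
#'   the one whose dosage is stored (0/1/2 copies).
#' @return data frame with class `snp_table` prepended.
#' @export
snp_table <- function(snp_id, chromosome, position_bp,
                      counted_allele = "A", other_allele = "B") {
  out <- data.frame(snp_id = as.character(snp_id),
                    chromosome = as.character(chromosome),
                    position_bp = as.integer(position_bp),
                    counted_allele = as.character(counted_allele),
                    other_allele = as.character(other_allele),
                    stringsAsFactors = FALSE)
  validate_snp_table(out)
}

validate_snp_table <- function(snps) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chromosome", "position_bp",
            "counted_allele", "other_allele")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    stop("SNP table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("snp_ids must be unique")
  if (any(snps$position_bp < 0, na.rm = TRUE))
    stop("SNP positions must be non-negative")
  if (any(snps$counted_allele == snps$other_allele))
    stop("counted_allele must differ from other_allele")
  class(snps) <- unique(c("snp_table", class(snps)))
  snps
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$sample_ids), " individuals x ",
      nrow(x$snps), " SNPs (",
      sum(is.na(x$dosages)), " missing calls)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param g a [genotype_matrix()].
#' @param individuals character ids or logical/integer index over rows.
#' @param snps character SNP ids or logical/integer index over columns.
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(g, individuals = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ri <- seq_along(g$sample_ids)
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) {
      m <- match(individuals, g$sample_ids)
      if (anyNA(m)) stop("unknown individual ids: ",
                         paste(individuals[is.na(m)], collapse = ", "))
      m
    } else which(rep_len(TRUE, length(g$sample_ids)))[individuals]
  }
  ci <- seq_len(nrow(g$snps))
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) {
      m <- match(snps, g$snps$snp_id)
      if (anyNA(m)) stop("unknown SNP ids: ",
                         paste(snps[is.na(m)], collapse = ", "))
      m
    } else ci[snps]
  }
  genotype_matrix(g$dosages[ri, ci, drop = FALSE],
                  g$sample_ids[ri], g$snps[ci, , drop = FALSE])
}
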