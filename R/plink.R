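#' Read a PLINK bed/bim/fam triplet
#'
#' Decodes a PLINK 1 binary fileset (v1.0 magic bytes, SNP-major layout)
#' into a [genotype_matrix()].  Dosages count copies of the .bim A1 allele,
#' which becomes the counted (reference) allele of the returned object; the
#' PLINK missing code maps to `NA`.
#'
#' @param prefix path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#' @return a `genotype_matrix`.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths)
    if (!file.exists(p)) stop("file not found: ", p)

  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2) stop("malformed .fam file: ", paths[3])
  sample_ids <- fam[[2]]

  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = "character")
  if (ncol(bim) < 6) stop("malformed .bim file: ", paths[2])
  snps <- snp_table(snp_id = bim[[2]], chromosome = bim[[1]],
                    position_bp = as.integer(bim[[4]]),
                    counted_allele = bim[[5]], other_allele = bim[[6]])

  n <- length(sample_ids)
  m <- nrow(snps)
  bpl <- ceiling(n / 4)                      # bytes per SNP block
  raw <- readBin(paths[1], "raw", n = 3 + m * bpl)
  if (length(raw) < 3 ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bad magic number in ", paths[1], ": not a PLINK .bed file")
  if (raw[3] != as.raw(0x01))
    stop(paths[1], " is not in SNP-major v1.0 layout")
  if (length(raw) != 3 + m * bpl)
    stop(paths[1], " has ", length(raw) - 3, " data bytes; expected ",
         m * bpl, " for ", n, " individuals x ", m, " SNPs")

  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit genotype codes, sample index fastest within each byte
  codes <- matrix(0L, nrow = 4 * bpl, ncol = m)
  shift <- c(1L, 4L, 16L, 64L)
  for (k in 1:4)
    codes[seq(k, by = 4, length.out = bpl), ] <-
      (matrix(body, nrow = bpl) %/% shift[k]) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  dos <- c(2, NA, 1, 0)[codes + 1L]
  dim(dos) <- c(n, m)
  genotype_matrix(dos, sample_ids, snps)
}

#' Write a genotype matrix as a PLINK bed/bim/fam triplet
#'
#' Inverse of [read_plink()]: the counted allele is written as A1 so that
#' write-then-read reproduces the dosage matrix exactly.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$sample_ids)
  m <- nrow(g$snps)

  fam <- data.frame(g$sample_ids, g$sample_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(g$snps$chromosome, g$snps$snp_id, 0L,
                    g$snps$position_bp, g$snps$counted_allele,
                    g$snps$other_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  bpl <- ceiling(n / 4)
  dos <- g$dosages
  code <- matrix(1L, nrow = 4 * bpl, ncol = m)    # 01 = missing
  map <- c(3L, 2L, 0L)                            # dosage 0/1/2 -> code
  idx <- seq_len(n)
  codes_obs <- matrix(1L, nrow = n, ncol = m)
  ok <- !is.na(dos)
  codes_obs[ok] <- map[dos[ok] + 1L]
  code[idx, ] <- codes_obs
  code[setdiff(seq_len(4 * bpl), idx), ] <- 0L    # pad bits are zero
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, nrow = bpl, ncol = m)
  for (k in 1:4)
    bytes <- bytes + code[seq(k, by = 4, length.out = bpl), , drop = FALSE] *
      shift[k]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read / write pedigree tables
#'
#' Pedigrees are tab-separated text with a header and columns
#' `id`, `sire`, `dam`; `"0"`, `""` or `NA` denote an unknown parent.
#'
#' @param path file path.
#' @return `read_pedigree`: a data frame with character columns `id`,
#'   `sire`, `dam` (`NA` = unknown parent).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns id, sire, dam")
  ped <- ped[need]
  for (col in c("sire", "dam"))
    ped[[col]][ped[[col]] %in% c("", "0", "NA")] <- NA_character_
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  ped <- validate_pedigree(ped)
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

validate_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns id, sire, dam")
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (anyDuplicated(ped$id))
    stop("pedigree ids must be unique")
  if (any(ped$id == ped$sire | ped$id == ped$dam, na.rm = TRUE))
    stop("an individual cannot be its own parent")
  ped
}

#' Read / write phenotype record tables
#'
#' Phenotype tables are tab-separated text with a header; one row per
#' measurement record, an `id` column linking records to individuals, and
#' arbitrary further trait/covariate/grouping columns.  Repeated rows per
#' individual carry repeated measures.
#'
#' @param path file path.
#' @return a data frame of records.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!"id" %in% names(ph))
    stop("phenotype file must have an 'id' column")
  # numeric columns only where every value parses as a number ("F"/"T"
  # sex codes must stay character)
  for (col in setdiff(names(ph), "id")) {
    x <- ph[[col]]
    num <- suppressWarnings(as.numeric(x))
    if (!any(is.na(num) & !is.na(x) & x != "NA")) ph[[col]] <- num
  }
  ph
}

#' @rdname read_phenotypes
#' @param phenos phenotype record data frame.
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.table(phenos, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}
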