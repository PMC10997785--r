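#' Write / read a GRM in the GCTA binary triplet format
#'
#' The triplet comprises `<prefix>.grm.bin` (lower-triangle values,
#' diagonal included, row by row, little-endian float32),
#' `<prefix>.grm.N.bin` (per-pair SNP counts, same order, float32) and
#' `<prefix>.grm.id` (two tab-separated text columns, family and
#' individual id).  Values survive a round trip to float32 precision.
#'
#' @param x a [grm()] (or an `amatrix`; the numerator relationship matrix
#'   can be exported in the same container for uniform downstream use).
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(x, prefix) {
  v <- if (inherits(x, "amatrix")) x$values else x$values
  ids <- x$ids
  n <- length(ids)
  lt <- v[lower_triangle_index(n)]
  Nmat <- x$n_snps_pair
  Nvals <- if (!is.null(Nmat)) Nmat[lower_triangle_index(n)]
           else rep(if (is.null(x$n_snps)) 0 else x$n_snps, length(lt))
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(Nvals), con, size = 4, endian = "little")
  close(con)
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(prefix)
}

# linear indices of (i >= j) pairs in GCTA order: i = 1..n, j = 1..i
lower_triangle_index <- function(n) {
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  (j - 1L) * n + i
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  idp <- paste0(prefix, ".grm.id")
  binp <- paste0(prefix, ".grm.bin")
  if (!file.exists(idp)) stop("file not found: ", idp)
  if (!file.exists(binp)) stop("file not found: ", binp)
  ids <- utils::read.table(idp, header = FALSE,
                           colClasses = "character")[[2]]
  n <- length(ids)
  npair <- n * (n + 1) / 2
  sz <- file.size(binp)
  if (sz != 4 * npair)
    stop("size mismatch: ", binp, " holds ", sz / 4,
         " float32 values but ", n, " ids require ", npair)
  lt <- readBin(binp, "numeric", n = npair, size = 4, endian = "little")
  v <- matrix(0, n, n)
  v[lower_triangle_index(n)] <- lt
  v <- v + t(v) - diag(diag(v))
  nbinp <- paste0(prefix, ".grm.N.bin")
  n_snps <- 1L
  n_snps_pair <- NULL
  if (file.exists(nbinp)) {
    Nvals <- readBin(nbinp, "numeric", n = npair, size = 4,
                     endian = "little")
    if (length(Nvals) == npair) {
      if (length(unique(Nvals)) == 1L) {
        n_snps <- max(1L, as.integer(Nvals[1]))
      } else {
        n_snps_pair <- matrix(0, n, n)
        n_snps_pair[lower_triangle_index(n)] <- Nvals
        n_snps_pair <- n_snps_pair + t(n_snps_pair) -
          diag(diag(n_snps_pair))
        n_snps <- max(1L, as.integer(round(max(Nvals))))
      }
    }
  }
  grm(v, ids, n_snps, provenance = list(kind = "full", source = "gcta"),
      n_snps_pair = n_snps_pair)
}

#' Export a relationship matrix as inspectable text
#'
#' Square tab-separated matrix with an id header row and id first column.
#'
#' @param x a [grm()] or `amatrix`.
#' @param path output path.
#' @export
write_grm_text <- function(x, path) {
  df <- data.frame(id = x$ids, x$values, check.names = FALSE)
  colnames(df) <- c("id", x$ids)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}
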