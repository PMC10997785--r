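#' Build the pedigree numerator relationship matrix A
#'
#' Henderson's recursion over a topologically sorted pedigree:
#' `a_ii = 1 + 0.5 * a(sire, dam)` and, for an earlier individual j,
#' `a_ij = 0.5 * (a(j, sire) + a(j, dam))`, with an unknown parent
#' contributing 0.  Individuals with both parents unknown are founders
#' (diagonal exactly 1); the diagonal is `1 + F_i` with `F_i` half the
#' parents' relatedness.
#'
#' @param ped pedigree data frame with character columns `id`, `sire`,
#'   `dam` (`NA` = unknown).  Parents referenced but absent from `id` are
#'   added as founders.  Row order is arbitrary; cycles are an error.
#' @param extra_ids optional ids to append as unrelated founders (e.g.
#'   genotyped individuals with no known pedigree link).
#' @return an object of class `amatrix`: list with `values` (symmetric
#'   matrix, dimnames = ids) and `ids`, ordered parents-before-offspring.
#' @export
build_A <- function(ped, extra_ids = NULL) {
  ped <- validate_pedigree(ped)
  known_parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(known_parents))
    ped <- rbind(data.frame(id = known_parents, sire = NA_character_,
                            dam = NA_character_), ped)
  if (!is.null(extra_ids)) {
    extra_ids <- setdiff(as.character(extra_ids), ped$id)
    if (length(extra_ids))
      ped <- rbind(ped, data.frame(id = extra_ids, sire = NA_character_,
                                   dam = NA_character_))
  }
  ord <- pedigree_toposort(ped)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)   # indices of parents, NA if unknown
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      js <- seq_len(i - 1)
      row <- 0.5 * ((if (is.na(s)) 0 else A[js, s]) +
                    (if (is.na(d)) 0 else A[js, d]))
      A[js, i] <- row
      A[i, js] <- row
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  dimnames(A) <- list(ped$id, ped$id)
  structure(list(values = A, ids = ped$id,
                 n_snps = NULL, n_snps_pair = NULL,
                 provenance = list(kind = "pedigree")),
            class = "amatrix")
}

#' @export
print.amatrix <- function(x, ...) {
  cat("amatrix: numerator relationship matrix for", length(x$ids),
      "individuals\n")
  invisible(x)
}

# Kahn toposort; errors on cycles listing the individuals involved.
pedigree_toposort <- function(ped) {
  n <- nrow(ped)
  id <- ped$id
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (pidx in c(si[i], di[i]))
      if (!is.na(pidx))
        children[[pidx]] <- c(children[[pidx]], i)
  }
  queue <- which(indeg == 0)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' Count relationship classes in a pedigree
#'
#' Exact counts of unordered pairs by relationship class:
#' parent-offspring, full siblings (both parents shared and known), half
#' siblings (exactly one known parent shared) and grandparent-grandchild
#' (a pair counted once even if linked through both a grandsire and a
#' granddam path).
#'
#' @param ped pedigree data frame (`id`, `sire`, `dam`).
#' @return named integer vector with elements `parent_offspring`,
#'   `full_sib`, `half_sib`, `grandparent_grandchild`.
#' @export
pedigree_pair_counts <- function(ped) {
  ped <- validate_pedigree(ped)
  id <- ped$id
  n <- nrow(ped)
  si <- ped$sire
  di <- ped$dam
  po <- sum(!is.na(si) & si %in% id) + sum(!is.na(di) & di %in% id)

  # sibling classes from shared known parents
  key_both <- ifelse(!is.na(si) & !is.na(di), paste(si, di), NA)
  fs <- sum(vapply(table(stats::na.omit(key_both)),
                   function(k) k * (k - 1) / 2, 0))
  same_sire <- sum(vapply(table(stats::na.omit(si)),
                          function(k) k * (k - 1) / 2, 0))
  same_dam <- sum(vapply(table(stats::na.omit(di)),
                         function(k) k * (k - 1) / 2, 0))
  # pairs sharing sire AND dam are counted in both same-parent tallies
  hs <- same_sire + same_dam - 2 * fs

  # grandparent-grandchild: distinct (grandparent, child) pairs
  parent_of <- rbind(
    data.frame(child = id, parent = si, stringsAsFactors = FALSE),
    data.frame(child = id, parent = di, stringsAsFactors = FALSE))
  parent_of <- parent_of[!is.na(parent_of$parent) &
                           parent_of$parent %in% id, ]
  gp <- merge(parent_of, parent_of,
              by.x = "parent", by.y = "child")[, c("child", "parent.y")]
  gp <- unique(gp)
  c(parent_offspring = as.integer(po),
    full_sib = as.integer(fs),
    half_sib = as.integer(hs),
    grandparent_grandchild = nrow(gp))
}

#' Mean pairwise pedigree relatedness
#'
#' Mean of the off-diagonal upper-triangle entries of a numerator
#' relationship matrix.
#'
#' @param a an `amatrix` from [build_A()] (a [grm()] works too).
#' @return scalar mean relatedness.
#' @export
mean_pairwise_relatedness <- function(a) {
  v <- a$values
  if (nrow(v) < 2) stop("need at least two individuals")
  mean(v[upper.tri(v)])
}
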