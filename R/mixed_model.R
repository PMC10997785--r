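#' Declare an animal model
#'
#' A declarative description of one animal model: the response column, the
#' fixed-effect covariates, the non-genetic random grouping factors and the
#' genetic covariance structures to fit.  [build_design()] realizes it
#' numerically against a phenotype record table.
#'
#' @param trait name of the response column in the phenotype table.
#' @param fixed character vector of fixed-effect column names.  Numeric
#'   columns enter as continuous covariates, non-numeric ones as
#'   categorical factors (first level as reference).  An intercept is
#'   always included.
#' @param poly_degree optional named integer vector; a named covariate
#'   enters with raw polynomial terms up to that degree (e.g.
#'   `c(mother_age = 2)` for linear + quadratic).
#' @param random character vector of grouping-factor column names fitted
#'   as i.i.d. non-genetic random effects (birth year, maternal id, ...).
#'   Use the individual id column (`"id"`) for a permanent-environment
#'   effect under repeated measures.
#' @param genetic named list of relationship matrices ([grm()] /
#'   [build_A()] output), e.g. `list(pop = g_full, kin = g_thresh)`.
#'   Labels become variance-component names.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(trait, fixed = character(), poly_degree = NULL,
                       random = character(), genetic = list()) {
  if (!length(genetic) && !length(random))
    stop("a model needs at least one genetic or non-genetic random component")
  if (length(genetic) && (is.null(names(genetic)) ||
                          anyDuplicated(names(genetic)) ||
                          any(names(genetic) == "")))
    stop("genetic components must have unique non-empty labels")
  if (any(names(genetic) %in% c(random, "residual")) ||
      "residual" %in% random)
    stop("component labels must be unique (\"residual\" is reserved)")
  structure(list(trait = trait, fixed = fixed, poly_degree = poly_degree,
                 random = random, genetic = genetic),
            class = "model_spec")
}

#' Realize the design matrices of an animal model
#'
#' Builds `y`, the fixed-effect matrix `X`, one incidence matrix per
#' non-genetic random factor, and the record-to-individual incidence `W`
#' that carries repeated measures (each row of `W` has exactly one 1).
#' Records with a missing response, covariate or grouping value are
#' dropped and counted.
#'
#' @param spec a [model_spec()].
#' @param phenos phenotype record data frame with an `id` column.
#' @param sample_order character vector fixing the individual order of the
#'   genetic covariance structures (usually the GRM ids).
#' @return an object of class `design_matrices`: list with `y`, `X`,
#'   `Z` (named list of sparse incidence matrices), `W` (sparse), `ids`
#'   (= `sample_order`), `record_ids` and `n_dropped`.
#' @export
build_design <- function(spec, phenos, sample_order) {
  stopifnot(inherits(spec, "model_spec"))
  phenos <- as.data.frame(phenos)
  if (!"id" %in% names(phenos)) stop("phenotype table needs an 'id' column")
  need <- unique(c(spec$trait, spec$fixed, spec$random))
  miss <- setdiff(need, names(phenos))
  if (length(miss))
    stop("phenotype table is missing columns: ",
         paste(miss, collapse = ", "))

  complete <- stats::complete.cases(phenos[, c("id", need), drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped)
    message("build_design: dropped ", n_dropped,
            " record(s) with missing values")
  ph <- phenos[complete, , drop = FALSE]
  if (!nrow(ph)) stop("no complete records left")

  unknown <- setdiff(unique(ph$id), sample_order)
  if (length(unknown))
    stop("records refer to individuals absent from sample_order: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  y <- ph[[spec$trait]]
  if (!is.numeric(y))
    stop("response '", spec$trait, "' must be numeric; code categorical ",
         "traits first (see code_categorical_trait)")

  terms <- character(0)
  for (f in spec$fixed) {
    deg <- if (!is.null(spec$poly_degree)) spec$poly_degree[f] else NA
    terms <- c(terms,
               if (!is.na(deg) && deg > 1)
                 paste0("poly(", f, ", ", deg, ", raw = TRUE)")
               else if (is.numeric(ph[[f]])) f
               else paste0("factor(", f, ")"))
  }
  fml <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  X <- stats::model.matrix(fml, data = ph)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }

  nrec <- nrow(ph)
  W <- Matrix::sparseMatrix(i = seq_len(nrec),
                            j = match(ph$id, sample_order),
                            x = 1, dims = c(nrec, length(sample_order)),
                            dimnames = list(NULL, sample_order))
  Z <- list()
  for (r in spec$random) {
    fac <- factor(ph[[r]])
    Z[[r]] <- Matrix::sparseMatrix(i = seq_len(nrec),
                                   j = as.integer(fac), x = 1,
                                   dims = c(nrec, nlevels(fac)),
                                   dimnames = list(NULL, levels(fac)))
  }
  structure(list(y = as.numeric(y), X = X, Z = Z, W = W,
                 ids = sample_order, record_ids = ph$id,
                 n_dropped = n_dropped),
            class = "design_matrices")
}

# Record-level covariance structures of a model: genetic matrices mapped
# through W as W M W', non-genetic factors as Z Z'.  Residual identity is
# implicit and always last.
record_covariances <- function(d, genetic = list()) {
  stopifnot(inherits(d, "design_matrices"))
  out <- list()
  for (lab in names(genetic)) {
    M <- genetic[[lab]]
    Mv <- if (inherits(M, "grm") || inherits(M, "amatrix")) {
      if (!identical(M$ids, d$ids)) {
        idx <- match(d$ids, M$ids)
        if (anyNA(idx))
          stop("relationship matrix '", lab, "' lacks individuals: ",
               paste(utils::head(d$ids[is.na(idx)], 5), collapse = ", "))
        M$values[idx, idx, drop = FALSE]
      } else M$values
    } else as.matrix(M)
    if (nrow(Mv) != length(d$ids))
      stop("covariance '", lab, "' has wrong dimension")
    W <- as.matrix(d$W)
    out[[lab]] <- W %*% Mv %*% t(W)
  }
  for (r in names(d$Z))
    out[[r]] <- as.matrix(Matrix::tcrossprod(d$Z[[r]]))
  out
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates the REML criterion
#' `-0.5 * (log|V| + log|X'V^-1 X| + y'Py + (n - p) log 2pi)` with
#' `V = sum_c sigma2_c V_c + sigma2_e I` and
#' `P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1`.  The `(n - p) log 2pi`
#' constant is included.
#'
#' @param d a [build_design()] result.
#' @param covariances named list of record-level covariance structures
#'   (see Details), or a named list of relationship matrices which are
#'   then mapped through `W`; non-genetic `Z` factors of `d` are appended
#'   automatically when `covariances` is a `genetic =` style list of
#'   `grm`/`amatrix` objects.
#' @param sigma2 named variance vector; one entry per structure plus a
#'   final `residual` entry.
#' @return scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(d, covariances, sigma2) {
  Vcs <- if (length(covariances) &&
             all(vapply(covariances, function(m)
               inherits(m, "grm") || inherits(m, "amatrix"), TRUE)))
    record_covariances(d, covariances)
  else covariances
  reml_eval(d$y, d$X, Vcs, sigma2)$loglik
}

# one evaluation of the REML criterion and its derivative ingredients
reml_eval <- function(y, X, Vcs, sigma2, want_derivs = FALSE) {
  n <- length(y)
  p <- ncol(X)
  labs <- c(names(Vcs), "residual")
  if (!all(labs %in% names(sigma2)))
    stop("sigma2 must name: ", paste(labs, collapse = ", "))
  V <- diag(rep(sigma2[["residual"]], n))
  for (lab in names(Vcs)) V <- V + sigma2[[lab]] * Vcs[[lab]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop("V is not positive definite at sigma2 = (",
         paste(signif(unlist(sigma2[labs]), 4), collapse = ", "), ")")
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  chx <- chol(XtVX)
  logdetX <- 2 * sum(log(diag(chx)))
  Cfix <- chol2inv(chx)
  P <- Vinv - VinvX %*% Cfix %*% t(VinvX)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  ll <- -0.5 * (logdetV + logdetX + yPy + (n - p) * log(2 * pi))
  out <- list(loglik = ll, P = P, Py = Py)
  if (want_derivs) {
    K <- length(labs)
    score <- numeric(K)
    u <- vector("list", K)
    for (k in seq_along(Vcs)) {
      trPV <- sum(P * Vcs[[k]])          # tr(P V_k), V_k symmetric
      u[[k]] <- drop(Vcs[[k]] %*% Py)
      score[k] <- -0.5 * (trPV - sum(Py * u[[k]]))
    }
    u[[K]] <- Py
    score[K] <- -0.5 * (sum(diag(P)) - sum(Py * Py))
    AI <- matrix(0, K, K)
    Pu <- lapply(u, function(v) drop(P %*% v))
    for (a in seq_len(K))
      for (b in a:K)
        AI[a, b] <- AI[b, a] <- 0.5 * sum(u[[a]] * Pu[[b]])
    dimnames(AI) <- list(labs, labs)
    out$score <- stats::setNames(score, labs)
    out$AI <- AI
  }
  out
}

#' Fit a multi-component animal model by AI-REML
#'
#' Maximizes the restricted log-likelihood over non-negative variance
#' components: a short expectation-maximization warm start, then average-
#' information (AI) updates with step-halving.  Components whose updates
#' go negative are pinned to a small floor (`1e-8` times the phenotypic
#' variance) and flagged.  Convergence requires the log-likelihood change
#' below `tol_loglik` and the maximum relative parameter change below
#' `tol_par`.  The sampling covariance of the estimates is the inverse of
#' the average-information matrix at the optimum; standard errors of
#' floored (boundary) components are reported as `NA`.
#'
#' @param d a [build_design()] result.
#' @param genetic named list of relationship matrices to fit (labels
#'   become variance-component names); the non-genetic factors present in
#'   `d` are fitted automatically.
#' @param init optional named starting variances.
#' @param constrain keep variances non-negative (default); with `FALSE`
#'   components may go negative (V must stay positive definite).
#' @param max_iter,n_em iteration caps (AI total / EM warm start).
#' @param tol_loglik,tol_par convergence tolerances.
#' @param verbose print an iteration trace.
#' @return an object of class `vc_fit`: list with `sigma2` (named, incl.
#'   `residual`), `loglik`, `sampling_cov`, `converged`, `n_iterations`,
#'   `constraint_flags`, `n_records`, `n_fixed`, `labels`.
#' @export
reml_fit <- function(d, genetic = list(), init = NULL, constrain = TRUE,
                     max_iter = 200, n_em = 3, tol_loglik = 1e-8,
                     tol_par = 1e-6, verbose = FALSE) {
  stopifnot(inherits(d, "design_matrices"))
  Vcs <- record_covariances(d, genetic)
  y <- d$y
  X <- d$X
  n <- length(y)
  labs <- c(names(Vcs), "residual")
  K <- length(labs)
  vp <- stats::var(y)
  floor_val <- 1e-8 * vp
  theta <- if (is.null(init)) stats::setNames(rep(vp / K, K), labs)
           else {
             if (!all(labs %in% names(init)))
               stop("init must name all components")
             pmax(unlist(init[labs]), floor_val)
           }

  # structure matrices (thresholded / rare-allele GRMs especially) can be
  # indefinite; shrink the non-residual start until V is positive definite
  for (k in 0:30) {
    ev <- tryCatch(reml_eval(y, X, Vcs, as.list(theta),
                             want_derivs = TRUE),
                   error = function(e) NULL)
    if (!is.null(ev)) break
    nr <- setdiff(labs, "residual")
    theta[nr] <- theta[nr] / 4
    theta["residual"] <- vp - sum(theta[nr])
  }
  if (is.null(ev))
    stop("could not find a positive-definite starting point")
  ll <- ev$loglik
  converged <- FALSE
  iter <- 0
  at_floor <- rep(FALSE, K)

  repeat {
    iter <- iter + 1
    if (iter <= n_em) {
      # EM-flavoured warm start: guaranteed-ascent-direction scaled step
      yPVPy <- vapply(seq_len(K), function(k) {
        u <- if (k < K) drop(Vcs[[k]] %*% ev$Py) else ev$Py
        sum(ev$Py * u)
      }, 0)
      trPV <- vapply(seq_len(K), function(k)
        if (k < K) sum(ev$P * Vcs[[k]]) else sum(diag(ev$P)), 0)
      prop <- theta + theta^2 * (yPVPy - trPV) / n
    } else {
      # active-set AI step: components pinned at the floor whose score
      # pulls them further down are held fixed; the AI system is solved
      # over the free components only
      fixed <- at_floor & (ev$score < 0)
      delta <- numeric(K)
      free <- which(!fixed)
      if (length(free))
        delta[free] <- tryCatch(
          solve(ev$AI[free, free, drop = FALSE], ev$score[free]),
          error = function(e) ev$score[free] / diag(ev$AI)[free])
      prop <- theta + delta
    }

    step <- 1
    repeat {
      cand <- theta + step * (prop - theta)
      if (constrain) cand <- pmax(cand, floor_val)
      ev_new <- tryCatch(reml_eval(y, X, Vcs, as.list(cand),
                                   want_derivs = TRUE),
                         error = function(e) NULL)
      if (!is.null(ev_new) &&
          (ev_new$loglik >= ll - 1e-10 || step < 2^-20)) break
      step <- step / 2
    }
    if (is.null(ev_new)) { converged <- FALSE; break }

    dll <- ev_new$loglik - ll
    rel <- max(abs(cand - theta) / pmax(abs(theta), floor_val))
    theta <- cand
    ll <- ev_new$loglik
    ev <- ev_new
    at_floor <- constrain & (theta <= floor_val * (1 + 1e-12))
    if (verbose)
      message(sprintf("iter %3d  ll = %.6f  (%s)", iter, ll,
                      paste(signif(theta, 4), collapse = ", ")))
    if (iter > n_em && abs(dll) < tol_loglik && rel < tol_par) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  scov <- tryCatch(solve(ev$AI), error = function(e)
    matrix(NA_real_, K, K, dimnames = list(labs, labs)))
  dimnames(scov) <- list(labs, labs)
  if (any(at_floor)) {
    scov[at_floor, ] <- NA_real_
    scov[, at_floor] <- NA_real_
  }
  structure(list(sigma2 = stats::setNames(as.numeric(theta), labs),
                 loglik = ll, sampling_cov = scov,
                 converged = converged, n_iterations = iter,
                 constraint_flags = stats::setNames(at_floor, labs),
                 n_records = n, n_fixed = ncol(X), labels = labs),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("vc_fit:", if (x$converged) "converged" else "NOT converged",
      "after", x$n_iterations, "iterations; restricted logL =",
      format(x$loglik, digits = 8), "\n")
  se <- sqrt(pmax(diag(x$sampling_cov), 0))
  tab <- data.frame(variance = x$sigma2, se = se,
                    at_boundary = x$constraint_flags)
  print(tab, digits = 4)
  invisible(x)
}

#' Heritability-type variance ratio from a fit
#'
#' Ratio of the summed named variance components to the total phenotypic
#' variance (all components plus residual), with a delta-method standard
#' error over the full sampling covariance of the components.
#'
#' @param fit a [reml_fit()] result.
#' @param numerator_labels component labels to sum in the numerator.
#' @param require_converged error on a non-converged fit (default TRUE).
#' @return named numeric vector `c(estimate, se)`; `se` is `NA` when any
#'   required sampling covariance entry is unavailable (boundary
#'   component).
#' @export
h2_from_fit <- function(fit, numerator_labels,
                        require_converged = TRUE) {
  stopifnot(inherits(fit, "vc_fit"))
  if (require_converged && !fit$converged)
    stop("fit did not converge; pass require_converged = FALSE to override")
  miss <- setdiff(numerator_labels, fit$labels)
  if (length(miss))
    stop("unknown component label(s): ", paste(miss, collapse = ", "))
  tot <- sum(fit$sigma2)
  if (tot <= 0) stop("total estimated variance is zero")
  num <- sum(fit$sigma2[numerator_labels])
  est <- num / tot
  in_num <- fit$labels %in% numerator_labels
  grad <- (in_num * tot - num) / tot^2
  se <- if (anyNA(fit$sampling_cov)) NA_real_ else {
    v <- drop(t(grad) %*% fit$sampling_cov %*% grad)
    sqrt(max(v, 0))
  }
  c(estimate = est, se = se)
}

#' Numeric coding of a categorical (monogenic) trait
#'
#' Two observed classes map to 0/1 and three classes to 0/1/2, in the
#' order of `levels` (or the sorted unique values), so that categorical
#' phenotypes can be analysed with the same linear machinery on the
#' observed scale.
#'
#' @param x character/factor vector of phenotype classes.
#' @param levels optional explicit class order.
#' @return numeric vector with attribute `"levels"`.
#' @export
code_categorical_trait <- function(x, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(as.character(x)))
  if (!all(as.character(x) %in% levels))
    stop("values outside the stated levels")
  if (length(levels) < 2 || length(levels) > 3)
    stop("expected 2 or 3 phenotype classes, got ", length(levels))
  out <- as.numeric(match(as.character(x), levels) - 1)
  attr(out, "levels") <- levels
  out
}
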