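make_design_fixture <- function() {
  ph <- data.frame(id = c("a", "a", "b", "b", "c"),
                   y = c(1.0, 1.2, 2.0, 1.9, 0.7),
                   sex = c("F", "F", "M", "M", "F"),
                   age = c(1, 2, 3, 5, 4))
  spec <- model_spec("y", fixed = c("sex", "age"),
                     poly_degree = c(age = 2),
                     genetic = list(pop = diag(3)))
  build_design(spec, ph, c("a", "b", "c"))
}

test_that("W maps records to individuals with one 1 per row", {
  d <- make_design_fixture()
  W <- as.matrix(d$W)
  expect_equal(dim(W), c(5, 3))
  expect_equal(unname(rowSums(W)), rep(1, 5))
  expect_equal(unname(colSums(W)), c(2, 2, 1))
})

test_that("factor expansion, polynomials and intercept shape X", {
  d <- make_design_fixture()
  # intercept + sex (2 levels -> 1 column) + age + age^2
  expect_equal(ncol(d$X), 4)
  poly_cols <- grep("poly", colnames(d$X))
  expect_equal(unname(d$X[, poly_cols[1]]), c(1, 2, 3, 5, 4))
  expect_equal(unname(d$X[, poly_cols[2]]), c(1, 4, 9, 25, 16))
})

test_that("rank-deficient fixed effects error with the aliased column", {
  ph <- data.frame(id = c("a", "b", "c"), y = 1:3,
                   x1 = c(1, 2, 3), x2 = c(2, 4, 6))
  spec <- model_spec("y", fixed = c("x1", "x2"),
                     genetic = list(pop = diag(3)))
  expect_error(build_design(spec, ph, c("a", "b", "c")), "aliased.*x2")
})

test_that("records with missing fields are dropped with a note", {
  ph <- data.frame(id = c("a", "b", "b"), y = c(1, NA, 3),
                   sex = c("F", "M", "M"))
  spec <- model_spec("y", fixed = "sex", genetic = list(pop = diag(2)))
  expect_message(d <- build_design(spec, ph, c("a", "b")), "dropped 1")
  expect_equal(length(d$y), 2)
})

test_that("records for unknown individuals are an alignment error", {
  ph <- data.frame(id = "zz", y = 1)
  spec <- model_spec("y", genetic = list(pop = diag(2)))
  expect_error(build_design(spec, ph, c("a", "b")), "absent from")
})

test_that("restricted loglik matches the closed form for V = I", {
  ph <- data.frame(id = c("a", "b", "c"), y = c(0, 0, 0))
  spec <- model_spec("y", genetic = list(pop = diag(3)))
  d <- build_design(spec, ph, c("a", "b", "c"))
  ll <- restricted_loglik(d, list(pop = diag(3)),
                          list(pop = 1e-12, residual = 1))
  # closed form: -0.5 (log|I| + log(n) + 0 + (n-1) log 2pi)
  expect_equal(ll, -0.5 * (log(3) + 2 * log(2 * pi)), tolerance = 1e-6)
})

test_that("scaling y and variances shifts loglik by the Jacobian only", {
  set.seed(41)
  n <- 20
  ph <- data.frame(id = sprintf("i%02d", 1:n), y = rnorm(n),
                   g = rep(1:4, 5))
  d <- build_design(model_spec("y", random = "g"), ph,
                    sprintf("i%02d", 1:n))
  Vcs <- heritpart:::record_covariances(d, list())
  s2 <- list(g = 0.5, residual = 1.2)
  ll1 <- heritpart:::reml_eval(d$y, d$X, Vcs, s2)$loglik
  cc <- 2.5
  s2c <- list(g = cc^2 * 0.5, residual = cc^2 * 1.2)
  ll2 <- heritpart:::reml_eval(cc * d$y, d$X, Vcs, s2c)$loglik
  # REML of scaled data: ll2 = ll1 - (n - p) log c
  expect_equal(ll2, ll1 - (n - 1) * log(cc), tolerance = 1e-8)
})

test_that("loglik agrees with a dense generic-solver oracle", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(20:50, 1)
    ids <- sprintf("i%03d", 1:n)
    M <- crossprod(matrix(rnorm(n * (n + 5)), n + 5, n)) / (n + 5)
    ph <- data.frame(id = ids, y = rnorm(n), x = rnorm(n),
                     grp = sample(letters[1:5], n, TRUE))
    d <- build_design(model_spec("y", fixed = "x", random = "grp"),
                      ph, ids)
    Vcs <- heritpart:::record_covariances(
      d, list(pop = grm(M, ids, 100)))
    s2 <- list(pop = 0.7, grp = 0.3, residual = 0.9)
    expect_equal(heritpart:::reml_eval(d$y, d$X, Vcs, s2)$loglik,
                 reml_oracle(d$y, d$X, Vcs, s2), tolerance = 1e-8)
  }
})

test_that("balanced one-way REML equals the ANOVA closed form", {
  set.seed(43)
  k <- 8; m <- 6
  grp <- rep(sprintf("g%d", 1:k), each = m)
  u <- rnorm(k, 0, sqrt(2))
  y <- 3 + u[as.integer(factor(grp))] + rnorm(k * m, 0, 1.5)
  ids <- sprintf("i%02d", seq_along(y))
  ph <- data.frame(id = ids, y = y, grp = grp)
  d <- build_design(model_spec("y", random = "grp"), ph, ids)
  fit <- reml_fit(d)
  ybar_g <- tapply(y, grp, mean)
  msb <- m * sum((ybar_g - mean(y))^2) / (k - 1)
  msw <- sum((y - ybar_g[grp])^2) / (k * (m - 1))
  expect_true(fit$converged)
  expect_equal(unname(fit$sigma2["residual"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["grp"]), (msb - msw) / m,
               tolerance = 1e-6)
})

test_that("zero-variance components reach the floor and are flagged", {
  # under sigma_g = 0 the REML optimum sits at the boundary for roughly
  # half of the draws; across several draws the floor must be reached,
  # flagged, and its SE withheld -- and never a large spurious estimate
  set.seed(44)
  n <- 120
  ids <- sprintf("i%03d", 1:n)
  dos <- matrix(rbinom(n * 300, 2, rep(runif(300, 0.2, 0.8), each = n)),
                n, 300)
  G <- build_grm(make_geno(dos, ids))
  floored <- logical(0)
  for (s in 1:6) {
    set.seed(100 + s)
    ph <- data.frame(id = ids, y = rnorm(n))   # no genetic signal
    d <- build_design(model_spec("y", genetic = list(pop = G)), ph, ids)
    fit <- reml_fit(d, list(pop = G))
    hit <- fit$sigma2[["pop"]] < 1e-6
    floored <- c(floored, hit)
    expect_equal(hit, unname(fit$constraint_flags[["pop"]]))
    if (hit) expect_true(is.na(fit$sampling_cov["pop", "pop"]))
  }
  expect_true(any(floored))
})

test_that("adding a nested component never lowers the maximized loglik", {
  st <- tiny_study()
  gf <- st$grm
  gk <- threshold_grm(gf, 0.1)
  d <- build_design(model_spec("y", fixed = "sex",
                               genetic = list(pop = gf)),
                    st$phenotypes, gf$ids)
  f1 <- reml_fit(d, list(pop = gf))
  f2 <- reml_fit(d, list(pop = gf, kin = gk))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("estimates are invariant to record permutation", {
  st <- tiny_study()
  gf <- st$grm
  ph <- st$phenotypes
  set.seed(45)
  perm <- sample(nrow(ph))
  d1 <- build_design(model_spec("y", fixed = "sex",
                                genetic = list(pop = gf)), ph, gf$ids)
  d2 <- build_design(model_spec("y", fixed = "sex",
                                genetic = list(pop = gf)),
                     ph[perm, ], gf$ids)
  f1 <- reml_fit(d1, list(pop = gf))
  f2 <- reml_fit(d2, list(pop = gf))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-4)
})

test_that("loglik is invariant to the fixed-effect reference level", {
  st <- tiny_study()
  gf <- st$grm
  ph <- st$phenotypes
  ph2 <- ph
  ph2$sex <- factor(ph2$sex, levels = c("M", "F"))
  d1 <- build_design(model_spec("y", fixed = "sex",
                                genetic = list(pop = gf)), ph, gf$ids)
  d2 <- build_design(model_spec("y", fixed = "sex",
                                genetic = list(pop = gf)), ph2, gf$ids)
  f1 <- reml_fit(d1, list(pop = gf))
  f2 <- reml_fit(d2, list(pop = gf))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("h2_from_fit computes ratios and delta-method SEs", {
  fit <- fake_fit(c(pop = 1, residual = 1))
  expect_equal(unname(h2_from_fit(fit, "pop")["estimate"]), 0.5)
  # sum ratio equals sum of separate ratios
  fit2 <- fake_fit(c(pop = 0.216, kin = 0.084, residual = 0.7))
  hpk <- h2_from_fit(fit2, c("pop", "kin"))
  expect_equal(unname(hpk["estimate"]),
               unname(h2_from_fit(fit2, "pop")["estimate"] +
                        h2_from_fit(fit2, "kin")["estimate"]))
  # delta SE against finite-difference propagation
  C <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3) * 1e-3
  fit3 <- fake_fit(c(pop = 0.4, kin = 0.1, residual = 0.5),
                   sampling_cov = C)
  se <- unname(h2_from_fit(fit3, "pop")["se"])
  ratio <- function(s) s[1] / sum(s)
  s0 <- c(0.4, 0.1, 0.5)
  eps <- 1e-6
  gr <- vapply(1:3, function(k) {
    sp <- s0; sp[k] <- sp[k] + eps
    (ratio(sp) - ratio(s0)) / eps
  }, 0)
  expect_equal(se, sqrt(drop(t(gr) %*% C %*% gr)), tolerance = 1e-6)
  expect_error(h2_from_fit(fit, "nope"), "unknown")
})

test_that("categorical trait coding maps 2 and 3 classes to 0/1(/2)", {
  two <- code_categorical_trait(c("horned", "scurred", "horned"))
  expect_equal(as.numeric(two), c(0, 1, 0))
  three <- code_categorical_trait(c("a", "Aa", "A"),
                                  levels = c("a", "Aa", "A"))
  expect_equal(as.numeric(three), c(0, 1, 2))
  expect_error(code_categorical_trait(letters[1:4]), "2 or 3")
})
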