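random_norm <- function(nr, nc, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(nr * nc), nr, nc)
  X <- t(scale(t(X)))  # row z-scored, as the pipeline guarantees
  as_norm(X)
}

test_that("SVD identities hold: reconstruction, ordering, energy", {
  nm <- random_norm(10, 8, seed = 4)
  d <- decompose(nm)
  A <- d$u %*% diag(d$d) %*% t(d$v)  # conditions x promoters
  expect_equal(t(A), nm$X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(d$d) <= 1e-12))
  expect_equal(sum(d$d^2), sum(nm$X^2), tolerance = 1e-8)
  expect_equal(crossprod(d$u), diag(8), tolerance = 1e-9, ignore_attr = TRUE)
  # singular values squared match an independent eigendecomposition of X'X
  ev <- sort(eigen(nm$X %*% t(nm$X), symmetric = TRUE)$values,
             decreasing = TRUE)
  expect_equal(d$d[1:8]^2, ev[1:8], tolerance = 1e-8)
})

test_that("rank-1 input is fully captured by the first component", {
  a <- c(1.2, -0.4, 2, 0.3)
  b <- c(0.5, 1, -1, 2, 0.1)
  X <- outer(a, b)
  nm <- as_norm(X, row_means = rep(0, 4), row_sds = rep(1, 4))
  d <- decompose(nm)
  expect_lt(d$d[2], 1e-10)
  expect_equal(variance_explained(d, 1), 1, tolerance = 1e-12)
  expect_equal(specific_component(d), X * 0, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(outer(d$loadings, d$scores), X, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("scores are oriented to correlate positively with growth", {
  nm <- random_norm(12, 9, seed = 5)
  d <- decompose(nm)
  expect_gte(cor(d$scores, d$growth_rates), 0)
  # flipping the growth axis flips the scores but not reconstruction or fit r
  d2 <- decompose(nm, growth_rates = -nm$growth_rates)
  expect_equal(abs(d2$scores), abs(d$scores), tolerance = 1e-9)
  expect_equal(outer(d2$loadings, d2$scores), outer(d$loadings, d$scores),
               tolerance = 1e-9)
  expect_equal(promoter_fit_r(d2), promoter_fit_r(d), tolerance = 1e-9)
})

test_that("variance fractions sum to one and k is validated", {
  nm <- random_norm(7, 6, seed = 6)
  d <- decompose(nm)
  fr <- vapply(seq_along(d$d), function(k) variance_explained(d, k),
               numeric(1))
  expect_equal(fr[length(fr)], 1, tolerance = 1e-12)
  expect_true(all(diff(fr) >= -1e-15))
  expect_error(variance_explained(d, 0), "out of range")
  expect_error(variance_explained(d, length(d$d) + 1), "out of range")
})

test_that("specific component is the exact rank-1 complement", {
  nm <- random_norm(9, 7, seed = 8)
  d <- decompose(nm)
  S <- specific_component(d)
  expect_equal(S + outer(d$loadings, d$scores), nm$X, tolerance = 1e-12)
  expect_equal(sum(S^2), sum(d$d[-1]^2), tolerance = 1e-8)
  # leading singular vector of S equals the second of X, up to sign
  s2 <- svd(t(S))
  expect_equal(abs(s2$u[, 1]), abs(d$u[, 2]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(s2$d[1], d$d[2], tolerance = 1e-8)
  expect_equal(residuals(d), S)
})

test_that("per-promoter fit r matches direct correlation and edge cases", {
  nm <- random_norm(6, 8, seed = 9)
  d <- decompose(nm)
  r <- promoter_fit_r(d)
  for (i in 1:6) {
    expect_equal(unname(r[i]),
                 unname(sign(d$loadings[i]) * cor(nm$X[i, ], d$scores)),
                 tolerance = 1e-10)
  }
  # constitutive noise-free promoter reconstructs perfectly
  tr <- tiny_constitutive_truth()
  act <- simulate_activity_matrix(tr, simulate_metabolome(tr))
  dc <- decompose(log_zscore(act))
  expect_equal(unname(promoter_fit_r(dc)), rep(1, 6), tolerance = 1e-8)
  # a row orthogonal to the scores has r near zero
  X <- rbind(outer(c(1, 1, 1), scale(1:6)[, 1])[1:2, ],
             rep(c(1, -1), 3) - mean(rep(c(1, -1), 3)))
  X[3, ] <- X[3, ] - sum(X[3, ] * X[1, ]) / sum(X[1, ]^2) * X[1, ]
  d3 <- decompose(as_norm(X))
  expect_lt(abs(promoter_fit_r(d3)[3]), 1e-6)
})

test_that("quadratic growth fit recovers exact coefficients", {
  mu <- seq(0.1, 1.5, length.out = 10)
  scores <- 1 + 2 * mu - mu^2
  X <- outer(rep(1, 5), scores)  # decomposition of a rank-1 matrix
  nm <- as_norm(X, growth_rates = setNames(mu, sprintf("C%02d", 1:10)))
  d <- decompose(nm)
  # map fitted scores back to the planted polynomial through the SVD scale
  fit <- fit_growth_poly(d)
  k <- d$scores[1] / scores[1]
  expect_equal(unname(fit$coefficients / k), c(1, 2, -1), tolerance = 1e-6)
  expect_error(fit_growth_poly(d, growth_rates = rep(c(0.1, 0.2), 5)),
               "4 distinct")
})

test_that("constant scores give zero polynomial slope terms", {
  mu <- seq(0.2, 1.2, length.out = 8)
  d <- list(scores = rep(2, 8), growth_rates = mu)
  class(d) <- "global_decomp"
  fit <- fit_growth_poly(d)
  expect_equal(unname(fit$coefficients), c(2, 0, 0), tolerance = 1e-9)
})

test_that("confidence band tightens as conditions accumulate", {
  width_at <- function(n) {
    set.seed(42)
    mu <- seq(0.1, 1.5, length.out = n)
    scores <- 1 + 2 * mu - mu^2 + rnorm(n, 0, 0.1)
    d <- structure(list(scores = scores, growth_rates = mu),
                   class = "global_decomp")
    fit <- fit_growth_poly(d)
    pr <- predict(fit$lm, newdata = data.frame(mu = 0.8),
                  interval = "confidence")
    pr[, "upr"] - pr[, "lwr"]
  }
  w <- vapply(c(8, 16, 64, 256), width_at, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("growth-rate predictions round-trip noise-free training data", {
  tr <- tiny_constitutive_truth(n_conditions = 12)
  act <- simulate_activity_matrix(tr, simulate_metabolome(tr))
  nm <- log_zscore(act)
  d <- decompose(nm)
  fit <- fit_growth_poly(d)
  pred <- predict_from_growth(fit, d, mu = tr$growth_rates)
  # quadratic global truth means the quadratic fit interpolates exactly
  expect_equal(pred$fit, act$pa, tolerance = 0.01, ignore_attr = TRUE)
  expect_true(all(pred$fit > 0))
  expect_true(all(pred$lwr <= pred$fit & pred$fit <= pred$upr))
  expect_warning(p0 <- predict_from_growth(fit, d, mu = 0), "extrapolat")
  c0 <- fit$coefficients[1]
  expect_equal(unname(p0$fit[, 1]),
               unname(exp(d$row_means + d$row_sds * d$loadings * c0)),
               tolerance = 1e-9)
})

test_that("decompose validates its input", {
  nm <- random_norm(5, 5, seed = 10)
  nm$X[2, 2] <- NA
  expect_error(decompose(nm), "non-finite")
})
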