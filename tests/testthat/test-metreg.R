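test_that("absolute metabolites are ln-transformed and mean-centred", {
  raw <- matrix(c(2, 4, 8), 1, 3,
                dimnames = list("fbp", c("c1", "c2", "c3")))
  mt <- normalize_metabolites(raw, "absolute")
  expect_equal(unname(mt$M[1, ]), c(-log(2), 0, log(2)), tolerance = 1e-9)
  expect_equal(mean(mt$M[1, !mt$mask[1, ]]), 0, tolerance = 1e-10)
})

test_that("relative metabolites are ln ratios to the reference condition", {
  raw <- matrix(c(1.5, 3, 6), 1, 3,
                dimnames = list("camp", c("glc", "ace", "succ")))
  mt <- normalize_metabolites(raw, "relative", reference = "glc")
  expect_equal(unname(mt$M[1, "glc"]), 0)
  expect_equal(unname(mt$M[1, "ace"]), log(2), tolerance = 1e-12)
  expect_error(normalize_metabolites(raw, "relative"), "reference")
})

test_that("carbon-source/secretion annotations mask cells from all fits", {
  raw <- matrix(runif(6, 1, 5), 2, 3,
                dimnames = list(c("glc6p", "pyr"), c("c1", "c2", "c3")))
  ann <- data.frame(metabolite_id = "glc6p", condition_id = "c2",
                    reason = "carbon_source")
  mt <- normalize_metabolites(raw, "absolute", annotations = ann)
  expect_true(mt$mask["glc6p", "c2"])
  expect_false(any(mt$mask["pyr", ]))
  # centring ignores the masked cell
  expect_equal(mean(mt$M["glc6p", c("c1", "c3")]), 0, tolerance = 1e-10)
  expect_error(normalize_metabolites(raw, annotations = data.frame(
    metabolite_id = "pyr", condition_id = "c1", reason = "typo")),
    "carbon_source")
  raw[1, 1] <- -1
  expect_error(normalize_metabolites(raw), "non-positive")
})

test_that("single-metabolite slope matches the closed form and an RSS grid", {
  set.seed(14)
  m <- rnorm(10); s <- 2 * m
  expect_warning(f <- fit_single(s, m), "perfect fit")
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$pearson_r, 1, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-20)

  s2 <- rnorm(10)
  s2 <- s2 - sum(s2 * m) / sum(m^2) * m  # orthogonal to m
  f2 <- fit_single(s2, m)
  expect_equal(f2$slope, 0, tolerance = 1e-12)

  s3 <- rnorm(10)
  f3 <- fit_single(s3, m)
  grid <- seq(-3, 3, by = 1e-4)
  rss_g <- vapply(grid, function(p) sum((s3 - p * m)^2), numeric(1))
  expect_equal(f3$slope, grid[which.min(rss_g)], tolerance = 1e-3)
  expect_equal(f3$rss, min(rss_g), tolerance = 1e-6)
  expect_equal(f3$slope, sum(s3 * m) / sum(m^2), tolerance = 1e-12)
  expect_equal(f3$aic, aic_score(f3$rss, 10, 1), tolerance = 1e-9)

  expect_null(fit_single(s3[1:2], m[1:2]))
})

test_that("AIC formula and identities", {
  expect_equal(aic_score(20, 20, 1), 2)
  expect_equal(aic_score(20, 20, 2), 4)
  expect_equal(aic_score(5, 20, 2), 20 * log(0.25) + 4)
  expect_equal(aic_score(5, 20, 2), -23.7259, tolerance = 1e-4)
  expect_equal(aic_score(10, 15, 1) - aic_score(5, 15, 1), 15 * log(2),
               tolerance = 1e-12)
  expect_error(aic_score(0, 10, 1), "positive")
  expect_error(aic_score(5, 0, 1), ">= 1")
})

test_that("screen_all recovers planted couplings and respects the cutoff", {
  tr <- generate_truth(sim_config(noise_sd_ln = 0.05), seed = 17)
  met <- simulate_metabolome(tr)
  act <- simulate_activity_matrix(tr, met)
  nm <- log_zscore(act)
  d <- decompose(nm)
  scr <- screen_all(specific_component(d), met)
  expect_equal(scr$cutoff, 0.75)
  expect_equal(formals(screen_all)$cutoff, 0.75)
  planted <- which(tr$coupling_slopes != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(planted))) {
    b <- scr$best[scr$best$promoter_id == tr$promoters[planted[r, 1]], ]
    expect_equal(b$metabolite_id, tr$metabolites[planted[r, 2]])
    expect_true(b$passed_cutoff)
    expect_gte(abs(b$pearson_r), 0.9)
    expect_equal(sign(b$slope), sign(tr$coupling_slopes[planted[r, ,
                                                                drop = FALSE]]))
  }
})

test_that("uncoupled promoters rarely pass the correlation cutoff", {
  # null: pure-noise specific components screened against the metabolome
  hits <- vapply(1:10, function(sd) {
    tr <- generate_truth(sim_config(n_coupled = 0, noise_sd_ln = 0.1),
                         seed = 200 + sd)
    met <- simulate_metabolome(tr)
    act <- simulate_activity_matrix(tr, met)
    d <- decompose(log_zscore(act))
    scr <- screen_all(specific_component(d), met)
    mean(scr$best$passed_cutoff)
  }, numeric(1))
  expect_lt(mean(hits), 0.1)
})

test_that("screening is invariant to metabolite rescaling, slopes inverse", {
  set.seed(19)
  S <- matrix(rnorm(3 * 8), 3, 8,
              dimnames = list(paste0("p", 1:3), paste0("c", 1:8)))
  M1 <- matrix(rnorm(2 * 8), 2, 8,
               dimnames = list(c("m1", "m2"), paste0("c", 1:8)))
  mt1 <- metabolite_table(M1)
  mt2 <- metabolite_table(M1 * 5)
  s1 <- screen_all(S, mt1); s2 <- screen_all(S, mt2)
  expect_equal(s2$fits$pearson_r, s1$fits$pearson_r, tolerance = 1e-12)
  expect_equal(s2$fits$slope, s1$fits$slope / 5, tolerance = 1e-12)
})

test_that("pair slopes match the normal-equation oracle", {
  set.seed(23)
  for (rep in 1:5) {
    M <- matrix(rnorm(4 * 12), 4, 12,
                dimnames = list(paste0("m", 1:4), paste0("c", 1:12)))
    s <- rnorm(12)
    mt <- metabolite_table(M)
    best <- fit_single(s, M[1, ], metabolite_id = "m1")
    ps <- pair_scan(s, mt, best)
    for (i in seq_len(nrow(ps))) {
      Xp <- t(M[c(ps$metabolite_1[i], ps$metabolite_2[i]), ])
      beta <- solve(crossprod(Xp), crossprod(Xp, s))
      expect_equal(c(ps$slope_1[i], ps$slope_2[i]), c(beta),
                   tolerance = 1e-8)
      expect_equal(ps$rss[i], sum((s - Xp %*% beta)^2), tolerance = 1e-8)
    }
  }
})

test_that("a planted metabolite pair is decisively preferred by AIC", {
  set.seed(29)
  n <- 23
  M <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("m", 1:6), paste0("c", 1:n)))
  mt <- metabolite_table(M)
  s <- M[2, ] + M[5, ] + rnorm(n, 0, 0.05)
  scr <- screen_all(matrix(s, 1, n, dimnames = list("p1", colnames(M))), mt)
  ps <- pair_scan(s, mt, as.list(scr$best[1, ]))
  top <- ps[1, ]
  expect_setequal(c(top$metabolite_1, top$metabolite_2), c("m2", "m5"))
  expect_true(top$better)
  expect_gte(top$delta_aic, 2)
  expect_equal(c(top$slope_1, top$slope_2), c(1, 1), tolerance = 0.1)
})

test_that("collinear pairs are skipped", {
  M <- matrix(rnorm(8), 1, 8)
  M <- rbind(M, 2 * M)
  dimnames(M) <- list(c("m1", "m2"), paste0("c", 1:8))
  mt <- metabolite_table(M)
  s <- rnorm(8)
  best <- fit_single(s, M[1, ], metabolite_id = "m1")
  ps <- pair_scan(s, mt, best)
  expect_equal(nrow(ps), 0)
  expect_equal(nrow(attr(ps, "skipped")), 1)
})

test_that("masked conditions are dropped pairwise in single and pair fits", {
  set.seed(31)
  M <- matrix(rnorm(2 * 10), 2, 10,
              dimnames = list(c("m1", "m2"), paste0("c", 1:10)))
  mask <- matrix(FALSE, 2, 10); mask[1, 1:2] <- TRUE
  mt <- metabolite_table(M, mask = mask)
  s <- setNames(rnorm(10), paste0("c", 1:10))
  f <- fit_single(s, mt$M[1, ], usable = !mt$mask[1, ])
  expect_equal(f$n_used, 8)
  expect_equal(f$slope, sum(s[-(1:2)] * M[1, -(1:2)]) / sum(M[1, -(1:2)]^2),
               tolerance = 1e-12)
  ps <- pair_scan(s, mt, f)
  expect_equal(ps$n_used, 8)
})

test_that("leave-one-condition-out flags leverage-driven fits", {
  m <- c(1, -1, 0.5, -0.5, 0.2, -0.2, 10)
  s_exact <- 3 * m
  r <- loco_stability(s_exact, m)
  expect_length(r, 7)
  expect_equal(unname(r), rep(1, 7), tolerance = 1e-12, ignore_attr = TRUE)
  # relation carried almost entirely by the outlier condition 7
  set.seed(37)
  s_noise <- c(rnorm(6, 0, 1), 30)
  r2 <- loco_stability(s_noise, m)
  expect_gt(max(r2) - r2[7], 0.2)
  expect_equal(attr(r2, "min"), min(r2))
  expect_error(loco_stability(s_exact[1:3], m[1:3]), "at least 4")
})
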