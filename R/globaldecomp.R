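#' Decompose promoter activity into global and specific regulation
#'
#' Fits the rank-1 "global regulation" model to a z-scored ln-activity matrix
#' by singular value decomposition, treating promoters as variables and
#' conditions as observations. The per-condition global score is
#' `t_j = sigma_1 * u1_j` and the per-promoter loading is `v1_i`, so the
#' rank-1 reconstruction of promoter i in condition j is
#' `loading_i * score_j`; the specific (transcription-factor-mediated)
#' component is the exact residual `S = X - loadings %o% scores`. The sign of
#' `(u1, v1)` is oriented jointly so that the scores correlate positively
#' with growth rate.
#'
#' @param norm a [log_zscore()] result.
#' @param growth_rates optional per-condition growth rates; defaults to the
#'   rates carried by `norm`.
#' @return An object of class `"global_decomp"` with components `u`, `d`
#'   (singular values, descending), `v`, `scores`, `loadings`, the training
#'   matrix `X` and its row stats, ids, and `growth_rates`. Methods:
#'   [print()], [summary()], [coef()] (loadings), [residuals()] (the specific
#'   matrix), [fitted()] (rank-1 reconstruction), [plot()], [predict()].
#' @examples
#' tr <- generate_truth(sim_config(noise_sd_ln = 0), seed = 1)
#' act <- simulate_activity_matrix(tr, simulate_metabolome(tr))
#' d <- decompose(log_zscore(act))
#' variance_explained(d, 1)
#' @export
decompose <- function(norm, growth_rates = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  X <- norm$X
  if (anyNA(X) || !all(is.finite(X))) {
    stop("normalized matrix contains non-finite values", call. = FALSE)
  }
  if (nrow(X) < 2L || ncol(X) < 2L) {
    stop("need at least 2 promoters and 2 conditions", call. = FALSE)
  }
  if (is.null(growth_rates)) growth_rates <- norm$growth_rates
  growth_rates <- growth_rates[colnames(X)]
  sv <- svd(t(X))  # conditions x promoters: u is condition-side
  u <- sv$u; v <- sv$v; d <- sv$d
  scores <- d[1] * u[, 1]
  if (stats::sd(scores) > 0 && stats::sd(growth_rates) > 0 &&
      stats::cor(scores, growth_rates) < 0) {
    u[, 1] <- -u[, 1]
    v[, 1] <- -v[, 1]
    scores <- -scores
  }
  rownames(u) <- colnames(X); rownames(v) <- rownames(X)
  names(scores) <- colnames(X)
  structure(list(u = u, d = d, v = v,
                 scores = scores,
                 loadings = stats::setNames(v[, 1], rownames(X)),
                 X = X, row_means = norm$row_means, row_sds = norm$row_sds,
                 promoters = rownames(X), conditions = colnames(X),
                 growth_rates = growth_rates),
            class = "global_decomp")
}

#' @export
print.global_decomp <- function(x, ...) {
  cat("Global/specific decomposition of promoter activity\n")
  cat(sprintf("  %d promoters x %d conditions\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  SV1 explains %.1f%% of total variance; cor(SV1, growth) = %.3f\n",
              100 * variance_explained(x, 1),
              stats::cor(x$scores, x$growth_rates)))
  invisible(x)
}

#' @export
summary.global_decomp <- function(object, n_components = 5L, ...) {
  k <- min(n_components, length(object$d))
  frac <- object$d^2 / sum(object$d^2)
  r <- promoter_fit_r(object)
  out <- list(
    components = data.frame(component = seq_len(k),
                            singular_value = object$d[seq_len(k)],
                            variance_fraction = frac[seq_len(k)],
                            cumulative = cumsum(frac)[seq_len(k)]),
    fit_r = r,
    growth_cor = stats::cor(object$scores, object$growth_rates))
  class(out) <- "summary.global_decomp"
  out
}

#' @export
print.summary.global_decomp <- function(x, ...) {
  cat("Variance captured by leading components:\n")
  print(x$components, row.names = FALSE, digits = 3)
  cat(sprintf("cor(global score, growth rate) = %.3f\n", x$growth_cor))
  cat(sprintf("median per-promoter reconstruction r (rank-1) = %.3f\n",
              stats::median(x$fit_r, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.global_decomp <- function(object, ...) object$loadings

#' @export
fitted.global_decomp <- function(object, ...) {
  outer(object$loadings, object$scores)
}

#' Specific-regulation residual matrix
#'
#' The exact complement of the rank-1 global reconstruction:
#' `S = X - loadings %o% scores`. Its squared Frobenius norm equals the sum
#' of the squared singular values beyond the first.
#'
#' @param d a [decompose()] result.
#' @return Matrix `S`, same shape and dimnames as the training matrix.
#' @export
specific_component <- function(d) {
  stopifnot(inherits(d, "global_decomp"))
  d$X - outer(d$loadings, d$scores)
}

#' @export
residuals.global_decomp <- function(object, ...) specific_component(object)

#' Fraction of total variance explained by the leading k components
#'
#' @param d a [decompose()] result.
#' @param k number of leading components, `1 <= k <= rank`.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(d, k = 1L) {
  stopifnot(inherits(d, "global_decomp"))
  if (k < 1L || k > length(d$d)) stop("k out of range", call. = FALSE)
  sum(d$d[seq_len(k)]^2) / sum(d$d^2)
}

#' Per-promoter agreement with the rank-1 reconstruction
#'
#' Pearson correlation, across conditions, between each promoter's measured
#' normalized activity and its reconstruction from the first singular vector
#' alone. Promoters whose reconstruction is constant (zero loading) get `NaN`
#' with a warning.
#'
#' @param d a [decompose()] result.
#' @return Named vector of correlations.
#' @export
promoter_fit_r <- function(d) {
  stopifnot(inherits(d, "global_decomp"))
  recon <- outer(d$loadings, d$scores)
  r <- vapply(seq_len(nrow(d$X)), function(i) {
    if (stats::sd(recon[i, ]) == 0 || stats::sd(d$X[i, ]) == 0) return(NaN)
    stats::cor(d$X[i, ], recon[i, ])
  }, numeric(1))
  names(r) <- rownames(d$X)
  if (anyNA(r)) {
    warning("constant reconstruction for promoter(s): ",
            paste(names(r)[is.na(r)], collapse = ", "), call. = FALSE)
  }
  r
}

#' Quadratic fit of the global score to growth rate
#'
#' Ordinary least squares of the per-condition global score on a second-degree
#' polynomial in growth rate, as used to predict activities in new conditions
#' from their growth rate alone.
#'
#' @param d a [decompose()] result.
#' @param growth_rates optional override of the training growth rates.
#' @param level confidence level for intervals, default 0.95.
#' @return Object of class `"growth_poly"`: `coefficients` (c0, c1, c2),
#'   `vcov`, the underlying `lm` fit, `mu_range`, `level`.
#' @export
fit_growth_poly <- function(d, growth_rates = NULL, level = 0.95) {
  stopifnot(inherits(d, "global_decomp"))
  mu <- if (is.null(growth_rates)) d$growth_rates else growth_rates
  if (length(unique(mu)) < 4L) {
    stop("need at least 4 distinct growth rates", call. = FALSE)
  }
  dat <- data.frame(score = d$scores, mu = mu)
  fit <- stats::lm(score ~ mu + I(mu^2), data = dat)
  structure(list(coefficients = stats::setNames(stats::coef(fit),
                                                c("c0", "c1", "c2")),
                 # noise-free inputs fit exactly; the perfect-fit warning from
                 # summary.lm is expected there and not informative
                 vcov = suppressWarnings(stats::vcov(fit)), lm = fit,
                 mu_range = range(mu), level = level),
            class = "growth_poly")
}

#' @export
print.growth_poly <- function(x, ...) {
  cat("Quadratic growth-rate model of the global score:\n")
  cat(sprintf("  score = %.4g + %.4g mu + %.4g mu^2   (mu in [%.2f, %.2f]/h)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$mu_range[1], x$mu_range[2]))
  invisible(x)
}

#' Predict linear-scale promoter activity from growth rate alone
#'
#' Evaluates the quadratic growth model to obtain a global score for each
#' supplied growth rate, multiplies by the promoter loadings, and reverts
#' through the stored row statistics to the linear activity scale:
#' `pa_hat = exp(mean_i + sd_i * loading_i * poly(mu))`. Confidence bounds on
#' the polynomial are propagated through the same monotone transform.
#'
#' @param fit a [fit_growth_poly()] result.
#' @param d the matching [decompose()] result.
#' @param mu growth rate(s) (1/h); values outside the training range trigger
#'   an extrapolation warning.
#' @return List of matrices (promoters x length(mu)): `fit`, `lwr`, `upr`.
#' @export
predict_from_growth <- function(fit, d, mu) {
  stopifnot(inherits(fit, "growth_poly"), inherits(d, "global_decomp"))
  if (any(mu < fit$mu_range[1] - 1e-9 | mu > fit$mu_range[2] + 1e-9)) {
    warning("growth rate outside training range; extrapolating",
            call. = FALSE)
  }
  pr <- stats::predict(fit$lm, newdata = data.frame(mu = mu),
                       interval = "confidence", level = fit$level)
  mk <- function(score_vec) {
    z <- outer(d$loadings, score_vec)
    exp(d$row_means + d$row_sds * z)
  }
  lo <- mk(pr[, "lwr"]); hi <- mk(pr[, "upr"])
  list(fit = mk(pr[, "fit"]), lwr = pmin(lo, hi), upr = pmax(lo, hi))
}

#' @export
predict.global_decomp <- function(object, mu = object$growth_rates,
                                  fit = NULL, ...) {
  if (is.null(fit)) fit <- fit_growth_poly(object)
  predict_from_growth(fit, object, mu)
}

#' @export
plot.global_decomp <- function(x, which = 1L, ...) {
  if (1L %in% which) {
    graphics::plot(x$growth_rates, x$scores, pch = 19,
                   xlab = "growth rate (1/h)", ylab = "global score (SV1)",
                   main = sprintf("SV1 vs growth (%.0f%% of variance)",
                                  100 * variance_explained(x, 1)), ...)
    fit <- fit_growth_poly(x)
    mu_grid <- seq(min(x$growth_rates), max(x$growth_rates), length.out = 100)
    pr <- stats::predict(fit$lm, newdata = data.frame(mu = mu_grid),
                         interval = "confidence", level = fit$level)
    graphics::lines(mu_grid, pr[, "fit"])
    graphics::lines(mu_grid, pr[, "lwr"], lty = 2)
    graphics::lines(mu_grid, pr[, "upr"], lty = 2)
  }
  if (2L %in% which) {
    r <- sort(promoter_fit_r(x), decreasing = TRUE)
    graphics::plot(seq_along(r), r, pch = 19, xlab = "promoter (sorted)",
                   ylab = "r (measured vs rank-1 reconstruction)",
                   main = "Per-promoter fit of global regulation", ...)
    graphics::abline(h = 0.75, lty = 3)
  }
  invisible(x)
}

#' Export decomposition results as CSV files
#'
#' Writes per-condition scores (with growth rates), per-promoter loadings and
#' rank-1 fit correlations, and the specific residual matrix.
#'
#' @param d a [decompose()] result.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_decomposition_csv <- function(d, dir) {
  stopifnot(inherits(d, "global_decomp"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(scores = file.path(dir, "scores.csv"),
             loadings = file.path(dir, "loadings.csv"),
             specific = file.path(dir, "specific_matrix.csv"))
  utils::write.csv(data.frame(condition_id = d$conditions,
                              score = unname(d$scores),
                              growth_rate = unname(d$growth_rates)),
                   paths["scores"], row.names = FALSE)
  utils::write.csv(data.frame(promoter_id = d$promoters,
                              loading = unname(d$loadings),
                              fit_r = unname(suppressWarnings(promoter_fit_r(d)))),
                   paths["loadings"], row.names = FALSE)
  S <- specific_component(d)
  utils::write.csv(data.frame(promoter_id = rownames(S), S,
                              check.names = FALSE),
                   paths["specific"], row.names = FALSE)
  invisible(paths)
}
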