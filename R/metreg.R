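#' ln-normalized metabolite x condition table
#'
#' Holds the ln-scale metabolite matrix used to explain specific
#' transcriptional regulation, the per-metabolite quantification mode, and
#' the exclusion mask (cells where a metabolite was used as a carbon source
#' or secreted, which all fits ignore).
#'
#' @param M numeric matrix (metabolites x conditions) of ln-normalized
#'   values, with dimnames. Absolute-mode rows are centred over unmasked
#'   conditions; relative-mode rows are ln ratios to the reference condition.
#' @param mode per-metabolite mode, `"absolute"` or `"relative"` (recycled).
#' @param reference_condition reference condition id for relative rows.
#' @param mask logical matrix, `TRUE` = excluded cell; `NA` values in `M` are
#'   always masked.
#' @return Object of class `"metabolite_table"`.
#' @export
metabolite_table <- function(M, mode = "absolute",
                             reference_condition = NULL, mask = NULL) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  mode <- rep_len(mode, nrow(M))
  names(mode) <- rownames(M)
  stopifnot(all(mode %in% c("absolute", "relative")))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(M), ncol(M), dimnames = dimnames(M))
  stopifnot(identical(dim(mask), dim(M)))
  mask <- mask | is.na(M)
  dimnames(mask) <- dimnames(M)
  structure(list(M = M, metabolites = rownames(M), conditions = colnames(M),
                 mode = mode, reference_condition = reference_condition,
                 mask = mask),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("Metabolite table: %d metabolites x %d conditions (%d masked cells)\n",
              nrow(x$M), ncol(x$M), sum(x$mask)))
  invisible(x)
}

#' Normalize raw metabolite concentrations
#'
#' Absolutely quantified metabolites are ln-transformed and centred by their
#' mean over unmasked conditions; relatively quantified metabolites are
#' expressed as the natural log of the ratio to the reference condition
#' (not centred). Conditions in which a metabolite was used as a carbon
#' source or secreted are masked and ignored by every downstream fit.
#'
#' @param raw numeric matrix (metabolites x conditions) of concentrations
#'   (mM for absolute rows, arbitrary consistent units for relative rows);
#'   must be positive where present, `NA` allowed.
#' @param modes per-metabolite `"absolute"`/`"relative"` (recycled).
#' @param reference reference condition id, required if any row is relative.
#' @param annotations optional data frame with columns `metabolite_id`,
#'   `condition_id`, `reason` (`"carbon_source"` or `"secreted"`) marking
#'   cells to exclude.
#' @return A [metabolite_table()].
#' @export
normalize_metabolites <- function(raw, modes = "absolute", reference = NULL,
                                  annotations = NULL) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)), !is.null(colnames(raw)))
  if (any(raw <= 0, na.rm = TRUE)) {
    stop("non-positive metabolite concentration", call. = FALSE)
  }
  modes <- rep_len(modes, nrow(raw))
  mask <- matrix(FALSE, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  if (!is.null(annotations) && nrow(annotations)) {
    ok_reason <- annotations$reason %in% c("carbon_source", "secreted")
    if (!all(ok_reason)) {
      stop("unknown exclusion reason(s): ",
           paste(unique(annotations$reason[!ok_reason]), collapse = ", "),
           "; allowed: carbon_source, secreted", call. = FALSE)
    }
    mask[cbind(match(annotations$metabolite_id, rownames(raw)),
               match(annotations$condition_id, colnames(raw)))] <- TRUE
  }
  mask <- mask | is.na(raw)
  M <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (k in seq_len(nrow(raw))) {
    if (modes[k] == "absolute") {
      lk <- log(raw[k, ])
      M[k, ] <- lk - mean(lk[!mask[k, ]])
    } else {
      if (is.null(reference) || !reference %in% colnames(raw)) {
        stop("relative metabolite requires a reference condition",
             call. = FALSE)
      }
      if (is.na(raw[k, reference])) {
        stop("metabolite ", rownames(raw)[k],
             ": no value in reference condition", call. = FALSE)
      }
      M[k, ] <- log(raw[k, ] / raw[k, reference])
    }
  }
  metabolite_table(M, modes, reference, mask)
}

#' Akaike information criterion for a least-squares fit
#'
#' `AIC = N * ln(RSS/N) + 2K` with the natural log, where N is the number of
#' conditions used, RSS the residual sum of squares and K the number of
#' fitted slopes (1 for a single metabolite, 2 for a pair).
#'
#' @param rss residual sum of squares, positive.
#' @param n number of observations, >= 1.
#' @param k number of parameters.
#' @return The AIC value.
#' @examples
#' aic_score(5, 20, 2)  # 20*log(0.25) + 4
#' @export
aic_score <- function(rss, n, k) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (rss <= 0) stop("rss must be positive", call. = FALSE)
  n * log(rss / n) + 2 * k
}

# AIC that tolerates a numerically perfect fit (upstream callers report a
# -Inf sentinel with a warning rather than erroring).
aic_safe <- function(rss, n, k) {
  if (rss < 1e-12) {
    warning("perfect fit: AIC reported as -Inf", call. = FALSE)
    return(-Inf)
  }
  aic_score(rss, n, k)
}

#' No-intercept regression of specific regulation on one metabolite
#'
#' Fits `s = p * m` by least squares over the shared unmasked conditions:
#' `p = sum(s m) / sum(m^2)`. The goodness of fit is stored as the signed
#' Pearson correlation between `s` and `m` (identical in magnitude to the
#' correlation between `s` and the fitted values); a Spearman rank
#' correlation and the AIC are attached.
#'
#' @param s numeric vector, one promoter's specific-regulation row.
#' @param m numeric vector, one metabolite's ln-normalized row.
#' @param usable logical vector of conditions to include (default all);
#'   non-finite entries are dropped as well.
#' @param promoter_id,metabolite_id identifiers carried into the result.
#' @return A list of class `"regression_fit"` (`slope`, `n_used`, `rss`,
#'   `k_params`, `aic`, `pearson_r`, `spearman_r`, ids), or `NULL` with
#'   attribute `"reason"` if fewer than 3 conditions are usable.
#' @export
fit_single <- function(s, m, usable = NULL,
                       promoter_id = NA_character_,
                       metabolite_id = NA_character_) {
  if (is.null(usable)) usable <- rep(TRUE, length(s))
  usable <- usable & is.finite(s) & is.finite(m)
  n <- sum(usable)
  if (n < 3L) return(NULL)
  su <- s[usable]; mu <- m[usable]
  smm <- sum(mu^2)
  if (smm == 0) stop("metabolite row is identically zero", call. = FALSE)
  p <- sum(su * mu) / smm
  rss <- sum((su - p * mu)^2)
  structure(list(
    promoter_id = promoter_id, metabolite_id = metabolite_id,
    slope = p, n_used = n, rss = rss, k_params = 1L,
    aic = aic_safe(rss, n, 1L),
    pearson_r = if (stats::sd(su) == 0 || stats::sd(mu) == 0) NaN else
      stats::cor(su, mu),
    spearman_r = suppressWarnings(stats::cor(su, mu, method = "spearman"))
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("s = %.4g * %s  (n = %d, r = %.3f, AIC = %.2f)\n",
              x$slope, x$metabolite_id, x$n_used, x$pearson_r, x$aic))
  invisible(x)
}

#' Screen every promoter against every metabolite
#'
#' Runs [fit_single()] for all promoter x metabolite combinations, marks the
#' fits whose Pearson correlation passes the cutoff, and selects each
#' promoter's best single metabolite (largest `|r|`; ties broken by larger
#' `|Spearman|`, then lexicographic metabolite id). The sign of the passing
#' correlation is recorded as activation (+) or inhibition (-).
#'
#' @param S specific-regulation matrix (promoters x conditions), e.g.
#'   [specific_component()].
#' @param M a [metabolite_table()] sharing the condition ordering.
#' @param cutoff absolute Pearson correlation cutoff, default 0.75.
#' @return Object of class `"met_screen"`: `fits` (all fits, data frame),
#'   `best` (one row per promoter, with `sign` and `passed_cutoff`),
#'   `skipped` (fits with too few usable conditions), `cutoff`.
#' @export
screen_all <- function(S, M, cutoff = 0.75) {
  stopifnot(is.matrix(S), inherits(M, "metabolite_table"))
  if (!identical(colnames(S), M$conditions)) {
    stop("S and metabolite table must share condition ordering",
         call. = FALSE)
  }
  nf <- nrow(S) * nrow(M$M)
  o_prom <- o_met <- character(nf)
  o_slope <- o_rss <- o_aic <- o_r <- o_rho <- numeric(nf)
  o_n <- integer(nf)
  skipped <- list()
  ri <- 0L
  for (i in seq_len(nrow(S))) {
    for (k in seq_len(nrow(M$M))) {
      f <- fit_single(S[i, ], M$M[k, ], usable = !M$mask[k, ],
                      promoter_id = rownames(S)[i],
                      metabolite_id = M$metabolites[k])
      if (is.null(f)) {
        n_ok <- sum(!M$mask[k, ] & is.finite(S[i, ]) & is.finite(M$M[k, ]))
        skipped[[length(skipped) + 1L]] <- data.frame(
          promoter_id = rownames(S)[i], metabolite_id = M$metabolites[k],
          reason = sprintf("only %d usable conditions", n_ok),
          stringsAsFactors = FALSE)
        next
      }
      ri <- ri + 1L
      o_prom[ri] <- f$promoter_id; o_met[ri] <- f$metabolite_id
      o_slope[ri] <- f$slope; o_n[ri] <- f$n_used; o_rss[ri] <- f$rss
      o_aic[ri] <- f$aic; o_r[ri] <- f$pearson_r; o_rho[ri] <- f$spearman_r
    }
  }
  keep <- seq_len(ri)
  fits <- data.frame(
    promoter_id = o_prom[keep], metabolite_id = o_met[keep],
    slope = o_slope[keep], n_used = o_n[keep], rss = o_rss[keep],
    aic = o_aic[keep], pearson_r = o_r[keep], spearman_r = o_rho[keep],
    stringsAsFactors = FALSE)
  fits$passed_cutoff <- !is.na(fits$pearson_r) & abs(fits$pearson_r) >= cutoff
  best <- do.call(rbind, lapply(split(fits, fits$promoter_id), function(g) {
    g <- g[!is.na(g$pearson_r), , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g <- g[order(-abs(g$pearson_r), -abs(g$spearman_r), g$metabolite_id), ]
    g[1, , drop = FALSE]
  }))
  best$sign <- ifelse(best$pearson_r >= 0, "activation", "inhibition")
  best <- best[match(rownames(S)[rownames(S) %in% best$promoter_id],
                     best$promoter_id), ]
  rownames(best) <- NULL
  structure(list(fits = fits, best = best,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
                 cutoff = cutoff),
            class = "met_screen")
}

#' @export
print.met_screen <- function(x, ...) {
  n_pass <- sum(x$best$passed_cutoff)
  cat(sprintf("Metabolite screen: %d fits, cutoff |r| >= %.2f\n",
              nrow(x$fits), x$cutoff))
  cat(sprintf("  %d of %d promoters have a passing best single metabolite\n",
              n_pass, nrow(x$best)))
  invisible(x)
}

#' Scan all metabolite pairs for one promoter
#'
#' Fits `s = p1*m1 + p2*m2` (no intercept) for every metabolite pair by
#' closed-form normal equations over the conditions unmasked for both
#' metabolites, and compares each pair to the promoter's best single
#' metabolite via `delta_AIC = AIC_best_single - AIC_pair`. A pair is flagged
#' as genuinely better only when `delta_AIC >= delta_aic`; the default 10
#' (the conventional "essentially no support" boundary for the worse model)
#' guards against the heavy selection multiplicity of scanning ~1,000 pairs,
#' which a margin of 2 does not (see the package vignette). Near-collinear
#' pairs are skipped.
#'
#' @param s one promoter's specific-regulation row.
#' @param M a [metabolite_table()].
#' @param best the promoter's best single [fit_single()] result (or its row
#'   from [screen_all()]`$best`).
#' @param delta_aic acceptance margin on the AIC difference, default 10.
#' @param kappa_max condition-number threshold on the 2x2 normal matrix above
#'   which a pair is skipped as collinear, default 1e10.
#' @return Data frame of pair fits (`metabolite_1`, `metabolite_2`,
#'   `slope_1`, `slope_2`, `n_used`, `rss`, `aic`, `pearson_r`, `delta_aic`,
#'   `better`), sorted by AIC, with skipped pairs in attribute `"skipped"`.
#' @export
pair_scan <- function(s, M, best, delta_aic = 10, kappa_max = 1e10) {
  stopifnot(inherits(M, "metabolite_table"))
  nm <- nrow(M$M)
  if (nm < 2L) stop("need at least two metabolites", call. = FALSE)
  best_aic <- if (is.list(best)) best$aic else stop("best fit required")
  usable_k <- lapply(seq_len(nm), function(k) {
    !M$mask[k, ] & is.finite(M$M[k, ]) & is.finite(s)
  })
  no_mask <- !any(M$mask) && all(is.finite(s)) && all(is.finite(M$M))
  if (no_mask) {
    G <- M$M %*% t(M$M)
    Ds <- drop(M$M %*% s)
    rsums <- rowSums(M$M)
    ssum <- sum(s); ss2 <- sum(s^2); n_all <- length(s)
  }
  n_pairs <- nm * (nm - 1L) %/% 2L
  o_i <- o_j <- o_n <- integer(n_pairs)
  o_p1 <- o_p2 <- o_rss <- o_aic <- o_r <- numeric(n_pairs)
  np <- 0L
  skipped <- list()
  for (i in seq_len(nm - 1L)) {
    for (j in (i + 1L):nm) {
      if (no_mask) {
        n <- n_all
        a <- G[i, i]; b <- G[i, j]; cc <- G[j, j]
        d1 <- Ds[i]; d2 <- Ds[j]
        sm1 <- rsums[i]; sm2 <- rsums[j]; ssum_u <- ssum; ss2_u <- ss2
        m1 <- M$M[i, ]; m2 <- M$M[j, ]; su <- s
      } else {
        u <- usable_k[[i]] & usable_k[[j]]
        n <- sum(u)
        if (n < 3L) {
          skipped[[length(skipped) + 1L]] <- c(i, j)
          next
        }
        m1 <- M$M[i, u]; m2 <- M$M[j, u]; su <- s[u]
        a <- sum(m1^2); b <- sum(m1 * m2); cc <- sum(m2^2)
        d1 <- sum(su * m1); d2 <- sum(su * m2)
        sm1 <- sum(m1); sm2 <- sum(m2); ssum_u <- sum(su); ss2_u <- sum(su^2)
      }
      tr <- a + cc
      disc <- sqrt(max((a - cc)^2 + 4 * b^2, 0))
      lam1 <- (tr + disc) / 2; lam2 <- (tr - disc) / 2
      if (lam2 <= 0 || lam1 / lam2 > kappa_max) {
        skipped[[length(skipped) + 1L]] <- c(i, j)
        next
      }
      det <- a * cc - b^2
      p1 <- (cc * d1 - b * d2) / det
      p2 <- (a * d2 - b * d1) / det
      rss <- max(ss2_u - (p1 * d1 + p2 * d2), 0)
      aic <- if (rss < 1e-12) -Inf else aic_score(rss, n, 2L)
      # Pearson r between s and fitted values from scalar aggregates
      sf <- p1 * d1 + p2 * d2
      fsum <- p1 * sm1 + p2 * sm2
      f2 <- p1^2 * a + 2 * p1 * p2 * b + p2^2 * cc
      num <- sf - ssum_u * fsum / n
      den <- sqrt(max(ss2_u - ssum_u^2 / n, 0) * max(f2 - fsum^2 / n, 0))
      r <- if (den > 0) num / den else NaN
      np <- np + 1L
      o_i[np] <- i; o_j[np] <- j; o_n[np] <- n
      o_p1[np] <- p1; o_p2[np] <- p2
      o_rss[np] <- rss; o_aic[np] <- aic; o_r[np] <- r
    }
  }
  keep <- seq_len(np)
  out <- data.frame(
    metabolite_1 = M$metabolites[o_i[keep]],
    metabolite_2 = M$metabolites[o_j[keep]],
    slope_1 = o_p1[keep], slope_2 = o_p2[keep], n_used = o_n[keep],
    rss = o_rss[keep], aic = o_aic[keep], pearson_r = o_r[keep],
    stringsAsFactors = FALSE)
  out$delta_aic <- best_aic - out$aic
  out$better <- out$delta_aic >= delta_aic
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  if (length(skipped)) {
    sk <- do.call(rbind, skipped)
    attr(out, "skipped") <- data.frame(
      metabolite_1 = M$metabolites[sk[, 1]],
      metabolite_2 = M$metabolites[sk[, 2]], stringsAsFactors = FALSE)
  }
  attr(out, "delta_aic") <- delta_aic
  out
}

#' Leave-one-condition-out stability of a single-metabolite fit
#'
#' For each condition used by the fit, refits the slope without it and
#' records the Pearson correlation between `s` and `m` on the remaining
#' conditions. Large drops flag fits driven by a single leverage condition.
#'
#' @param s,m,usable as in [fit_single()].
#' @return Named vector of left-out correlations (length = number of used
#'   conditions) with attributes `"min"` and `"range"`.
#' @export
loco_stability <- function(s, m, usable = NULL) {
  if (is.null(usable)) usable <- rep(TRUE, length(s))
  usable <- usable & is.finite(s) & is.finite(m)
  idx <- which(usable)
  if (length(idx) < 4L) stop("need at least 4 usable conditions", call. = FALSE)
  r <- vapply(idx, function(j) {
    keep <- setdiff(idx, j)
    stats::cor(s[keep], m[keep])
  }, numeric(1))
  names(r) <- if (!is.null(names(s))) names(s)[idx] else as.character(idx)
  attr(r, "min") <- min(r)
  attr(r, "range") <- diff(range(r))
  r
}

#' Write / read a metabolome as concentration CSVs
#'
#' The metabolome CSV has columns `metabolite_id`, `mode`, then one column
#' per condition holding concentrations (the ln-normalized table is
#' reconstructed with [normalize_metabolites()] on reading); the optional
#' annotation CSV lists excluded (metabolite, condition) cells.
#'
#' @param M a [metabolite_table()] (written as `exp(M)` concentrations for
#'   absolute rows, i.e. relative to the row geometric mean).
#' @param path,annotations_path CSV paths.
#' @param annotations optional annotation data frame to write.
#' @return The written path(s) / a [metabolite_table()].
#' @export
write_metabolome_csv <- function(M, path, annotations = NULL,
                                 annotations_path = NULL) {
  stopifnot(inherits(M, "metabolite_table"))
  conc <- exp(M$M)
  conc[M$mask] <- NA
  df <- data.frame(metabolite_id = M$metabolites, mode = unname(M$mode),
                   conc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(annotations) && !is.null(annotations_path)) {
    utils::write.csv(annotations, annotations_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_metabolome_csv
#' @param reference reference condition id for relative rows.
#' @export
read_metabolome_csv <- function(path, annotations_path = NULL,
                                reference = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  raw <- as.matrix(df[, setdiff(names(df), c("metabolite_id", "mode")),
                      drop = FALSE])
  rownames(raw) <- df$metabolite_id
  ann <- if (!is.null(annotations_path)) {
    utils::read.csv(annotations_path, stringsAsFactors = FALSE)
  }
  normalize_metabolites(raw, df$mode, reference, ann)
}
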