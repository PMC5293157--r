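#' Leave-one-condition-out cross-validation of the combined model
#'
#' For each held-out condition, the slope of every accepted
#' promoter-metabolite interaction is re-fitted on the remaining conditions
#' (the global scores and loadings are kept from the full decomposition,
#' matching the fact that only the interaction parameters are re-estimated),
#' the held-out specific component is predicted from the metabolite
#' concentration, summed with the global contribution, and reverted to the
#' linear activity scale. Promoters without an accepted interaction are
#' predicted from global regulation alone, as are cells whose metabolite is
#' masked in the held-out condition (these are flagged).
#'
#' @param norm the [log_zscore()] training matrix.
#' @param d the matching [decompose()] result.
#' @param M a [metabolite_table()].
#' @param interactions data frame of accepted fits with columns
#'   `promoter_id`, `metabolite_1`, optionally `metabolite_2` (`NA` for
#'   single-metabolite models).
#' @return Object of class `"crossval_result"`: `predictions` and `measured`
#'   (linear-scale matrices), `per_promoter_r` (Pearson on the ln scale),
#'   `overall_r2` (squared Pearson over all cells, ln scale),
#'   `overall_r2_linear`, and `flagged` (cells predicted from global only
#'   because of masking).
#' @export
loocv_full_model <- function(norm, d, M, interactions) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(d, "global_decomp"),
            inherits(M, "metabolite_table"))
  X <- norm$X
  conds <- colnames(X)
  if (!identical(conds, M$conditions)) {
    stop("condition ordering mismatch between matrix and metabolome",
         call. = FALSE)
  }
  if (nrow(interactions)) {
    if (!all(interactions$promoter_id %in% rownames(X))) {
      stop("interaction references unknown promoter", call. = FALSE)
    }
    if (!all(stats::na.omit(c(interactions$metabolite_1,
                              interactions$metabolite_2)) %in% M$metabolites)) {
      stop("interaction references unknown metabolite", call. = FALSE)
    }
  }
  has_m2 <- "metabolite_2" %in% names(interactions)
  z_hat <- outer(d$loadings, d$scores)
  S <- specific_component(d)
  flagged <- NULL
  for (j in seq_along(conds)) {
    for (ii in seq_len(nrow(interactions))) {
      prom <- interactions$promoter_id[ii]
      mets <- interactions$metabolite_1[ii]
      if (has_m2 && !is.na(interactions$metabolite_2[ii])) {
        mets <- c(mets, interactions$metabolite_2[ii])
      }
      s_row <- S[prom, ]
      usable <- rep(TRUE, length(conds))
      for (mk in mets) usable <- usable & !M$mask[mk, ] & is.finite(M$M[mk, ])
      if (!usable[j]) {
        flagged <- rbind(flagged, data.frame(promoter_id = prom,
                                             condition_id = conds[j],
                                             stringsAsFactors = FALSE))
        next
      }
      train <- usable
      train[j] <- FALSE
      Mt <- M$M[mets, train, drop = FALSE]
      p <- solve(Mt %*% t(Mt), Mt %*% s_row[train])
      z_hat[prom, j] <- z_hat[prom, j] + sum(p * M$M[mets, j])
    }
  }
  measured <- invert_log_zscore(norm)
  predictions <- invert_log_zscore(norm, z_hat)
  ln_m <- log(measured); ln_p <- log(predictions)
  per_r <- vapply(seq_len(nrow(X)), function(i) {
    stats::cor(ln_m[i, ], ln_p[i, ])
  }, numeric(1))
  names(per_r) <- rownames(X)
  structure(list(
    predictions = predictions, measured = measured,
    per_promoter_r = per_r,
    overall_r2 = stats::cor(as.vector(ln_m), as.vector(ln_p))^2,
    overall_r2_linear = stats::cor(as.vector(measured),
                                   as.vector(predictions))^2,
    flagged = flagged,
    interactions = interactions
  ), class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("Leave-one-condition-out cross-validation\n")
  cat(sprintf("  overall R^2 (ln scale) = %.3f (linear scale %.3f)\n",
              x$overall_r2, x$overall_r2_linear))
  cat(sprintf("  %d accepted interactions; median per-promoter r = %.3f\n",
              nrow(x$interactions), stats::median(x$per_promoter_r)))
  invisible(x)
}

#' Reporter protein concentration from activity and growth rate
#'
#' At steady state the concentration of a stable reporter equals the
#' promoter activity divided by the growth rate (production balanced by
#' dilution), so constitutively expressed proteins accumulate at slow growth.
#'
#' @param pa promoter activity (fluorescence units/h), vector or matrix
#'   (promoters x conditions).
#' @param mu growth rate(s) (1/h), strictly positive; recycled across matrix
#'   columns.
#' @return Concentration in fluorescence units, same shape as `pa`.
#' @export
gfp_concentration <- function(pa, mu) {
  if (any(mu <= 0)) {
    stop("growth rate must be positive (lag-phase records excluded)",
         call. = FALSE)
  }
  if (is.matrix(pa)) {
    sweep(pa, 2, mu, "/")
  } else {
    pa / mu
  }
}

# resolve an input that may already be an object or a path
resolve_input <- function(x, reader, cls) {
  if (is.null(x) || inherits(x, cls)) return(x)
  reader(x)
}

#' Run the full analysis pipeline
#'
#' Executes quantification (optional) -> matrix assembly and normalization ->
#' global/specific decomposition -> metabolite screening and pair scan ->
#' transcription-factor mapping (optional) -> leave-one-condition-out
#' cross-validation, and collects a machine-readable summary. Stages whose
#' inputs are absent are skipped with a notice (e.g. without a metabolome the
#' pipeline stops after the decomposition).
#'
#' @param config list with entries (all optional unless noted):
#'   `plates` + `metadata` (plate CSV paths) or `records` (steady-state
#'   record data frame) or `activity` (an [activity_table()], required in one
#'   of the three forms); `metabolome` (a [metabolite_table()]);
#'   `network` (a [regulatory_network()]); `reported` (reported-interaction
#'   data frame for [recovery_quadrants()]); parameters `smoothing_window`
#'   (3), `threshold_sd` (3), `window_policy`, `cutoff_r` (0.75),
#'   `cluster_cutoff` (0.225), `p_cutoff` (0.1), `delta_aic` (10);
#'   `outdir` to write CSV/JSON outputs.
#' @return List of stage results plus `summary` (named numerics: variance
#'   explained by SV1, fraction of promoters explained by a single
#'   metabolite, LOOCV R-squared, sector fractions, ...).
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  p <- utils::modifyList(list(
    smoothing_window = 3L, threshold_sd = 3, window_policy = list(),
    cutoff_r = 0.75, cluster_cutoff = 0.225, p_cutoff = 0.1, delta_aic = 10,
    outdir = NULL), config)
  out <- list()
  summary <- list()

  # quantification
  activity <- p$activity
  if (is.null(activity) && !is.null(p$records)) {
    activity <- stage("assemble", assemble(p$records))
  }
  if (is.null(activity) && !is.null(p$plates)) {
    activity <- stage("quantify", {
      tc <- read_plate_table(p$plates, p$metadata)
      tc <- preprocess(tc, p$smoothing_window)
      ss <- steady_state(differentiate(tc), p$window_policy)
      filt <- filter_inactive(ss, p$threshold_sd)
      out$filter <- filt
      summary$n_promoters_discarded <-
        length(unique(filt$discarded$promoter_id))
      assemble(filt$active)
    })
  }
  if (is.null(activity)) stop("no activity input supplied", call. = FALSE)
  out$activity <- activity
  summary$n_promoters <- nrow(activity$pa)
  summary$n_conditions <- ncol(activity$pa)

  out$clusters <- stage("cluster", cluster_promoters(activity, p$cluster_cutoff))
  summary$n_clusters <- length(unique(out$clusters))

  norm <- stage("normalize", log_zscore(activity))
  d <- stage("decompose", decompose(norm))
  out$norm <- norm
  out$decomposition <- d
  out$growth_fit <- stage("growth_poly", fit_growth_poly(d))
  summary$variance_explained_k1 <- variance_explained(d, 1)
  summary$sv1_growth_cor <- stats::cor(d$scores, d$growth_rates)
  fit_r <- suppressWarnings(promoter_fit_r(d))
  out$promoter_fit_r <- fit_r
  summary$frac_promoters_global_r075 <- mean(fit_r >= 0.75, na.rm = TRUE)

  if (is.null(p$metabolome)) {
    message("no metabolome supplied; skipping metabolite inference, ",
            "TF mapping and cross-validation")
    out$summary <- summary
    return(out)
  }

  M <- p$metabolome
  S <- specific_component(d)
  scr <- stage("screen", screen_all(S, M, p$cutoff_r))
  out$screen <- scr
  summary$frac_promoters_single_metabolite <- mean(scr$best$passed_cutoff)

  # pair scan for every promoter with a usable best single fit
  pair_better <- logical(nrow(scr$best))
  pair_rows <- list()
  for (i in seq_len(nrow(scr$best))) {
    b <- as.list(scr$best[i, ])
    ps <- stage("pair_scan",
                pair_scan(S[b$promoter_id, ], M, b, p$delta_aic))
    if (nrow(ps) && any(ps$better)) {
      pair_better[i] <- TRUE
      pair_rows[[length(pair_rows) + 1L]] <-
        cbind(promoter_id = b$promoter_id, ps[which.min(ps$aic), ])
    }
  }
  out$pairs_better <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  summary$frac_promoters_pair_better <- mean(pair_better)

  # accepted interactions: best single where the cutoff is passed, upgraded
  # to the best pair where decisively better
  acc <- scr$best[scr$best$passed_cutoff, , drop = FALSE]
  interactions <- data.frame(promoter_id = acc$promoter_id,
                             metabolite_1 = acc$metabolite_id,
                             metabolite_2 = NA_character_,
                             stringsAsFactors = FALSE)
  if (!is.null(out$pairs_better)) {
    for (i in seq_len(nrow(out$pairs_better))) {
      pb <- out$pairs_better[i, ]
      hit <- interactions$promoter_id == pb$promoter_id
      if (any(hit)) {
        interactions$metabolite_1[hit] <- pb$metabolite_1
        interactions$metabolite_2[hit] <- pb$metabolite_2
      }
    }
  }
  out$interactions <- interactions

  if (!is.null(p$network)) {
    net <- p$network
    tab <- interactions
    enr <- list()
    for (met in unique(tab$metabolite_1)) {
      targets <- tab$promoter_id[tab$metabolite_1 == met]
      if (length(intersect(targets, net$universe)) > 2L) {
        enr[[met]] <- stage("tf_map",
                            map_metabolite_to_tf(targets, net, p$p_cutoff))
      }
    }
    out$enrichment <- enr
    if (!is.null(p$reported)) {
      out$quadrants <- stage("quadrants",
                             recovery_quadrants(p$reported, S, norm$X, M,
                                                p$cutoff_r))
      summary <- c(summary, as.list(stats::setNames(
        out$quadrants$fractions,
        paste0("frac_reported_", names(out$quadrants$fractions)))))
    }
  } else {
    message("no regulatory network supplied; skipping TF mapping")
  }

  cv <- stage("loocv", loocv_full_model(norm, d, M, interactions))
  out$loocv <- cv
  summary$loocv_r2 <- cv$overall_r2
  cv0 <- stage("loocv_global_only",
               loocv_full_model(norm, d, M, interactions[0, , drop = FALSE]))
  summary$loocv_r2_global_only <- cv0$overall_r2

  out$summary <- summary
  if (!is.null(p$outdir)) {
    if (!dir.exists(p$outdir)) dir.create(p$outdir, recursive = TRUE)
    write_decomposition_csv(d, p$outdir)
    utils::write.csv(scr$fits, file.path(p$outdir, "metabolite_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(interactions, file.path(p$outdir, "interactions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(p$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
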