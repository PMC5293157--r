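#' Simulation settings for synthetic promoter-activity studies
#'
#' Builds the configuration used by [generate_truth()]. Defaults emulate a
#' steady-state reporter study of bacterial central metabolism: 26 growth
#' conditions spanning growth rates 0.1--1.5/h, 64 active promoters whose
#' log-activity is a shared growth-linked signal plus sparse metabolite-driven
#' inputs, and 47 metabolites organised in strongly cross-correlated blocks.
#'
#' @param n_conditions number of growth conditions.
#' @param n_promoters number of (active) promoters.
#' @param n_metabolites number of measured metabolites.
#' @param growth_range range of steady-state growth rates (1/h); rates are
#'   evenly spaced over this range.
#' @param global_poly coefficients `c(c0, c1, c2)` of the quadratic global
#'   score `g(mu) = c0 + c1*mu + c2*mu^2` (dimensionless, ln-activity units).
#'   The default rises monotonically over the growth range but saturates, so
#'   that reporter concentration (activity divided by growth rate) declines
#'   with growth rate for every promoter, as observed for constitutively
#'   expressed proteins.
#' @param loading_range range of per-promoter loadings on the global score.
#' @param baseline_range range of per-promoter baseline ln-activities
#'   (ln fluorescence units/h).
#' @param n_coupled number of promoters receiving a specific metabolite input.
#' @param n_regulatory number of distinct regulatory metabolites among which
#'   the coupled promoters are distributed (each coupled promoter senses
#'   exactly one metabolite).
#' @param coupling_range range of absolute coupling slopes (ln-activity units
#'   per ln-concentration unit); signs are random.
#' @param coupling_metabolites optional explicit metabolite indices to use as
#'   regulatory metabolites (overrides `n_regulatory`).
#' @param n_blocks,block_size number and size of cross-correlated metabolite
#'   blocks; remaining metabolites are mutually independent.
#' @param block_cor target within-block pairwise Pearson correlation.
#' @param noise_sd_ln standard deviation of i.i.d. Gaussian ln-activity noise.
#'   The default 0.15 corresponds to the 10--20% day-to-day variation typical
#'   of plate-reader promoter-activity measurements.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [generate_truth()]
#' @export
sim_config <- function(n_conditions = 26L,
                       n_promoters = 64L,
                       n_metabolites = 47L,
                       growth_range = c(0.1, 1.5),
                       global_poly = c(-1, 1.8, -0.6),
                       loading_range = c(0.6, 1.4),
                       baseline_range = log(c(50, 500)),
                       n_coupled = 10L,
                       n_regulatory = 3L,
                       coupling_range = c(0.3, 0.8),
                       coupling_metabolites = NULL,
                       n_blocks = 5L,
                       block_size = 6L,
                       block_cor = 0.83,
                       noise_sd_ln = 0.15) {
  cfg <- list(
    n_conditions = as.integer(n_conditions),
    n_promoters = as.integer(n_promoters),
    n_metabolites = as.integer(n_metabolites),
    growth_range = growth_range,
    global_poly = global_poly,
    loading_range = loading_range,
    baseline_range = baseline_range,
    n_coupled = as.integer(n_coupled),
    n_regulatory = as.integer(n_regulatory),
    coupling_range = coupling_range,
    coupling_metabolites = coupling_metabolites,
    n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size),
    block_cor = block_cor,
    noise_sd_ln = noise_sd_ln
  )
  if (cfg$n_conditions < 4L) {
    stop("configuration error: need at least 4 conditions", call. = FALSE)
  }
  if (cfg$n_promoters < 1L || cfg$n_metabolites < 1L) {
    stop("configuration error: non-positive dimensions", call. = FALSE)
  }
  if (any(growth_range <= 0) || diff(growth_range) < 0) {
    stop("configuration error: growth range must be positive", call. = FALSE)
  }
  if (cfg$n_blocks * cfg$block_size > cfg$n_metabolites) {
    stop("block structure exceeds number of metabolites", call. = FALSE)
  }
  if (block_cor < 0 || block_cor > 1) {
    stop("block_cor must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_coupled > cfg$n_promoters) {
    stop("more coupled promoters than promoters", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate ground-truth parameters for a synthetic study
#'
#' Draws all promoter-, condition- and metabolite-level parameters for one
#' synthetic study: evenly spaced growth rates, a quadratic growth->global
#' score map, per-promoter loadings and baselines, a sparse promoter x
#' metabolite coupling-slope matrix, the metabolite block structure, and a
#' metabolite -> transcription factor -> target-promoter map (each regulatory
#' metabolite acts through one transcription factor whose targets are exactly
#' the promoters coupled to it).
#'
#' @param config a [sim_config()] object (or `NULL` for defaults).
#' @param seed integer seed; the same seed reproduces the identical truth.
#'
#' @return A list of class `"synthetic_truth"` with elements
#'   `growth_rates`, `global_score_fn`, `promoter_loadings`, `baselines`,
#'   `coupling_slopes` (promoters x metabolites, mostly exact zeros),
#'   `blocks` (list of metabolite index vectors), `tf_map`, `config`, `seed`,
#'   and id vectors `promoters`, `conditions`, `metabolites`.
#' @examples
#' tr <- generate_truth(seed = 1)
#' dim(tr$coupling_slopes)
#' @export
generate_truth <- function(config = sim_config(), seed = 1L) {
  if (is.null(config)) config <- sim_config()
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  nc <- config$n_conditions
  np <- config$n_promoters
  nm <- config$n_metabolites

  promoters <- sprintf("P%03d", seq_len(np))
  conditions <- sprintf("C%02d", seq_len(nc))
  metabolites <- sprintf("M%02d", seq_len(nm))

  growth_rates <- seq(config$growth_range[1], config$growth_range[2],
                      length.out = nc)
  names(growth_rates) <- conditions

  cf <- config$global_poly
  global_score_fn <- function(mu) cf[1] + cf[2] * mu + cf[3] * mu^2

  loadings <- stats::runif(np, config$loading_range[1], config$loading_range[2])
  names(loadings) <- promoters
  baselines <- stats::runif(np, config$baseline_range[1], config$baseline_range[2])
  names(baselines) <- promoters

  blocks <- list()
  if (config$n_blocks > 0L && config$block_size > 1L) {
    idx <- 1L
    for (b in seq_len(config$n_blocks)) {
      blocks[[b]] <- idx:(idx + config$block_size - 1L)
      idx <- idx + config$block_size
    }
  }

  coupling <- matrix(0, np, nm, dimnames = list(promoters, metabolites))
  tf_map <- NULL
  if (config$n_coupled > 0L) {
    reg_mets <- config$coupling_metabolites
    if (is.null(reg_mets)) {
      reg_mets <- sort(sample.int(nm, min(config$n_regulatory, nm)))
    }
    coupled <- sort(sample.int(np, config$n_coupled))
    assigned <- reg_mets[1L + (seq_along(coupled) - 1L) %% length(reg_mets)]
    slope <- stats::runif(length(coupled), config$coupling_range[1],
                          config$coupling_range[2]) *
      sample(c(-1, 1), length(coupled), replace = TRUE)
    coupling[cbind(coupled, assigned)] <- slope
    tf_map <- data.frame(
      metabolite_id = metabolites[assigned],
      tf_id = sprintf("TF_%s", metabolites[assigned]),
      promoter_id = promoters[coupled],
      sign = ifelse(slope > 0, "activation", "repression"),
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    promoters = promoters, conditions = conditions, metabolites = metabolites,
    growth_rates = growth_rates,
    global_score_fn = global_score_fn,
    promoter_loadings = loadings,
    baselines = baselines,
    coupling_slopes = coupling,
    blocks = blocks,
    tf_map = tf_map,
    noise_sd_ln = config$noise_sd_ln,
    config = config,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic study truth\n")
  cat(sprintf("  %d promoters x %d conditions, %d metabolites\n",
              length(x$promoters), length(x$conditions), length(x$metabolites)))
  cat(sprintf("  growth rates %.2f-%.2f/h, ln-noise sd %.3f\n",
              min(x$growth_rates), max(x$growth_rates), x$noise_sd_ln))
  cat(sprintf("  %d planted promoter-metabolite couplings on %d metabolite(s)\n",
              sum(x$coupling_slopes != 0),
              sum(colSums(x$coupling_slopes != 0) > 0)))
  invisible(x)
}

#' Simulate a ln-scale metabolome matrix
#'
#' Metabolites within a declared block share a latent factor:
#' `m_k = sqrt(rho) * z_block + sqrt(1 - rho) * eps_k` with standard normal
#' latents, so the population within-block pairwise correlation equals the
#' configured target `rho`; metabolites outside blocks are independent.
#' Rows are centred, matching the convention for absolutely quantified
#' metabolites (ln concentration normalised by its mean across conditions).
#'
#' @param truth a [generate_truth()] object.
#' @param seed integer seed (defaults to `truth$seed + 1`).
#' @return A [metabolite_table()] with all cells unmasked, mode `"absolute"`.
#' @export
simulate_metabolome <- function(truth, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  nm <- length(truth$metabolites)
  nc <- length(truth$conditions)
  rho <- truth$config$block_cor
  M <- matrix(stats::rnorm(nm * nc), nm, nc,
              dimnames = list(truth$metabolites, truth$conditions))
  for (blk in truth$blocks) {
    z <- stats::rnorm(nc)
    for (k in blk) {
      M[k, ] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(nc)
    }
  }
  M <- M - rowMeans(M)
  metabolite_table(M, mode = "absolute")
}

#' Simulate the steady-state activity matrix from a truth object
#'
#' Forward model on the natural-log scale:
#' `ln pa_ij = baseline_i + loading_i * g(mu_j) + sum_k slope_ik * m_kj + eps_ij`
#' with `eps ~ N(0, noise_sd_ln^2)`. The returned activities are exponentiated
#' (linear scale, strictly positive).
#'
#' @param truth a [generate_truth()] object.
#' @param metabolome a [metabolite_table()]; dimensions must match the truth.
#' @param seed integer seed (defaults to `truth$seed + 2`).
#' @return An [activity_table()].
#' @export
simulate_activity_matrix <- function(truth, metabolome,
                                     seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(metabolome, "metabolite_table"))
  if (!identical(dim(metabolome$M),
                 c(length(truth$metabolites), length(truth$conditions)))) {
    stop("dimension mismatch between truth and metabolome", call. = FALSE)
  }
  set.seed(seed)
  g <- truth$global_score_fn(truth$growth_rates)
  ln_pa <- truth$baselines +
    outer(truth$promoter_loadings, g) +
    truth$coupling_slopes %*% metabolome$M
  if (truth$noise_sd_ln > 0) {
    ln_pa <- ln_pa + matrix(stats::rnorm(length(ln_pa), 0, truth$noise_sd_ln),
                            nrow(ln_pa), ncol(ln_pa))
  }
  dimnames(ln_pa) <- list(truth$promoters, truth$conditions)
  activity_table(exp(ln_pa), truth$growth_rates)
}

#' Simulate plate-reader OD/GFP time courses
#'
#' Forward-simulates exponential growth and reporter accumulation for every
#' (promoter, condition) well plus, per condition, a promoter-less control
#' well (background fluorescence production only) and a cell-free blank well.
#' OD follows `OD(t) = OD0 * exp(mu t)`; accumulated fluorescence uses the
#' exact integral `GFP(t) = GFP0 + (pa + bg) * OD0 * (exp(mu t) - 1)/mu`
#' (linear limit `(pa + bg) * OD0 * t` at `mu = 0`). Constant blank offsets
#' are added to both channels, and optional i.i.d. Gaussian measurement noise.
#'
#' @param truth a [generate_truth()] object (supplies growth rates and ids).
#' @param activities an [activity_table()] of steady-state activities to drive
#'   the wells (e.g. from [simulate_activity_matrix()]).
#' @param sampling list of settings: `interval` (h, default 0.1), `od0`
#'   (inoculum OD, default 0.01), `od_max` (OD at which sampling stops,
#'   default 0.6), `gfp0` (default 0), `od_blank`, `gfp_blank` (additive
#'   offsets, defaults 0.04 and 30), `background_activity` (apparent activity
#'   of the promoter-less plasmid, default 5), `noise_od`, `noise_gfp`
#'   (measurement noise sd, defaults 0), `duration` (h; overrides `od_max`).
#' @param replicates wells per (promoter, condition), default 1.
#' @param seed integer seed (defaults to `truth$seed + 3`).
#' @return A [timecourse_set()].
#' @export
simulate_plate_timecourses <- function(truth, activities,
                                       sampling = list(), replicates = 1L,
                                       seed = truth$seed + 3L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(activities, "activity_table"))
  s <- utils::modifyList(list(
    interval = 0.1, od0 = 0.01, od_max = 0.6, gfp0 = 0,
    od_blank = 0.04, gfp_blank = 30, background_activity = 5,
    noise_od = 0, noise_gfp = 0, duration = NULL
  ), sampling)
  if (s$interval <= 0) stop("sampling interval must be positive", call. = FALSE)
  set.seed(seed)

  wells <- list(); series <- list()
  add_well <- function(id, promoter, condition, replicate, role,
                       pa, mu, duration) {
    time <- seq(0, duration, by = s$interval)
    if (role == "blank") {
      od_true <- rep(0, length(time)); gfp_true <- rep(0, length(time))
    } else {
      od_true <- s$od0 * exp(mu * time)
      rate <- pa + s$background_activity
      gfp_true <- if (abs(mu) < 1e-12) {
        s$gfp0 + rate * s$od0 * time
      } else {
        s$gfp0 + rate * s$od0 * (exp(mu * time) - 1) / mu
      }
    }
    od <- od_true + s$od_blank
    gfp <- gfp_true + s$gfp_blank
    if (s$noise_od > 0) od <- od + stats::rnorm(length(od), 0, s$noise_od)
    if (s$noise_gfp > 0) gfp <- gfp + stats::rnorm(length(gfp), 0, s$noise_gfp)
    wells[[length(wells) + 1L]] <<- data.frame(
      well_id = id, promoter_id = promoter, condition_id = condition,
      replicate = replicate, role = role, stringsAsFactors = FALSE)
    series[[id]] <<- list(time = time, od = od, gfp = gfp)
  }

  for (j in seq_along(truth$conditions)) {
    cond <- truth$conditions[j]
    mu <- truth$growth_rates[j]
    duration <- if (!is.null(s$duration)) s$duration else
      log(s$od_max / s$od0) / max(mu, 1e-12)
    for (i in seq_along(truth$promoters)) {
      for (r in seq_len(replicates)) {
        add_well(sprintf("%s_%s_r%d", cond, truth$promoters[i], r),
                 truth$promoters[i], cond, r, "reporter",
                 activities$pa[i, j], mu, duration)
      }
    }
    add_well(sprintf("%s_ctrl", cond), "p139", cond, 1L,
             "promoterless_control", 0, mu, duration)
    add_well(sprintf("%s_blank", cond), NA_character_, cond, 1L,
             "blank", 0, mu, duration)
  }
  timecourse_set(do.call(rbind, wells), series)
}

#' Write the files of a synthetic study to disk
#'
#' Emits the CSV/TSV dialects consumed by the analysis entry points (plate
#' time courses plus well metadata, activity matrix plus condition table,
#' metabolome, regulatory-network edge list) and a `truth.json` with the
#' ground-truth parameters for later assertions.
#'
#' @param truth,metabolome,activities,timecourses the simulated objects;
#'   `timecourses` may be `NULL` to skip the (large) plate files.
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_study <- function(truth, metabolome, activities,
                                  timecourses = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    activity = file.path(dir, "activity.csv"),
    conditions = file.path(dir, "conditions.csv"),
    metabolome = file.path(dir, "metabolome.csv"),
    network = file.path(dir, "network.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_activity_csv(activities, paths["activity"], paths["conditions"])
  write_metabolome_csv(metabolome, paths["metabolome"])
  if (!is.null(truth$tf_map)) {
    net <- unique(truth$tf_map[, c("tf_id", "promoter_id", "sign")])
    names(net) <- c("tf", "target", "effect")
    utils::write.table(net, paths["network"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tr <- truth
  tr$global_score_fn <- NULL
  tr$config$coupling_metabolites <- as.list(tr$config$coupling_metabolites)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  if (!is.null(timecourses)) {
    pp <- write_plate_csv(timecourses, dir)
    paths <- c(paths, pp)
  }
  invisible(paths)
}
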