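#' Container for per-well plate-reader time courses
#'
#' @param wells data frame with columns `well_id`, `promoter_id`,
#'   `condition_id`, `replicate`, `role` (one of `"reporter"`,
#'   `"promoterless_control"`, `"blank"`).
#' @param series named list (by `well_id`) of lists with numeric vectors
#'   `time` (hours, strictly increasing), `od`, `gfp`.
#' @return An object of class `"timecourse_set"`.
#' @export
timecourse_set <- function(wells, series) {
  stopifnot(is.data.frame(wells),
            all(c("well_id", "promoter_id", "condition_id",
                  "replicate", "role") %in% names(wells)))
  bad_role <- setdiff(wells$role, c("reporter", "promoterless_control", "blank"))
  if (length(bad_role)) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(wells$well_id)) stop("duplicate well ids", call. = FALSE)
  missing <- setdiff(wells$well_id, names(series))
  if (length(missing)) {
    stop("no series for well(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (id in wells$well_id) {
    w <- series[[id]]
    if (length(w$time) < 5L) {
      stop("well ", id, ": fewer than 5 time points", call. = FALSE)
    }
    if (any(diff(w$time) <= 0)) {
      stop("well ", id, ": time not strictly increasing", call. = FALSE)
    }
    if (length(w$od) != length(w$time) || length(w$gfp) != length(w$time)) {
      stop("well ", id, ": od/gfp length mismatch", call. = FALSE)
    }
  }
  structure(list(wells = wells, series = series[wells$well_id]),
            class = "timecourse_set")
}

#' @export
print.timecourse_set <- function(x, ...) {
  cat(sprintf("Time-course set: %d wells (%d reporter, %d control, %d blank)\n",
              nrow(x$wells), sum(x$wells$role == "reporter"),
              sum(x$wells$role == "promoterless_control"),
              sum(x$wells$role == "blank")))
  invisible(x)
}

#' Read plate-reader CSV files and well metadata
#'
#' Each plate file holds a `time` column followed by one `<well>_od` and one
#' `<well>_gfp` column per well; the metadata file maps wells to promoter,
#' condition, replicate and role.
#'
#' @param paths character vector of plate CSV paths.
#' @param metadata_path CSV with columns `well_id`, `promoter_id`,
#'   `condition_id`, `replicate`, `role`.
#' @param time_units `"hours"` (default) or `"minutes"` (converted to hours).
#' @return A [timecourse_set()].
#' @export
read_plate_table <- function(paths, metadata_path, time_units = c("hours", "minutes")) {
  time_units <- match.arg(time_units)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("well_id", "promoter_id", "condition_id", "replicate", "role")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  series <- list()
  for (p in paths) {
    tab <- utils::read.csv(p, check.names = FALSE)
    if (!"time" %in% names(tab)) {
      stop("plate file ", p, " has no time column", call. = FALSE)
    }
    time <- tab$time
    if (time_units == "minutes") time <- time / 60
    if (any(diff(time) <= 0)) {
      stop("plate file ", p, ": time not strictly increasing", call. = FALSE)
    }
    od_cols <- grep("_od$", names(tab), value = TRUE)
    for (oc in od_cols) {
      well <- sub("_od$", "", oc)
      gc <- paste0(well, "_gfp")
      if (!gc %in% names(tab)) {
        stop("plate file ", p, ": well ", well, " has OD but no GFP column",
             call. = FALSE)
      }
      series[[well]] <- list(time = time, od = tab[[oc]], gfp = tab[[gc]])
    }
  }
  unmatched <- setdiff(names(series), meta$well_id)
  if (length(unmatched)) {
    stop("well(s) without metadata: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[meta$well_id %in% names(series), , drop = FALSE]
  timecourse_set(meta, series)
}

#' Write a timecourse_set as per-condition plate CSVs plus metadata
#'
#' @param tc a [timecourse_set()].
#' @param dir output directory.
#' @return Invisibly, named vector of written paths (one plate file per
#'   condition plus `well_metadata.csv`).
#' @export
write_plate_csv <- function(tc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(metadata = file.path(dir, "well_metadata.csv"))
  utils::write.csv(tc$wells, paths["metadata"], row.names = FALSE)
  for (cond in unique(tc$wells$condition_id)) {
    ids <- tc$wells$well_id[tc$wells$condition_id == cond]
    tab <- data.frame(time = tc$series[[ids[1]]]$time)
    for (id in ids) {
      tab[[paste0(id, "_od")]] <- tc$series[[id]]$od
      tab[[paste0(id, "_gfp")]] <- tc$series[[id]]$gfp
    }
    p <- file.path(dir, sprintf("plate_%s.csv", cond))
    utils::write.csv(tab, p, row.names = FALSE)
    paths[paste0("plate_", cond)] <- p
  }
  invisible(paths)
}

# Centered moving average with truncated windows at the series edges.
moving_average <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("smoothing window must be odd and >= 1", call. = FALSE)
  }
  n <- length(x)
  if (window > n) stop("smoothing window larger than series", call. = FALSE)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Blank-correct and smooth plate time courses
#'
#' Subtracts the blank OD and GFP signals (measured before/without cell
#' addition) and smooths both channels with a centred moving average whose
#' edge windows are truncated rather than padded.
#'
#' @param tc a [timecourse_set()].
#' @param smoothing_window odd window size, default 3.
#' @param blank either `"wells"` (default: per-condition mean of blank-role
#'   wells, falling back to the global blank-well mean) or a numeric
#'   `c(od = ..., gfp = ...)` applied to every well.
#' @return A new [timecourse_set()] with corrected, smoothed series.
#' @export
preprocess <- function(tc, smoothing_window = 3L, blank = "wells") {
  stopifnot(inherits(tc, "timecourse_set"))
  is_blank <- tc$wells$role == "blank"
  if (is.numeric(blank)) {
    blank_of <- function(cond) blank[c("od", "gfp")]
  } else {
    if (!any(is_blank)) {
      stop("no blank wells and no numeric blank estimate supplied",
           call. = FALSE)
    }
    blank_ids <- tc$wells$well_id[is_blank]
    blank_cond <- tc$wells$condition_id[is_blank]
    global <- c(
      od = mean(unlist(lapply(tc$series[blank_ids], `[[`, "od"))),
      gfp = mean(unlist(lapply(tc$series[blank_ids], `[[`, "gfp"))))
    blank_of <- function(cond) {
      ids <- blank_ids[blank_cond == cond]
      if (!length(ids)) return(global)
      c(od = mean(unlist(lapply(tc$series[ids], `[[`, "od"))),
        gfp = mean(unlist(lapply(tc$series[ids], `[[`, "gfp"))))
    }
  }
  series <- tc$series
  for (i in seq_len(nrow(tc$wells))) {
    id <- tc$wells$well_id[i]
    b <- blank_of(tc$wells$condition_id[i])
    series[[id]]$od <- moving_average(series[[id]]$od - b[["od"]],
                                      smoothing_window)
    series[[id]]$gfp <- moving_average(series[[id]]$gfp - b[["gfp"]],
                                       smoothing_window)
  }
  timecourse_set(tc$wells, series)
}

#' Two-point finite-difference growth and activity series
#'
#' For each non-blank well computes, at interval midpoints,
#' `growth(t) = d ln(OD)/dt` and `activity(t) = dGFP/(dt * OD)` where the OD
#' in the denominator is the mean of the two flanking measurements. The
#' ln-difference makes the growth series exact for exponential OD regardless
#' of the sampling interval. Midpoints with non-positive OD are dropped with
#' a warning.
#'
#' @param tc a preprocessed [timecourse_set()].
#' @return An object of class `"timecourse_derivatives"`: the well table plus
#'   a per-well list of `time` (midpoints), `growth`, `activity`, `od_mid`.
#' @export
differentiate <- function(tc) {
  stopifnot(inherits(tc, "timecourse_set"))
  keep <- tc$wells$role != "blank"
  wells <- tc$wells[keep, , drop = FALSE]
  deriv <- list()
  dropped <- character()
  for (id in wells$well_id) {
    w <- tc$series[[id]]
    n <- length(w$time)
    dt <- diff(w$time)
    od_mid <- (w$od[-1] + w$od[-n]) / 2
    ok <- w$od[-1] > 0 & w$od[-n] > 0
    if (any(!ok)) dropped <- c(dropped, id)
    growth <- ifelse(ok, c(diff(log(pmax(w$od, .Machine$double.xmin)))) / dt, NA_real_)
    activity <- ifelse(ok, diff(w$gfp) / (dt * od_mid), NA_real_)
    tm <- (w$time[-1] + w$time[-n]) / 2
    use <- ok
    deriv[[id]] <- list(time = tm[use], growth = growth[use],
                        activity = activity[use], od_mid = od_mid[use])
  }
  if (length(dropped)) {
    warning("non-positive OD points dropped in well(s): ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  }
  structure(list(wells = wells, deriv = deriv),
            class = "timecourse_derivatives")
}

# Longest contiguous run of TRUE of length >= min_points; returns index range
# or NULL.
longest_run <- function(ok, min_points) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_points)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  c(starts[best], ends[best])
}

# Exponential-phase window: midpoints whose OD lies in od_range and whose
# growth rate stays within growth_tol of its running median.
select_window <- function(d, policy) {
  k <- min(length(d$growth), policy$runmed_k)
  if (k %% 2L == 0L) k <- k - 1L
  med <- if (k >= 3) stats::runmed(d$growth, k) else d$growth
  ok <- d$od_mid >= policy$od_range[1] & d$od_mid <= policy$od_range[2] &
    abs(d$growth - med) <= policy$growth_tol * pmax(abs(med), 1e-12) &
    is.finite(d$growth) & is.finite(d$activity)
  longest_run(ok, policy$min_points)
}

#' Steady-state promoter activity and growth rate per well
#'
#' Averages the finite-difference growth and activity series over an
#' automatically selected exponential-phase window (the longest contiguous
#' run of at least `min_points` midpoints whose OD lies inside `od_range` and
#' whose growth rate stays within `growth_tol` of its running median), then
#' subtracts the apparent activity of the condition's promoter-less control
#' (interpolated onto the reporter's midpoints) and averages replicates.
#'
#' @param derived a [differentiate()] result.
#' @param window_policy list with `min_points` (default 5), `od_range`
#'   (default `c(0.05, 0.5)`), `growth_tol` (default 0.15, relative),
#'   `runmed_k` (running-median width, default 31).
#' @return A list of class `"steady_state_result"`:
#'   `records` — data frame (`promoter_id`, `condition_id`, `pa`
#'   [background-subtracted], `pa_raw`, `mu`, `window_start`, `window_end`,
#'   `n_points`, `n_replicates`); `control` — per-condition apparent activity
#'   of the promoter-less control.
#' @export
steady_state <- function(derived, window_policy = list()) {
  stopifnot(inherits(derived, "timecourse_derivatives"))
  policy <- utils::modifyList(list(min_points = 5L, od_range = c(0.05, 0.5),
                                   growth_tol = 0.15, runmed_k = 31L),
                              window_policy)
  wells <- derived$wells
  failed <- character()

  # control apparent activity, per condition
  ctrl <- list()
  for (cond in unique(wells$condition_id)) {
    ids <- wells$well_id[wells$condition_id == cond &
                           wells$role == "promoterless_control"]
    if (!length(ids)) {
      stop("no promoter-less control well for condition ", cond, call. = FALSE)
    }
    d <- derived$deriv[[ids[1]]]
    win <- select_window(d, policy)
    if (is.null(win)) { failed <- c(failed, ids[1]); next }
    idx <- win[1]:win[2]
    ctrl[[cond]] <- list(
      time = d$time, activity = d$activity,
      level = mean(d$activity[idx]), mu = mean(d$growth[idx]))
  }

  rows <- list()
  rep_wells <- wells[wells$role == "reporter", , drop = FALSE]
  for (i in seq_len(nrow(rep_wells))) {
    id <- rep_wells$well_id[i]
    cond <- rep_wells$condition_id[i]
    if (is.null(ctrl[[cond]])) next
    d <- derived$deriv[[id]]
    win <- select_window(d, policy)
    if (is.null(win)) { failed <- c(failed, id); next }
    idx <- win[1]:win[2]
    bg <- stats::approx(ctrl[[cond]]$time, ctrl[[cond]]$activity,
                        xout = d$time[idx], rule = 2)$y
    rows[[length(rows) + 1L]] <- data.frame(
      promoter_id = rep_wells$promoter_id[i], condition_id = cond,
      pa = mean(d$activity[idx] - bg),
      pa_raw = mean(d$activity[idx]),
      mu = mean(d$growth[idx]),
      window_start = d$time[win[1]], window_end = d$time[win[2]],
      n_points = length(idx), stringsAsFactors = FALSE)
  }
  if (length(failed)) {
    stop("no exponential-phase window satisfying the policy for well(s): ",
         paste(unique(failed), collapse = ", "), call. = FALSE)
  }
  per_well <- do.call(rbind, rows)
  # replicate averaging after per-well computation
  key <- interaction(per_well$promoter_id, per_well$condition_id, drop = TRUE)
  agg <- lapply(split(per_well, key), function(g) {
    data.frame(promoter_id = g$promoter_id[1], condition_id = g$condition_id[1],
               pa = mean(g$pa), pa_raw = mean(g$pa_raw), mu = mean(g$mu),
               window_start = min(g$window_start),
               window_end = max(g$window_end),
               n_points = sum(g$n_points), n_replicates = nrow(g),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, agg)
  rownames(records) <- NULL
  control <- data.frame(
    condition_id = names(ctrl),
    activity = vapply(ctrl, `[[`, numeric(1), "level"),
    mu = vapply(ctrl, `[[`, numeric(1), "mu"),
    stringsAsFactors = FALSE)
  rownames(control) <- NULL
  structure(list(records = records, control = control, policy = policy),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Steady-state records: %d (promoter, condition) pairs, %d conditions\n",
              nrow(x$records), nrow(x$control)))
  invisible(x)
}

#' Discard promoters inactive in every condition
#'
#' The detection threshold is the mean plus `threshold_sd` standard deviations
#' of the promoter-less control's apparent activity across conditions; a
#' promoter is kept iff its activity before background subtraction exceeds
#' this threshold in at least one condition.
#'
#' @param ss a [steady_state()] result, or a records data frame with columns
#'   `promoter_id` and `pa_raw` plus a `control` argument.
#' @param threshold_sd multiplier on the control activity sd, default 3.
#' @param control optional per-condition control table (needed if `ss` is a
#'   plain data frame).
#' @param threshold optional explicit detection threshold overriding the
#'   control-derived one.
#' @return list with `active` and `discarded` record data frames, and the
#'   `threshold` used.
#' @export
filter_inactive <- function(ss, threshold_sd = 3, control = NULL,
                            threshold = NULL) {
  if (inherits(ss, "steady_state_result")) {
    records <- ss$records
    control <- ss$control
  } else {
    records <- ss
    if (is.null(control) && is.null(threshold)) {
      stop("control activities required", call. = FALSE)
    }
  }
  thr <- if (!is.null(threshold)) threshold else {
    mean(control$activity) +
      threshold_sd * (if (nrow(control) > 1) stats::sd(control$activity) else 0)
  }
  above <- tapply(records$pa_raw > thr, records$promoter_id, any)
  keep <- names(above)[above]
  list(active = records[records$promoter_id %in% keep, , drop = FALSE],
       discarded = records[!records$promoter_id %in% keep, , drop = FALSE],
       threshold = thr)
}
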