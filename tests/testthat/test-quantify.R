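make_tc <- function(series, roles = NULL) {
  ids <- names(series)
  wells <- data.frame(
    well_id = ids, promoter_id = sub("_.*", "", ids),
    condition_id = "C1", replicate = 1L,
    role = if (is.null(roles)) "reporter" else roles,
    stringsAsFactors = FALSE)
  timecourse_set(wells, series)
}

test_that("plate CSVs and metadata are read back faithfully", {
  tr <- tiny_constitutive_truth(n_conditions = 4, n_promoters = 2)
  act <- simulate_activity_matrix(tr, simulate_metabolome(tr))
  tc <- simulate_plate_timecourses(tr, act, sampling = list(duration = 2))
  dir <- withr::local_tempdir()
  paths <- write_plate_csv(tc, dir)
  tc2 <- read_plate_table(paths[grep("^plate_", names(paths))],
                          paths["metadata"])
  expect_setequal(tc2$wells$well_id, tc$wells$well_id)
  id <- tc$wells$well_id[1]
  expect_equal(tc2$series[[id]], tc$series[[id]], tolerance = 1e-9)

  # times recorded in minutes are converted to hours
  tab <- utils::read.csv(paths[grep("^plate_", names(paths))][1],
                         check.names = FALSE)
  tab$time <- tab$time * 60
  p_min <- file.path(dir, "minutes.csv")
  utils::write.csv(tab, p_min, row.names = FALSE)
  tc3 <- read_plate_table(p_min, paths["metadata"], time_units = "minutes")
  expect_equal(tc3$series[[id]]$time, tc$series[[id]]$time, tolerance = 1e-9)
})

test_that("wells without metadata are reported by name", {
  dir <- withr::local_tempdir()
  tab <- data.frame(time = 0:5, wellA_od = rep(0.1, 6), wellA_gfp = rep(1, 6),
                    wellB_od = rep(0.1, 6), wellB_gfp = rep(1, 6))
  pp <- file.path(dir, "plate.csv"); utils::write.csv(tab, pp, row.names = FALSE)
  meta <- data.frame(well_id = "wellA", promoter_id = "p1",
                     condition_id = "c1", replicate = 1, role = "reporter")
  pm <- file.path(dir, "meta.csv"); utils::write.csv(meta, pm, row.names = FALSE)
  expect_error(read_plate_table(pp, pm), "wellB")
})

test_that("moving average uses truncated edge windows", {
  expect_equal(promdecon:::moving_average(c(1, 2, 3, 4, 5), 3),
               c(1.5, 2, 3, 4, 4.5))
  expect_equal(promdecon:::moving_average(rep(7, 10), 5), rep(7, 10))
  expect_error(promdecon:::moving_average(1:3, 5), "larger than series")
  expect_error(promdecon:::moving_average(1:10, 4), "odd")
})

test_that("preprocess subtracts the blank and leaves constants unchanged", {
  s <- list(w1 = list(time = 0:5 / 2, od = c(0.15, 0.25, 0.15, 0.25, 0.15, 0.25),
                      gfp = rep(10, 6)))
  tc <- make_tc(s)
  out <- preprocess(tc, smoothing_window = 1, blank = c(od = 0.05, gfp = 10))
  expect_equal(out$series$w1$od, s$w1$od - 0.05)
  expect_equal(out$series$w1$gfp, rep(0, 6))
  # smoothing leaves a constant series unchanged
  out3 <- preprocess(tc, smoothing_window = 3, blank = c(od = 0, gfp = 0))
  expect_equal(out3$series$w1$gfp, rep(10, 6))
})

test_that("finite differences are exact for exponential OD and constant-OD GFP", {
  times <- seq(0, 5, by = 0.1)
  tc <- make_tc(list(
    w1 = list(time = times, od = 0.01 * exp(0.5 * times),
              gfp = rep(0, length(times))),
    w2 = list(time = times, od = rep(0.5, length(times)), gfp = 100 * times)))
  d <- differentiate(tc)
  expect_equal(d$deriv$w1$growth, rep(0.5, length(times) - 1), tolerance = 1e-10)
  expect_equal(d$deriv$w2$activity, rep(200, length(times) - 1),
               tolerance = 1e-10)
  # length n-1, at midpoints
  expect_length(d$deriv$w1$time, length(times) - 1)
  expect_equal(d$deriv$w1$time[1], 0.05)
})

test_that("activity recovery is within 1% at mid-exponential points", {
  times <- seq(0, 8, by = 0.1)  # 6-min sampling
  tc <- make_tc(list(w1 = make_well_series(pa = 50, mu = 1, times)))
  d <- differentiate(tc)
  mid <- d$deriv$w1$od_mid > 0.05 & d$deriv$w1$od_mid < 0.5
  expect_true(all(abs(d$deriv$w1$activity[mid] - 50) / 50 < 0.01))
})

test_that("steady state round-trips a noise-free simulated well", {
  times <- seq(0, 9, by = 0.1)
  tc <- make_tc(list(
    w1 = make_well_series(pa = 100, mu = 0.5, times, background = 5),
    ctrl = make_well_series(pa = 0, mu = 0.5, times, background = 5)),
    roles = c("reporter", "promoterless_control"))
  ss <- steady_state(differentiate(tc))
  expect_equal(ss$records$pa, 100, tolerance = 0.02)
  expect_equal(ss$records$mu, 0.5, tolerance = 0.01)
  expect_gte(ss$records$n_points, 3)
  expect_true(ss$records$window_start >= min(times) &&
                ss$records$window_end <= max(times))
})

test_that("a reporter identical to the control has activity near zero", {
  times <- seq(0, 9, by = 0.1)
  tc <- make_tc(list(
    w1 = make_well_series(pa = 0, mu = 0.5, times, background = 5),
    ctrl = make_well_series(pa = 0, mu = 0.5, times, background = 5)),
    roles = c("reporter", "promoterless_control"))
  ss <- steady_state(differentiate(tc))
  expect_lt(abs(ss$records$pa), 1e-8)
})

test_that("steady-state activity is invariant to a constant GFP offset", {
  times <- seq(0, 9, by = 0.1)
  w <- make_well_series(pa = 80, mu = 0.4, times, background = 5)
  w_off <- w; w_off$gfp <- w$gfp + 1234
  ctrl <- make_well_series(pa = 0, mu = 0.4, times, background = 5)
  ss1 <- steady_state(differentiate(make_tc(
    list(w1 = w, ctrl = ctrl), roles = c("reporter", "promoterless_control"))))
  ss2 <- steady_state(differentiate(make_tc(
    list(w1 = w_off, ctrl = ctrl), roles = c("reporter", "promoterless_control"))))
  expect_equal(ss1$records$pa, ss2$records$pa, tolerance = 1e-10)
})

test_that("an unsatisfiable window policy errors naming the well", {
  times <- seq(0, 9, by = 0.1)
  tc <- make_tc(list(
    w1 = make_well_series(pa = 100, mu = 0.5, times),
    ctrl = make_well_series(pa = 0, mu = 0.5, times)),
    roles = c("reporter", "promoterless_control"))
  expect_error(steady_state(differentiate(tc),
                            window_policy = list(min_points = 10000)),
               "w1|ctrl")
})

test_that("inactive-promoter filter is monotone in the threshold", {
  records <- data.frame(
    promoter_id = rep(c("a", "b", "c"), each = 2),
    condition_id = rep(c("x", "y"), 3),
    pa = c(100, 90, 4, 5, 0.1, 0.2),
    pa_raw = c(105, 95, 9, 10, 5.1, 5.2))
  control <- data.frame(condition_id = c("x", "y"), activity = c(5, 5.4))
  f3 <- filter_inactive(records, threshold_sd = 3, control = control)
  expect_setequal(unique(f3$active$promoter_id), c("a", "b"))
  expect_setequal(unique(f3$discarded$promoter_id), "c")
  for (k in c(0, 1, 5, 20)) {
    fk <- filter_inactive(records, threshold_sd = k, control = control)
    expect_true(all(unique(fk$active$promoter_id) %in%
                      unique(f3$active$promoter_id)) || k < 3)
    if (k > 3) {
      expect_true(all(unique(fk$active$promoter_id) %in%
                        unique(f3$active$promoter_id)))
    }
  }
  # degenerate thresholds
  expect_equal(nrow(filter_inactive(records, control = control,
                                    threshold = Inf)$active), 0)
  expect_equal(nrow(filter_inactive(records, control = control,
                                    threshold = -Inf)$discarded), 0)
})
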