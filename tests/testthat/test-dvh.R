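test_that("cumulative/differential conversion matches hand-computed bins and round-trips", {
  x <- dvh_cumulative(c(0, 20, 40, 60), c(1.0, 1.0, 0.5, 0.0))
  d <- to_differential(x)
  expect_equal(d$dose_gy, c(10, 30, 50))
  expect_equal(d$volume_fraction, c(0.0, 0.5, 0.5))
  expect_equal(sum(d$volume_fraction), x$volume_fraction[1], tolerance = 1e-9)

  back <- to_cumulative(d)
  expect_equal(back$dose_gy, x$dose_gy, tolerance = 1e-12)
  expect_equal(back$volume_fraction, x$volume_fraction, tolerance = 1e-12)

  # near-uniform dose: a single occupied bin at ~50 Gy
  u <- dvh_cumulative(c(0, 50, 50.01), c(1, 1, 0))
  du <- to_differential(u)
  expect_equal(du$volume_fraction[du$volume_fraction > 0], 1.0)
  expect_equal(du$dose_gy[du$volume_fraction > 0], 50.005)
})

test_that("round-trip identity holds on random DVHs", {
  set.seed(42)
  for (i in 1:25) {
    x <- random_cumulative_dvh()
    rt <- to_cumulative(to_differential(x))
    expect_equal(rt$volume_fraction, x$volume_fraction, tolerance = 1e-9)
    d <- to_differential(x)
    rt2 <- to_differential(to_cumulative(d))
    expect_equal(rt2$volume_fraction, d$volume_fraction, tolerance = 1e-9)
  }
})

test_that("invalid DVHs are rejected with informative errors", {
  expect_error(dvh_cumulative(c(0, 20, 40), c(1.0, 0.5, 0.8)),
               "increases at index 3")
  expect_error(dvh_cumulative(c(0, 40, 20), c(1, 0.5, 0)),
               "strictly increasing")
  expect_error(dvh_cumulative(c(0, 20), c(0.8, 0.5)), "start at volume fraction 1")
  expect_error(dvh_differential(c(0, 20), c(20, 40), c(0.5, -0.2)),
               "negative bin fraction at bin 2")
})

test_that("resampling interpolates linearly, zeroes beyond support, and preserves d_mean on refinement", {
  x <- dvh_cumulative(c(0, 60), c(1, 0))
  r <- resample_cumulative(x, c(0, 30, 60, 100))
  expect_equal(r$volume_fraction, c(1, 0.5, 0, 0))

  # identity on the original grid
  y <- dvh_cumulative(c(0, 10, 20, 30), c(1, 0.8, 0.3, 0))
  expect_equal(resample_cumulative(y, y$dose_gy)$volume_fraction,
               y$volume_fraction)

  # refinement then coarsening leaves d_mean unchanged
  set.seed(7)
  for (i in 1:10) {
    z <- random_cumulative_dvh(max_dose = 60, n_bins = 40)
    fine <- seq(0, max(z$dose_gy), length.out = 4 * nrow(z) - 3)  # strict refinement
    zf <- resample_cumulative(z, fine)
    back <- resample_cumulative(zf, z$dose_gy)
    expect_equal(dose_summary(back)$d_mean, dose_summary(z)$d_mean,
                 tolerance = 1e-9)
  }
  expect_error(resample_cumulative(x, numeric(0)), "grid")
})

test_that("digitized point ingestion sorts, clips, repairs monotonicity and prepends the origin", {
  p1 <- data.frame(dose_gy = c(40, 0, 20), volume_fraction = c(0.5, 1.0, 0.98))
  h1 <- ingest_digitized_points(p1)
  expect_equal(h1$dose_gy, c(0, 20, 40))
  expect_equal(h1$volume_fraction, c(1.0, 0.98, 0.5))

  # jitter-induced bump flattened by the running minimum
  p2 <- data.frame(dose_gy = c(0, 20, 25, 40),
                   volume_fraction = c(1.0, 0.60, 0.62, 0.3))
  expect_equal(ingest_digitized_points(p2)$volume_fraction,
               c(1.0, 0.60, 0.60, 0.3))

  # clipping to [0, 1] and origin prepending
  p3 <- data.frame(dose_gy = c(10, 60), volume_fraction = c(1.2, -0.1))
  h3 <- ingest_digitized_points(p3)
  expect_equal(h3$dose_gy, c(0, 10, 60))
  expect_equal(h3$volume_fraction, c(1, 1, 0))

  expect_error(ingest_digitized_points(data.frame(dose_gy = 1,
                                                  volume_fraction = 1)),
               "at least 2")
  expect_error(ingest_digitized_points(
    data.frame(dose_gy = c(5, 5), volume_fraction = c(1, 0.5))), "all equal")
})

test_that("ingestion yields a valid cumulative DVH for arbitrary point clouds", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    pts <- data.frame(dose_gy = stats::runif(n, 0, 80),
                      volume_fraction = stats::rnorm(n, 0.5, 0.6))
    h <- ingest_digitized_points(pts)
    expect_silent(validate_dvh(h))
    expect_equal(h$volume_fraction[1], 1)
    expect_true(all(diff(h$volume_fraction) <= 1e-12))
  }
})

test_that("dose summary matches hand-derived values and orders d_min <= d_mean <= d_max", {
  x <- dvh_cumulative(c(0, 20, 40, 60), c(1.0, 1.0, 0.5, 0.0))
  s <- dose_summary(x)
  expect_equal(s$d_mean, 40)
  expect_equal(s$d_min, 20, tolerance = 1e-3)
  expect_equal(s$d_max, 60, tolerance = 1e-3)

  # uniform dose: min = mean = max
  u <- dvh_cumulative(c(0, 49.995, 50.005), c(1, 1, 0))
  su <- dose_summary(u)
  expect_equal(su$d_min, 50, tolerance = 0.02)
  expect_equal(su$d_mean, 50, tolerance = 0.02)
  expect_equal(su$d_max, 50, tolerance = 0.02)

  # all volume at ~0 Gy
  z <- dvh_cumulative(c(0, 0.001), c(1, 0))
  expect_true(all(abs(unlist(dose_summary(z)[c("d_min", "d_mean", "d_max")])) < 0.01))

  set.seed(3)
  for (i in 1:30) {
    s <- dose_summary(random_cumulative_dvh())
    expect_true(s$d_min <= s$d_mean + 1e-9)
    expect_true(s$d_mean <= s$d_max + 1e-9)
  }
})

test_that("DVH CSV round-trips and rejects malformed files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tbl <- tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    course = c("RT1", "ReRT", "ReRT"),
    structure = c("brainstem", "brainstem", "gtv"),
    dvh = list(
      dvh_cumulative(c(0, 20, 40, 60), c(1, 1, 0.5, 0), "brainstem"),
      dvh_cumulative(c(0, 10, 20), c(1, 0.4, 0), "brainstem"),
      dvh_cumulative(c(0, 30, 36, 40), c(1, 1, 0.5, 0), "gtv",
                     absolute_volume_cc = 33.9)
    )
  )
  write_dvh_csv(tbl, tmp)
  back <- read_dvh_csv(tmp)
  expect_equal(nrow(back), 3)
  orig <- tbl[order(tbl$patient_id, tbl$course, tbl$structure), ]
  back <- back[order(back$patient_id, back$course, back$structure), ]
  for (i in 1:3) {
    expect_equal(back$dvh[[i]]$dose_gy, orig$dvh[[i]]$dose_gy)
    expect_equal(back$dvh[[i]]$volume_fraction, orig$dvh[[i]]$volume_fraction)
    expect_equal(dvh_structure(back$dvh[[i]]), dvh_structure(orig$dvh[[i]]))
  }
  expect_equal(dvh_absolute_volume(back$dvh[back$structure == "gtv"][[1]]), 33.9)

  # missing column
  writeLines("patient_id,course,structure,dose_gy", tmp)
  expect_error(read_dvh_csv(tmp), "missing required column")

  # unknown mode token
  writeLines(c("patient_id,course,structure,mode,dose_gy,volume_fraction,absolute_volume_cc",
               "P1,RT1,brain,sideways,0,1,NA"), tmp)
  expect_error(read_dvh_csv(tmp), "unknown DVH mode")

  # cumulative invariant violated in file
  writeLines(c("patient_id,course,structure,mode,dose_gy,volume_fraction,absolute_volume_cc",
               "P1,RT1,brain,cumulative,0,1,NA",
               "P1,RT1,brain,cumulative,10,0.4,NA",
               "P1,RT1,brain,cumulative,20,0.9,NA"), tmp)
  expect_error(read_dvh_csv(tmp), "increases")
})
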