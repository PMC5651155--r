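test_that("overlapping segmentation yields the enumerated window starts", {
  cfg <- segmentation_config()
  segs <- segment_channel(rnorm(1000), cfg, fs = 1000)
  expect_length(segs, 19L)
  expect_equal(vapply(segs, `[[`, integer(1), "start_sample"),
               seq(0L, 900L, by = 50L))
  expect_length(segment_channel(rnorm(100), cfg, 1000), 1L)
  expect_length(segment_channel(rnorm(149), cfg, 1000), 1L)
  expect_error(segment_channel(rnorm(99), cfg, 1000), "shorter than one window")
})

test_that("segment counts match brute-force enumeration across lengths", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:120, 1)
    step <- sample(1:n, 1)
    L <- sample(n:(10 * n), 1)
    expect_equal(segment_starts(L, n, step), brute_starts(L, n, step))
  }
})

test_that("median smoothing removes impulses and respects edges", {
  expect_equal(median_smooth(c(1, 9, 1, 1, 1), 3), rep(1, 5))
  expect_equal(median_smooth(rep(4.2, 10), 5), rep(4.2, 10))
  x <- rnorm(20)
  expect_identical(median_smooth(x, 1), x)
  expect_error(median_smooth(x, 4), "odd")
  expect_error(median_smooth(rnorm(3), 5), "exceeds segment length")
  # edge replication: hand-computed medians at the borders
  y <- c(5, 1, 2, 3, 4)
  expect_equal(median_smooth(y, 3),
               c(median(c(5, 5, 1)), median(c(5, 1, 2)), median(c(1, 2, 3)),
                 median(c(2, 3, 4)), median(c(3, 4, 4))))
})

test_that("the eight statistics match their hand-derived values", {
  f <- extract_features(c(1, 2, 3))
  expect_equal(f[["X3"]], 2)
  expect_equal(f[["X4"]], 1)
  expect_equal(f[["X7"]], 1)   # (1/(2*1)) * (1 + 0 + 1) with the 1/(N-1) form
  expect_equal(f[["X8"]], 0)
  f4 <- extract_features(c(1, 2, 3, 4))
  expect_equal(f4[["X6"]], 2)  # Q1 = 1.5, Q3 = 3.5, exclusive halves
  expect_equal(f4[["X5"]], 2.5)
  expect_equal(f4[["X1"]], 4)
  expect_equal(f4[["X2"]], 1)
})

test_that("zero-variance windows are degenerate with kurtosis = skewness = 0", {
  f <- extract_features(rep(7, 100))
  expect_equal(f[["X7"]], 0)
  expect_equal(f[["X8"]], 0)
  expect_true(isTRUE(attr(f, "degenerate")))
  expect_true(all(is.finite(f)))
})

test_that("features match the direct-summation oracle on random segments", {
  set.seed(42)
  for (i in 1:200) {
    x <- rnorm(100, sd = runif(1, 0.1, 10))
    got <- extract_features(x)
    want <- oracle_features(x)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("matrix and per-segment feature paths agree, odd and even N", {
  set.seed(7)
  for (n in c(99, 100)) {
    m <- matrix(rnorm(n * 40), nrow = n)
    fm <- extract_features_matrix(m)
    for (j in c(1, 17, 40))
      expect_equal(as.numeric(fm[j, ]),
                   as.numeric(extract_features(m[, j])), tolerance = 1e-12)
  }
})

test_that("features transform correctly under affine maps", {
  set.seed(9)
  x <- rnorm(100)
  f <- extract_features(x)
  shift <- extract_features(x + 3.7)
  expect_equal(shift[["X4"]], f[["X4"]])
  expect_equal(shift[["X6"]], f[["X6"]])
  expect_equal(shift[["X7"]], f[["X7"]])
  expect_equal(shift[["X8"]], f[["X8"]])
  expect_equal(shift[c("X1", "X2", "X3", "X5")],
               f[c("X1", "X2", "X3", "X5")] + 3.7)
  scaled <- extract_features(2.5 * x)
  expect_equal(as.numeric(scaled[1:6]), as.numeric(2.5 * f[1:6]))
  expect_equal(scaled[["X7"]], f[["X7"]])
  expect_equal(scaled[["X8"]], f[["X8"]])
})

test_that("window labels follow the half-window overlap rule", {
  ev <- function(s, e) data.frame(start_sample = s, end_sample = e)
  expect_equal(label_segments(0L, 100, ev(25, 90)), "spike")    # overlap 65
  expect_equal(label_segments(0L, 100, ev(90, 140)), "nonspike") # overlap 10
  expect_equal(label_segments(0L, 100, ev(50, 140)), "spike")   # boundary 50
  expect_equal(label_segments(0L, 100,
                              data.frame(start_sample = integer(),
                                         end_sample = integer())), "nonspike")
  expect_error(label_segments(0L, 100, ev(10, 10)), "malformed")
  seg <- list(values = numeric(100), start_sample = 0L)
  expect_equal(label_segment(seg, ev(25, 90)), "spike")
})

test_that("recording and annotation files round-trip", {
  rec <- recording(matrix(round(rnorm(24 * 500), 6), nrow = 24), fs = 1000,
                   region = "left_occipital")
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_equal(back$data, rec$data)
  expect_equal(back$fs, 1000)
  expect_equal(back$region, "left_occipital")
  ev <- data.frame(start_sample = c(10L, 300L), end_sample = c(80L, 380L))
  pa <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ev, pa, region = rec$region)
  expect_equal(read_annotations(pa)[, 1:2], ev)
})

test_that("feature tables label all channels of a window identically", {
  sim <- simulate_recording(sim_config(duration_s = 8, rng_seed = 5,
                                       spike_rate = 20))
  ft <- compute_feature_table(sim$recording, sim$events)
  expect_true(nrow(sim$events) > 0)
  expect_setequal(unique(ft$label), c("spike", "nonspike"))
  per_window <- tapply(ft$label, ft$start_sample,
                       function(l) length(unique(l)))
  expect_true(all(per_window == 1L))
  expect_equal(nrow(ft), 26 * length(unique(ft$start_sample)))
})
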