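test_that("regional voting is a strict majority for 26 and 24 channels", {
  for (n_votes in 0:26)
    expect_equal(vote_region(rep(c(TRUE, FALSE), c(n_votes, 26 - n_votes))),
                 if (n_votes > 13) "spike" else "nonspike")
  for (n_votes in 0:24)
    expect_equal(vote_region(rep(c(TRUE, FALSE), c(n_votes, 24 - n_votes))),
                 if (n_votes > 12) "spike" else "nonspike")
  expect_error(vote_region(rep(TRUE, 10)), "24 or 26")
})

test_that("voting is invariant under channel permutation", {
  set.seed(41)
  for (i in 1:20) {
    v <- runif(26) < 0.5
    expect_equal(vote_region(v), vote_region(sample(v)))
  }
})

test_that("score matrices have one finite scalar per channel and window", {
  rec <- recording(matrix(rnorm(26 * 730), nrow = 26), fs = 1000)
  s <- score_segments(rec, gp_terminal(4))
  expect_equal(dim(s), c(26L, 13L))  # floor((730-100)/50)+1
  expect_equal(attr(s, "starts"), seq(0L, 600L, by = 50L))
  expect_true(all(is.finite(s)))
  zero <- recording(matrix(0, 26, 300), fs = 1000)
  expect_true(all(score_segments(zero, gp_terminal(3)) == 0))
  const <- recording(matrix(rep(rnorm(300), each = 26), nrow = 26), fs = 1000)
  sc <- score_segments(const, parse_formula("(plus X4 (cos X1))"))
  expect_true(all(apply(sc, 2, function(col) all(col == col[1]))))
})

test_that("detection end-to-end on a hand-built separable fixture", {
  # flat recording with one burst over samples [100, 200): only windows
  # overlapping the burst by >= 50 samples are true spikes
  set.seed(42)
  dat <- matrix(0, 26, 400)
  dat[, 101:200] <- 5 * matrix(rnorm(26 * 100), 26, 100)
  rec <- recording(dat, fs = 1000)
  ann <- data.frame(start_sample = 100L, end_sample = 200L)
  # nonspike reference near zero, spike reference well below the burst sd
  model <- knn_model(c(0.05, 1), c("nonspike", "spike"), k = 1)
  dec <- detect_spikes(rec, gp_terminal(4), model, annotations = ann)
  expect_equal(nrow(dec), 7L)
  expect_equal(dec$truth, ifelse(dec$start_sample %in% c(50, 100, 150),
                                 "spike", "nonspike"))
  expect_equal(dec$decision, dec$truth)  # sd separates perfectly here
  expect_equal(dec$n_spike_votes[dec$decision == "spike"], rep(26L, 3L))
  ev <- evaluate_detections(dec)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 100)
  expect_equal(sum(ev$counts), nrow(dec))
})

test_that("an all-background recording yields no detections", {
  sim <- simulate_recording(sim_config(duration_s = 20, spike_rate = 0,
                                       rng_seed = 43))
  expect_equal(nrow(sim$events), 0L)
  model <- knn_model(c(1.0, 5.0), c("nonspike", "spike"), k = 1)
  dec <- detect_spikes(sim$recording, gp_terminal(4), model,
                       annotations = sim$events)
  expect_true(all(dec$decision == "nonspike"))
  ev <- evaluate_detections(dec)
  expect_true(is.na(ev$sensitivity))   # no positive truths: not applicable
  expect_equal(ev$specificity, 100)
})

test_that("evaluation counts and handles unknown truth strictly", {
  dec <- data.frame(start_sample = 0, end_sample = 100,
                    n_spike_votes = 20,
                    decision = rep(c("spike", "nonspike", "spike", "nonspike"),
                                   c(90, 10, 7, 93)),
                    truth = rep(c("spike", "nonspike"), c(100, 100)))
  ev <- evaluate_detections(dec)
  expect_equal(ev$sensitivity, 90)
  expect_equal(ev$specificity, 93)
  expect_equal(ev$counts, c(TP = 90L, FP = 7L, TN = 93L, FN = 10L))
  dec$truth[1] <- "unknown"
  expect_error(evaluate_detections(dec), "unknown ground truth")
})

test_that("adjacent positive windows merge into single events", {
  dec <- data.frame(start_sample = c(0, 50, 100, 300, 500),
                    end_sample = c(100, 150, 200, 400, 600),
                    n_spike_votes = 20,
                    decision = c("spike", "spike", "spike", "spike",
                                 "nonspike"),
                    truth = "unknown")
  m <- merge_detections(dec, step = 50)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start_sample, c(0, 300))
  expect_equal(m$end_sample, c(200, 400))
  expect_equal(m$n_windows, c(3L, 1L))
})
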