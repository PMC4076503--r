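test_that("coincidence counting matches hand-enumerated examples", {
  expect_equal(coincident_count(c(0.1, 0.2, 0.3), c(0.12, 0.5), 0.05), 1)
  # identical trains with ISIs > 2 dt: each spike pairs only with itself
  tr <- seq(0, 9, by = 1)
  expect_equal(coincident_count(tr, tr, 0.05), 10)
  expect_equal(coincident_count(numeric(0), tr, 0.05), 0)
  expect_equal(coincident_count(tr, numeric(0), 0.05), 0)
  expect_error(coincident_count(c(2, 1), tr, 0.05), "sorted")
  expect_error(coincident_count(tr, tr, 0), "positive")
})

test_that("two-pointer sweep equals brute force on random trains", {
  set.seed(7)
  for (rep in 1:300) {
    a <- sort(runif(sample(0:200, 1L), 0, 10))
    b <- sort(runif(sample(0:200, 1L), 0, 10))
    dt <- runif(1, 0.001, 0.5)
    expect_equal(coincident_count(a, b, dt), brute_coincidences(a, b, dt))
  }
})

test_that("coincidence count is monotone in the window width", {
  set.seed(11)
  for (rep in 1:20) {
    a <- sort(runif(100, 0, 10)); b <- sort(runif(100, 0, 10))
    dts <- sort(runif(5, 0.001, 1))
    counts <- vapply(dts, function(dt) coincident_count(a, b, dt),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("correlation index: formula, symmetry, shift invariance", {
  expect_equal(correlation_index(c(0.1, 0.2, 0.3), c(0.12, 0.5),
                                 dt = 0.05, T = 1),
               1 / (3 * 2 * 2 * 0.05))  # = 1.6667
  # disjoint trains
  expect_equal(correlation_index(c(1, 2), c(10, 20), 0.05, 100), 0)
  # empty train -> NaN, not 0
  expect_true(is.nan(correlation_index(numeric(0), c(1, 2), 0.05, 10)))

  set.seed(3)
  for (rep in 1:20) {
    a <- sort(runif(50, 1, 9)); b <- sort(runif(50, 1, 9))
    ci_ab <- correlation_index(a, b, 0.05, 10)
    expect_identical(ci_ab, correlation_index(b, a, 0.05, 10))
    # common time shift away from boundaries leaves CI unchanged
    expect_equal(correlation_index(a + 0.5, b + 0.5, 0.05, 10), ci_ab)
  }
})

test_that("independent Poisson trains calibrate the index near 1", {
  # Monte-Carlo: E[CI] = 1 under independence
  set.seed(123)
  T <- 1000; rate <- 1; dt <- 0.05
  cis <- replicate(200, {
    a <- sort(runif(rpois(1, rate * T), 0, T))
    b <- sort(runif(rpois(1, rate * T), 0, T))
    correlation_index(a, b, dt, T)
  })
  expect_gt(mean(cis), 0.9)
  expect_lt(mean(cis), 1.1)
})

test_that("ci_map enumerates all pairs with distances and NaN rules", {
  rec <- simulate_poisson(1, 60, "hex_60um_61", seed = 5)
  rec5 <- mea_recording(rec$epos[1:5, ],
                        unlist(lapply(1:5, unit_spikes, rec = rec)),
                        rec$sCount[1:5], rec$array, rec$meta)
  pairs <- ci_map(rec5, dt = 0.05)
  expect_equal(nrow(pairs), 10)  # 5 * 4 / 2
  expect_true(all(pairs$i < pairs$j))
  # dist() enumerates the lower triangle in the same (i, j) order
  expect_equal(pairs$distance, as.vector(dist(rec5$epos)),
               tolerance = 1e-12)

  # duplicate positions produce a distance-0 pair, which is kept
  recdup <- mea_recording(cbind(c(0, 0, 100), c(0, 0, 0)),
                          c(0.1, 0.5, 0.2, 0.6, 0.3), c(2, 2, 1),
                          "MCS_8x8_100um", mea_metadata("x", "mouse", 5))
  pd <- ci_map(recdup)
  expect_true(any(pd$distance == 0))

  # one empty train among three -> 2 of 3 pairs NaN
  rec0 <- mea_recording(cbind(c(0, 50, 100), c(0, 0, 0)),
                        c(0.1, 0.5, 0.2), c(2, 0, 1),
                        "MCS_8x8_100um", mea_metadata("x", "mouse", 5))
  p0 <- ci_map(rec0)
  expect_equal(sum(is.nan(p0$ci)), 2L)

  expect_error(ci_map(mea_recording(cbind(0, 0), c(0.5), 1L,
                                    "MCS_8x8_100um",
                                    mea_metadata("x", "mouse", 5))),
               "at least 2")
})

test_that("distance binning averages non-NaN pairs in 100 um bins", {
  one <- data.frame(i = 1, j = 2, distance = 50, ci = 3.0)
  b1 <- bin_ci_by_distance(one)
  expect_equal(b1$left, 0)
  expect_equal(b1$centre, 50)
  expect_equal(b1$mean_ci, 3.0)

  two <- data.frame(i = c(1, 1), j = c(2, 3), distance = c(50, 60),
                    ci = c(2, 4))
  expect_equal(bin_ci_by_distance(two)$mean_ci, 3.0)

  # NaN pairs are skipped; empty bins are omitted
  mix <- data.frame(i = 1:3, j = 2:4, distance = c(50, 60, 250),
                    ci = c(2, NaN, 5))
  bm <- bin_ci_by_distance(mix)
  expect_equal(bm$left, c(0, 200))
  expect_equal(bm$mean_ci, c(2, 5))
  expect_equal(bm$n_pairs, c(1L, 1L))

  expect_error(bin_ci_by_distance(one[0, ]), "at least one")
  expect_error(bin_ci_by_distance(one, width = 0), "positive")
})

test_that("population rate averages spikes over units and conserves mass", {
  # 10 uniform spikes on unit 1 of 2 in [0,10): each bin 0.5 Hz/unit
  rec <- mea_recording(cbind(c(0, 100), c(0, 0)),
                       c(seq(0.5, 9.5, by = 1)), c(10, 0),
                       "MCS_8x8_100um", mea_metadata("x", "mouse", 5))
  pr <- population_rate(rec)
  expect_equal(nrow(pr), 10)
  expect_equal(pr$rate, rep(0.5, 10))

  # silent bins are 0; total mass equals the spike count
  w <- simulate_waves(wave_sim_params(duration = 120, seed = 2))
  pw <- population_rate(w, binwidth = 1)
  expect_equal(sum(pw$rate) * 1 * n_units(w), w$summary$totalspikes)
  expect_true(any(pw$rate == 0))
})
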