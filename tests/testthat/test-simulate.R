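test_that("a single zero-rate superstate sits still", {
  G <- structure(matrix(0, 3, 3),
                 class = c("fret_generator", "matrix", "array"),
                 loads = 1L, active = 1L, psi = 1:3)
  traj <- simulate_trajectory(G, t_end = 5)
  expect_identical(nrow(traj$jumps), 0L)
  expect_identical(nrow(traj$emissions), 0L)
  expect_identical(traj$final_state, traj$init_state)
})

test_that("superstate holding times are exponential with the escape rate", {
  set.seed(51)
  # non-stiff toy so every superstate accumulates dwells
  phys <- photophysics_config(lambda_ex = 5, lambda_d = 20, lambda_a = 15)
  kin <- system_kinetics(matrix(c(0, 3, 2, 0), 2, 2, byrow = TRUE),
                         lambda_fret = c(4, 25))
  G <- build_generator(phys, kin)
  traj <- simulate_trajectory(G, t_end = 4000)
  expect_gt(nrow(traj$jumps), 1e4)
  state_seq <- c(traj$init_state, traj$jumps$state)
  dwell <- diff(c(traj$t_start, traj$jumps$time))
  occupied <- state_seq[seq_along(dwell)]
  for (s in unique(occupied)) {
    d <- dwell[occupied == s]
    if (length(d) < 200) next
    rate <- -unclass(G)[s, s]
    p <- stats::ks.test(d, "pexp", rate)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("donor photons split between channels by the cross-talk factors", {
  set.seed(52)
  n <- 1e5
  em <- tibble::tibble(time = sort(runif(n, 0, 100)), dye = "donor")
  det <- detection_model(phi_d = c(0.18, 0.82), phi_a = c(0.84, 0))
  tr <- emit_photons(em, det, t_start = 0, t_end = 100)
  expect_equal(nrow(tr), n)   # factors sum to 1: no loss
  frac1 <- mean(tr$channel == 1L)
  se <- sqrt(0.18 * 0.82 / n)
  expect_lt(abs(frac1 - 0.18), 3 * se)
})

test_that("acceptor detection loss and Poisson background behave as set", {
  set.seed(53)
  n <- 5e4
  em <- tibble::tibble(time = sort(runif(n, 0, 50)), dye = "acceptor")
  det <- calibration_preset("buffer")   # phi_a sums to 0.72
  tr <- emit_photons(em, det, t_start = 0, t_end = 50)
  expect_lt(abs(nrow(tr) / n - 0.72 - sum(det$bg) * 50 / n),
            3 * sqrt(0.72 * 0.28 / n))
  # pure background over a long window, published EG rates
  none <- tibble::tibble(time = numeric(0), dye = character(0))
  bg <- c(0.467, 0.283)
  det_bg <- detection_model(c(0, 0), c(0, 0), bg = bg)
  tr_bg <- emit_photons(none, det_bg, t_start = 0, t_end = 1e4)
  for (j in 1:2) {
    mu <- bg[j] * 1e4
    expect_lt(abs(sum(tr_bg$channel == j) - mu), 3 * sqrt(mu))
  }
  # nothing in, nothing out
  tr0 <- emit_photons(none, ideal_detection(), t_start = 0, t_end = 10)
  expect_identical(nrow(tr0), 0L)
})

test_that("traces are valid, reproducible, and hit photon targets exactly", {
  mod <- toy_two_state()
  det <- calibration_preset("eg36")
  set.seed(54)
  tr <- simulate_trace(mod$phys, mod$kin, det, photons = 1234)
  expect_identical(nrow(tr), 1234L)
  expect_true(all(diff(tr$time_s) > 0))
  set.seed(54)
  tr_again <- simulate_trace(mod$phys, mod$kin, det, photons = 1234)
  expect_identical(tr$time_s, tr_again$time_s)
  expect_identical(tr$channel, tr_again$channel)
})

test_that("acceptor fraction converges to the state's FRET efficiency", {
  set.seed(55)
  # one system state, ideal detection: acceptor share estimates epsilon
  ld <- 1 / 3.5e-9
  phys <- photophysics_config(lambda_ex = 1e4, lambda_d = ld)
  kin <- system_kinetics(matrix(0, 1, 1), fret_rate(0.9, ld))
  tr <- simulate_trace(phys, kin, ideal_detection(), photons = 2e4)
  frac_acc <- mean(tr$channel == 1L)
  expect_lt(abs(frac_acc - 0.9), 3 * sqrt(0.9 * 0.1 / 2e4))
})

test_that("benchmark scenarios carry their published ground truths", {
  b3 <- fretjump:::benchmark_spec("three_state_x1")
  expect_equal(unname(escape_rates(b3$kin)), c(10, 20, 30))   # 0.01-0.03 /ms
  expect_equal(b3$efficiency, c(0.09, 0.5, 0.9))
  expect_equal(b3$phys$lambda_ex, 1e4)
  expect_equal(b3$photons, 2e6)
  b3c <- fretjump:::benchmark_spec("three_state_x100")
  expect_equal(unname(escape_rates(b3c$kin)), c(1000, 2000, 3000))
  b2 <- fretjump:::benchmark_spec("robustness_two_state")
  expect_equal(unname(escape_rates(b2$kin)), c(4.3, 23.0))
  expect_equal(b2$efficiency, c(0.0, 0.8))
  expect_equal(b2$photons, 2e5)
  expect_equal(b2$det$phi_a, c(0.72, 0))
  expect_equal(b2$det$bg, c(1.561, 0.312))
  b4 <- fretjump:::benchmark_spec("robustness_four_state")
  expect_equal(unname(escape_rates(b4$kin)), c(4.31, 24.97, 8.87, 6.6))
  expect_equal(b4$efficiency, c(0.0, 0.72, 0.28, 0.92))
  expect_error(fretjump:::benchmark_spec("no_such_design"), "unknown benchmark")
  # photon-count override is honored exactly
  bench <- make_benchmark("three_state_x1", photons = 500, seed = 5)
  expect_identical(nrow(bench$trace), 500L)
})
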