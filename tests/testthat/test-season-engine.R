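test_that("parasitoid phase handles the degenerate corners exactly", {
  np <- portugal_params(0.75)
  # no adults: nothing laid
  r0 <- parasitoid_phase(0, 0.8, np)
  expect_equal(r0$p_end, 0)
  expect_equal(r0$q_end, 0)
  expect_equal(r0$emergence, 0.8)
  # no hosts: adults idle, nothing laid
  r1 <- parasitoid_phase(1, 0, np)
  expect_equal(r1$p_end, 1)
  expect_equal(r1$q_end, 0)
  expect_error(parasitoid_phase(-1, 1, np), "nonnegative")
})

test_that("parasitoid phase conserves q + E_t * p and matches the oracle", {
  set.seed(42)
  for (i in 1:20) {
    eta <- runif(1, 0.5, 1)
    np <- nondim_parameters(mu = 10, tau = 1 / eta,
                            E_d = eta * 150, E_t = runif(1, 5, 40),
                            eta = eta)
    p0 <- runif(1, 0.01, 1)
    v_prev <- runif(1, 0.01, 1)
    ph <- parasitoid_phase(p0, v_prev, np)
    # conservation identity q = E_t (p0 - p), exact along trajectories
    expect_equal(ph$q_end, np$E_t * (p0 - ph$p_end), tolerance = 1e-8)
    # complementary split is consistent
    expect_equal(ph$q_end + ph$emergence, v_prev, tolerance = 1e-10)
    expect_lte(ph$q_end, v_prev)
    expect_lte(ph$p_end, p0)
  }
  # end-of-phase values agree with a fixed-step RK4 oracle at dt = 1e-5
  set.seed(7)
  for (i in 1:5) {
    eta <- runif(1, 0.5, 1)
    np <- nondim_parameters(mu = 10, tau = 1 / eta, E_d = eta * 150,
                            E_t = runif(1, 5, 40), eta = eta)
    p0 <- runif(1, 0.05, 1); v_prev <- runif(1, 0.05, 1)
    ph <- parasitoid_phase(p0, v_prev, np)
    or <- oracle_parasitoid(p0, v_prev, np$E_t, np$tau,
                            np$parasitoid_phase_length)
    expect_equal(ph$p_end, or$p_end, tolerance = 1e-8)
    expect_equal(ph$q_end, or$q_end, tolerance = 1e-8)
  }
})

test_that("wasp phase matches closed form, oracle and saturation bounds", {
  # E_d -> 0 limit: v stays 0, so u' = -2 mu u + c integrates exactly to
  # u(t) = (c / 2 mu)(1 - exp(-2 mu t))
  np0 <- nondim_parameters(mu = 10, tau = 1, E_d = 0, E_t = 33.37)
  w <- wasp_phase(v_prev = 1, q_end = 0, np0)
  expect_equal(w$u_end, (1 / 20) * (1 - exp(-20)), tolerance = 1e-6)
  expect_equal(w$v_end, 0)

  # no emergence: absorbing empty state
  np <- portugal_params(0.85)
  w0 <- wasp_phase(v_prev = 0.3, q_end = 0.3, np)
  expect_equal(w0$u_end, 0)
  expect_equal(w0$v_end, 0)

  # full emergence at carrying scale: near-saturation, oracle-checked
  w1 <- wasp_phase(v_prev = 1, q_end = 0, np)
  or <- oracle_wasp(1, np$E_d, np$mu, 1)
  expect_equal(w1$v_end, or$v_end, tolerance = 1e-8)
  expect_equal(w1$u_end, or$u_end, tolerance = 1e-8)
  expect_gt(w1$v_end, 0.9)
  expect_lte(w1$v_end, 1)

  expect_error(wasp_phase(0.1, 0.5, np), "exceeds")
})

test_that("trajectories are monotone the way the biology demands", {
  np <- portugal_params(0.75)
  ph <- parasitoid_phase(0.5, 0.8, np, trajectory = TRUE)
  expect_true(all(diff(ph$trajectory$q) >= -1e-12))   # eggs accumulate
  expect_true(all(diff(ph$trajectory$p) <= 1e-12))    # adults only deplete
  w <- wasp_phase(1, 0.2, np, trajectory = TRUE)
  expect_true(all(diff(w$trajectory$v) >= -1e-12))
  expect_true(all(w$trajectory$u >= -1e-12))
})

test_that("multi-year map couples seasons and respects bounds", {
  np <- portugal_params(0.75)
  ss <- run_multi_year(params = np, n_years = 25)
  expect_s3_class(ss, "season_series")
  expect_equal(nrow(ss), 25)
  # season-to-season bounds: 0 <= q_n <= v_{n-1}, 0 <= v_n <= 1
  v_prev <- c(1, ss$v_end[-25])
  expect_true(all(ss$q_end >= 0 & ss$q_end <= v_prev + 1e-12))
  expect_true(all(ss$v_end >= 0 & ss$v_end <= 1))
  # first season reproduces the two phases run by hand
  pa <- parasitoid_phase(1e-9, 1, np)
  wa <- wasp_phase(1, pa$q_end, np, emergence = pa$emergence)
  expect_equal(ss$v_end[1], wa$v_end)
  expect_equal(ss$q_end[1], pa$q_end)
})

test_that("parasitoid-free control run keeps the pest saturated", {
  np <- portugal_params(0.65)
  ss <- run_multi_year(q0 = 0, params = np, n_years = 10)
  expect_true(all(ss$q_end == 0))
  expect_true(all(ss$v_end > 0.99))
})

test_that("establishment precedes collapse with the reference dynamics", {
  for (eta in c(0.65, 0.75, 0.85)) {
    ss <- homog_run(eta)
    first7 <- ss[1:7, ]
    expect_true(all(diff(first7$q_end) > 0))   # steady parasitoid growth
    expect_true(all(first7$v_end > 0.99))      # pest unaffected meanwhile
    yr_q <- ss$year[which(ss$q_end > 0.1)[1]]
    yr_v <- ss$year[which(ss$v_end < 1e-2)[1]]
    expect_lt(yr_q, yr_v)
  }
})

test_that("extinction clamping zeroes sub-threshold densities and flags them", {
  np <- portugal_params(0.85)
  th <- egg_capacity_and_threshold(5, 2e6)
  ss <- run_multi_year(params = np, n_years = 12, threshold = th,
                       clamp = TRUE)
  expect_true(any(ss$clamped))
  n_first <- which(ss$clamped)[1]
  expect_true(ss$v_end[n_first] == 0 || ss$q_end[n_first] == 0)
  # once both species are clamped to zero the system stays empty
  if (any(ss$v_end == 0 & ss$q_end == 0)) {
    n0 <- which(ss$v_end == 0 & ss$q_end == 0)[1]
    expect_true(all(ss$v_end[n0:12] == 0))
  }
  expect_error(run_multi_year(params = np, n_years = 2, clamp = TRUE),
               "threshold")
  expect_error(run_multi_year(params = np, n_years = 0), "n_years")
})
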