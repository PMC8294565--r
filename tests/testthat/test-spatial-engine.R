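test_that("discrete Laplacian is conservative and kills constants", {
  g <- spatial_grid(2, 1, h = 0.1)
  expect_equal(discrete_laplacian(matrix(3.7, g$nx, g$ny), g),
               matrix(0, g$nx, g$ny))
  set.seed(11)
  f <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  # zero-flux closure: total flux out of the domain is identically zero
  expect_equal(sum(discrete_laplacian(f, g)) * g$h^2, 0, tolerance = 1e-12)
  expect_error(discrete_laplacian(matrix(0, 3, 3), g), "shape")
})

test_that("Laplacian reproduces the Neumann cosine eigenvalue at O(h^2)", {
  err <- sapply(c(0.1, 0.05), function(h) {
    g <- spatial_grid(2, 1, h = h)
    f <- outer(cos(pi * g$x / g$Lx), rep(1, g$ny))
    lam <- -(pi / g$Lx)^2
    max(abs(discrete_laplacian(f, g) - lam * f))
  })
  expect_lt(err[2], err[1] / 3)  # halving h cuts the error ~4x
})

test_that("pure diffusion conserves mass under zero-flux boundaries", {
  # with v_prev = 0 the parasitoid reaction vanishes identically, leaving
  # p_t = delta * Lap(p); delta = 1 exercises the same operator the gall
  # wasp equation uses
  g <- spatial_grid(1, 1, h = 0.05)
  blob <- matrix(0, g$nx, g$ny)
  blob[5:8, 9:12] <- 1
  for (delta in c(1, 0.018)) {
    np <- nondim_parameters(mu = 10, tau = 1, E_d = 97.5, E_t = 33.37,
                            delta = delta)
    ph <- spatial_parasitoid_phase(blob, matrix(0, g$nx, g$ny), np, g,
                                   rtol = 1e-8, atol = 1e-14)
    expect_equal(sum(ph$p), sum(blob), tolerance = 1e-6)
    expect_equal(max(ph$q), 0)
    expect_true(all(ph$p >= 0))
    # diffusion spreads the blob: peak decreases, support grows
    expect_lt(max(ph$p), max(blob))
  }
})

test_that("spatially uniform runs reproduce the homogeneous engine", {
  np <- portugal_params(0.65)
  g <- spatial_grid(1, 1, h = 0.1)
  sp <- run_spatial_multi_year(g, uniform_infestation_init(g, q0 = 1e-9),
                               NULL, np, n_years = 10,
                               probes = list(c(0.5, 0.5)),
                               rtol = 1e-9, atol = 1e-30)
  hh <- run_multi_year(params = np, n_years = 10)
  expect_lt(max(abs(sp$probes[[1]]$v_end - hh$v_end)), 1e-6)
  expect_lt(max(abs(sp$probes[[1]]$q_end - hh$q_end)), 1e-6)
  # uniform fields stay uniform: diffusion terms vanish identically
  expect_lt(diff(range(sp$fields$v[, , 10])), 1e-12)
})

test_that("releases seed single cells, clip at the carrying scale", {
  np <- portugal_params(0.65)
  g <- spatial_grid(1, 1, h = 0.1)
  sched <- make_release_schedule("initial-only",
                                 data.frame(x = c(0, 0.02), y = c(0, 0)),
                                 amplitude = 0.8)
  # two stations mapping to the same corner cell: additive but clipped at 1
  p <- torysim:::.apply_releases(matrix(0, g$nx, g$ny), g, sched, 1L)
  expect_equal(p[1, 1], 1)            # 0.8 + 0.8 clipped
  expect_equal(sum(p > 0), 1L)        # single-cell footprint
  p2 <- torysim:::.apply_releases(matrix(0, g$nx, g$ny), g, sched, 2L)
  expect_equal(sum(p2), 0)            # no event scheduled in season 2
  expect_error(
    run_spatial_multi_year(g, uniform_infestation_init(g), NULL, np,
                           n_years = 1, probes = list(c(5, 5))),
    "outside")
})

test_that("nonnegativity and egg bounds hold along a short release run", {
  np <- portugal_params(0.65)
  g <- spatial_grid(2, 2, h = 0.1)
  sp <- run_spatial_multi_year(g, uniform_infestation_init(g),
                               make_release_schedule("initial-only", c(0, 0)),
                               np, n_years = 6, probes = list(c(1, 1)))
  expect_true(all(sp$fields$p >= 0) && all(sp$fields$q >= 0) &&
              all(sp$fields$u >= 0) && all(sp$fields$v >= 0))
  expect_true(all(sp$fields$v <= 1))
  # parasitoid eggs never exceed the hosts that were available
  v_prev <- array(1, dim(sp$fields$v))
  v_prev[, , -1] <- sp$fields$v[, , -dim(sp$fields$v)[3]]
  expect_true(all(sp$fields$q <= v_prev + 1e-9))
})

test_that("front radius diagnostic recovers a constructed suppression disc", {
  g <- spatial_grid(4, 4, h = 0.05)
  r0 <- 1.3
  d <- sqrt(outer(g$x, g$y, function(x, y) x^2 + y^2))
  f <- array(ifelse(d < r0, 0, 1), c(g$nx, g$ny, 1))
  expect_equal(front_radius_series(f, g, c(0, 0))[1], r0,
               tolerance = g$h * 2)
  # uniform saturated field: no front
  expect_true(is.na(front_radius_series(array(1, c(g$nx, g$ny, 1)),
                                        g, c(0, 0))[1]))
})
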