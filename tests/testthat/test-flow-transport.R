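test_that("Stokes solution reproduces Poiseuille flow in a straight channel", {
  m <- channel_mask(w = 32L, len = 80L, pad = 4L)
  vf <- solve_stokes(m, flow_config(u_m_target = 20))
  prof <- vf$u[5:36, 40L]
  expect_lt(abs(max(prof) / mean(prof) - 1.5), 0.03)       # centreline/mean 1.5 +- 2%
  expect_lt(vf$div_max, 1e-8)
  expect_equal(vf$u_m, 20)
  expect_true(all(vf$speed[m$grid == 0L] == 0))             # no-slip on solid
  expect_true(all(abs(vf$v[5:36, 40L]) < 1e-8 * max(prof))) # unidirectional
})

test_that("Stokes solution is exactly linear in the imposed flow rate", {
  m <- channel_mask(w = 16L, len = 50L)
  v1 <- solve_stokes(m, flow_config(Q = 0.1))
  v2 <- solve_stokes(m, flow_config(Q = 0.2))
  expect_lt(max(abs(v2$u - 2 * v1$u)) / max(abs(v1$u)), 1e-10)
  expect_lt(max(abs(v2$v - 2 * v1$v)) / max(abs(v1$u)), 1e-10)
})

test_that("flow stagnates inside dead-end pores", {
  sc <- test_scene()
  vf <- solve_stokes(sc$gen$mask, flow_config(u_m_target = 20))
  expect_lt(vf$div_max, 1e-8)
  lm <- sc$disc$label_map
  tp_mean <- mean(vf$speed[lm$grid == 2L])
  reg <- lm$dep_regions[[1L]]
  deep <- reg$pixels[reg$depth_map_px[reg$pixels] > reg$width_px]
  expect_lt(mean(vf$speed[deep]) / tp_mean, 1e-2)
  # whole-DEP mean is still far below the TP mean
  expect_lt(mean(vf$speed[lm$grid == 1L]) / tp_mean, 0.2)
})

test_that("non-percolating masks are rejected", {
  g <- matrix(1L, 40, 60)
  g[, 30] <- 0L                                            # wall across
  expect_error(solve_stokes(pore_mask(g, 1)), "percolate")
})

test_that("shear rate is u_m / h in consistent units", {
  expect_equal(shear_rate(20, flow_config(h = 0.05)), 0.4)
  expect_equal(shear_rate(0, flow_config(h = 0.05)), 0)
  expect_equal(shear_rate(40, flow_config(h = 0.05)), 0.8)
  expect_error(flow_config(h = -1), "positive")
})

test_that("sealed diffusion preserves a uniform field and total mass", {
  m <- channel_mask(w = 30L, len = 50L, pixel_size = 5)
  s <- simulate_tracer(m, NULL, D = 6e-4, t_end = 20, dt = 1, init = 0.7,
                       inlet = "sealed")
  last <- s$frames[[length(s$frames)]]
  expect_lt(max(abs(last[m$grid == 1L] - 0.7)), 1e-10)
  expect_lt(diff(range(s$mass)) / s$mass[1L], 1e-12)
})

test_that("pure diffusion of a step matches the closed-form erf profile", {
  m <- pore_mask(matrix(1L, 8, 400), pixel_size = 5)
  init <- matrix(0, 8, 400); init[, 1:200] <- 1
  D <- 6e-4; tend <- 100
  s <- simulate_tracer(m, NULL, D = D, t_end = tend, dt = 0.5, init = init,
                       inlet = "sealed")
  fin <- s$frames[[length(s$frames)]][4L, ]
  x_mm <- ((1:400) - 0.5 - 200) * 5e-3
  ana <- 0.5 * (1 - pracma::erf(x_mm / (2 * sqrt(D * tend))))
  expect_lt(max(abs(fin - ana)), 0.01)
})

test_that("displacement keeps concentrations bounded and mass non-increasing", {
  sc <- test_scene()
  vf <- solve_stokes(sc$gen$mask, flow_config(u_m_target = 20))
  s <- simulate_tracer(sc$gen$mask, vf, D = 6e-4, t_end = 60, dt = 2)
  for (fr in s$frames) {
    expect_gte(min(fr), -1e-9)
    expect_lte(max(fr), 1 + 1e-9)
  }
  expect_true(all(diff(s$mass) <= 1e-12))
})

test_that("DEP-entrance gradients persist longer with flow than without", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  vf <- solve_stokes(sc$gen$mask, flow_config(u_m_target = 20))
  pv <- scene_pv_time(sc$gen$mask, vf)
  t_end <- 1.6 * pv
  s_flow <- simulate_tracer(sc$gen$mask, vf, D = 6e-4, t_end = t_end, dt = 2)
  s_still <- simulate_tracer(sc$gen$mask, NULL, D = 6e-4, t_end = t_end, dt = 2)
  p_flow <- gradient_persistence(s_flow, lm)
  p_still <- gradient_persistence(s_still, lm)
  expect_true(all(p_flow$persistence_s >= p_still$persistence_s))
  # with flow the entrance gradient is still detectable at one pore volume
  expect_gte(max(p_flow$persistence_s), pv)
})

test_that("gradient persistence returns the exact step-vanishing time", {
  # hand-built series on a toy labelled scene: gradient present up to
  # frame k, gone afterwards
  cc <- channel_with_cavity(cav_depth = 40L, cav_w = 16L, len = 60L,
                            pixel_size = 4)
  d <- discretize_pores(cc$mask)
  pore <- cc$mask$grid == 1L
  mk <- function(delta) {
    f <- matrix(0, nrow(pore), ncol(pore))
    f[pore] <- 0.2
    reg <- d$label_map$dep_regions[[1L]]
    f[reg$pixels] <- 0.2 + delta
    f
  }
  series <- structure(list(
    frames = list(mk(0.8), mk(0.8), mk(0.5), mk(0.05), mk(0.0)),
    times = c(0, 10, 20, 30, 40), mass = rep(1, 5), D = 6e-4,
    pixel_size = 4, pore = pore, inlet = "dirichlet", inlet_value = 0),
    class = "tracer_series")
  p <- gradient_persistence(series, d$label_map, threshold = 0.1,
                            reference = 1)
  expect_equal(p$persistence_s, 20)
  expect_true(p$detected)
})

test_that("scene pore-volume and diffusive times are consistent", {
  expect_equal(diffusive_time(0.2, 6e-4), 200 / 3, tolerance = 1e-12)
  expect_equal(elution_time(2.4, 0.1, n_pv = 5), 120)
  m <- channel_mask(w = 20L, len = 100L, pad = 2L, pixel_size = 10)
  vf <- solve_stokes(m, flow_config(u_m_target = 50))
  pv <- scene_pv_time(m, vf)
  # plug-like transport: pore volume time ~ length / mean speed
  expect_lt(abs(pv - (100 * 10 / 50)) / 20, 0.35)
})
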