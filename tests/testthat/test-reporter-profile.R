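# Shared reporter fixture: uniform biomass, activation front at 0.1 mm.
.rep_cache <- new.env(parent = emptyenv())
reporter_fixture <- function() {
  if (is.null(.rep_cache$fx)) {
    sc <- test_scene()
    lm <- sc$disc$label_map
    times <- seq(0, 4 * 3600, length.out = 5)
    gen <- generate_biomass_stack(lm, times, 1.5, fill = "uniform",
                                  noise_sd = 0, seed = 21L)
    rep <- generate_reporter_stack(lm, gen, front_depth_mm = 0.1,
                                   steepness = 400, seed = 22L)
    corr <- preprocess_stack(gen$stack, lm)
    crep <- preprocess_stack(rep$stack, lm)
    .rep_cache$fx <- list(sc = sc, lm = lm, corr = corr, crep = crep,
                          gen = gen, rep = rep)
  }
  .rep_cache$fx
}

test_that("activity normalization is the reporter/biomass ratio where valid", {
  bio <- matrix(c(0, 2, 5, 10), 2, 2)
  rep0 <- matrix(0, 2, 2)
  a0 <- normalize_activity(rep0, bio, floor = 1)
  expect_true(all(a0$activity[a0$valid] == 0))
  expect_false(a0$valid[1L, 1L])
  a2 <- normalize_activity(2 * bio, bio, floor = 1)
  expect_true(all(abs(a2$activity[a2$valid] - 2) < 1e-12))
  expect_error(normalize_activity(rep0, bio, floor = 0), "positive")
  expect_error(normalize_activity(matrix(0, 3, 3), bio), "co-registered")
})

test_that("sigmoidal activation is recovered within a few percent", {
  fx <- reporter_fixture()
  act <- normalize_activity(fx$crep$frames[[5L]], fx$corr$frames[[5L]],
                            floor = 1)
  reg <- fx$lm$dep_regions[[1L]]
  deep <- reg$pixels[reg$depth_map_px[reg$pixels] * fx$lm$pixel_size / 1000 > 0.15]
  shallow <- reg$pixels[reg$depth_map_px[reg$pixels] * fx$lm$pixel_size / 1000 < 0.05]
  expect_gt(mean(act$activity[deep], na.rm = TRUE), 0.97)
  expect_lt(mean(act$activity[shallow], na.rm = TRUE), 0.03)
})

test_that("depth profiles sample every step and respect uniform fields", {
  fx <- reporter_fixture()
  # uniform activity map -> flat profile at that value
  dm <- dim(fx$lm$grid)
  uni <- structure(list(activity = matrix(0.7, dm[1L], dm[2L]),
                        valid = matrix(TRUE, dm[1L], dm[2L])),
                   class = "activity_map")
  prof <- dep_depth_profile(uni, fx$lm, fx$sc$disc$skeleton, fx$sc$disc$disks)
  expect_true(all(abs(prof$activity - 0.7) < 1e-12))
  # sample count ~ path length / step
  reg <- fx$lm$dep_regions[[1L]]
  smax <- max(reg$skeleton_depth_px[is.finite(reg$skeleton_depth_px)])
  expect_equal(nrow(prof[prof$dep_id == reg$dep_id, ]),
               floor(smax / 10) + 1L, tolerance = 2)
  expect_true(all(diff(prof$s_um[prof$dep_id == reg$dep_id]) > 0))
})

test_that("the activation front is recovered within one sampling step", {
  fx <- reporter_fixture()
  act <- normalize_activity(fx$crep$frames[[5L]], fx$corr$frames[[5L]],
                            floor = 1)
  prof <- dep_depth_profile(act, fx$lm, fx$sc$disc$skeleton, fx$sc$disc$disks)
  fronts <- extract_front(prof)
  step_mm <- 10 * fx$lm$pixel_size / 1000
  for (k in seq_len(nrow(fronts)))
    expect_lt(abs(fronts$zeta_mm[k] - 0.1), step_mm)
})

test_that("front extraction handles steps, constants and empty profiles", {
  prof <- tibble::tibble(dep_id = 1L, s_um = seq(0, 200, by = 10),
                         activity = as.numeric(seq(0, 200, by = 10) >= 120))
  expect_lt(abs(extract_front(prof)$zeta_mm - 0.115), 0.006)  # within the sample spacing
  const <- tibble::tibble(dep_id = 1L, s_um = c(0, 10, 20),
                          activity = c(0.4, 0.4, 0.4))
  expect_equal(extract_front(const)$zeta_mm, 0)
  zero <- tibble::tibble(dep_id = 2L, s_um = c(0, 10), activity = c(0, 0))
  out <- extract_front(zero)
  expect_true(is.na(out$zeta_mm))
  expect_false(out$detected)
})

test_that("raising near-entrance activity can only move the front inwards", {
  s <- seq(0, 200, by = 10)
  base_act <- 1 / (1 + exp(-(s - 100) / 10))
  z0 <- extract_front(tibble::tibble(dep_id = 1L, s_um = s,
                                     activity = base_act))$zeta_mm
  for (boost in c(0.05, 0.2, 0.5)) {
    act2 <- base_act + boost * exp(-s / 40)
    z2 <- extract_front(tibble::tibble(dep_id = 1L, s_um = s,
                                       activity = act2))$zeta_mm
    expect_lte(z2, z0 + 1e-12)
  }
})

test_that("profiles transform with the scene under mirroring", {
  fx <- reporter_fixture()
  lm <- fx$lm
  flip <- function(m) m[, ncol(m):1, drop = FALSE]
  mask_f <- pore_mask(flip(fx$sc$gen$mask$grid), pixel_size = lm$pixel_size)
  d_f <- discretize_pores(mask_f)
  act_grid <- normalize_activity(fx$crep$frames[[5L]], fx$corr$frames[[5L]],
                                 floor = 1)
  act_f <- structure(list(activity = flip(act_grid$activity),
                          valid = flip(act_grid$valid)),
                     class = "activity_map")
  prof <- dep_depth_profile(act_grid, lm, fx$sc$disc$skeleton,
                            fx$sc$disc$disks)
  prof_f <- dep_depth_profile(act_f, d_f$label_map, d_f$skeleton, d_f$disks)
  f0 <- extract_front(prof); f1 <- extract_front(prof_f)
  expect_equal(nrow(f0), nrow(f1))
  expect_equal(sort(f1$zeta_mm), sort(f0$zeta_mm),
               tolerance = 10 * lm$pixel_size / 1000 / min(f0$zeta_mm))
})
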