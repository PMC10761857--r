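make_uniform_stack <- function(lm, levels, channel = "brightfield") {
  dm <- dim(lm$grid)
  bg <- 20000
  frames <- c(list(matrix(bg, dm[1L], dm[2L])),
              lapply(levels, function(v) {
                f <- matrix(bg, dm[1L], dm[2L])
                f[lm$grid > 0L] <- bg - v
                f
              }))
  image_stack(frames, seq(0, by = 600, length.out = length(frames)),
              channel = channel, pixel_size = lm$pixel_size)
}

test_that("preprocessing subtracts the background, clips and masks", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  st <- make_uniform_stack(lm, c(100, 250))
  corr <- preprocess_stack(st, lm)
  expect_true(all(corr$frames[[1L]] == 0))
  expect_equal(unique(corr$frames[[2L]][lm$grid > 0L]), 100)
  expect_true(all(corr$frames[[3L]][lm$grid == 0L] == 0))
  # identical frames -> all-zero corrected stack
  st0 <- make_uniform_stack(lm, c(0, 0))
  corr0 <- preprocess_stack(st0, lm)
  for (f in corr0$frames) expect_true(all(f == 0))
  # shape mismatch is a registration error
  bad <- image_stack(list(matrix(0, 5, 5), matrix(1, 5, 5)), c(0, 1))
  expect_error(preprocess_stack(bad, lm), "registration")
})

test_that("cluster detection finds planted spots and returns empty sets cleanly", {
  fr <- matrix(0, 60, 80)
  fr[18:22, 18:22] <- 50
  fr[40:46, 55:61] <- 50
  region <- seq_len(60 * 80)
  cl <- detect_clusters(fr, region, pixel_size = 1)
  expect_equal(nrow(cl), 2L)
  expect_equal(unname(sort(cl$area_px)), c(25L, 49L))
  expect_equal(sum(cl$intensity), sum(fr))
  expect_true(all(cl$mass_per_area == 50))
  # flat zero frame: empty cluster set, not an error
  cl0 <- detect_clusters(matrix(0, 30, 30), seq_len(900))
  expect_equal(nrow(cl0), 0L)
  expect_error(detect_clusters(fr, integer(0)), "empty region")
})

test_that("noise-free generator scenes are recovered exactly by cluster detection", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  times <- seq(0, 3600 * 4, length.out = 5)
  gen <- generate_biomass_stack(lm, times, 1.8, clusters_per_dep = 2,
                                noise_sd = 0, seed = 9L)
  corr <- preprocess_stack(gen$stack, lm)
  fr <- corr$frames[[5L]]
  reg <- lm$dep_regions[[1L]]
  cl <- detect_clusters(fr, reg$pixels, lm$pixel_size)
  planted <- sum(gen$truth$centers$region == "dep")
  expect_equal(nrow(cl), planted)
  # integrated cluster mass equals the deposited signal inside the DEP
  expect_equal(sum(cl$intensity), sum(gen$truth$signal[[5L]][reg$pixels]),
               tolerance = 1e-10)
})

test_that("uniform intensity gives retention ratio 1 and partition = area fraction", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  corr <- preprocess_stack(make_uniform_stack(lm, c(120, 300)), lm)
  rc <- retention_curve(corr, lm)
  expect_equal(rc$ratio[-1L], c(1, 1), tolerance = 1e-12)
  bs <- biomass_timeseries(corr, lm)
  f_dep <- sum(lm$grid == 1L) / sum(lm$grid > 0L)
  expect_equal(bs$dep_partition[-1L], rep(f_dep, 2), tolerance = 1e-12)
  # DEP at twice the TP intensity -> ratio exactly 2
  dm <- dim(lm$grid)
  bg <- 20000
  f2 <- matrix(bg, dm[1L], dm[2L])
  f2[lm$grid == 2L] <- bg - 100
  f2[lm$grid == 1L] <- bg - 200
  st2 <- image_stack(list(matrix(bg, dm[1L], dm[2L]), f2), c(0, 600),
                     pixel_size = lm$pixel_size)
  rc2 <- retention_curve(preprocess_stack(st2, lm), lm)
  expect_equal(rc2$ratio[2L], 2, tolerance = 1e-12)
})

test_that("biomass series is additive and equivariant under intensity scaling", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  gen <- generate_biomass_stack(lm, seq(0, 7200, length.out = 4),
                                c(1, 1.4, 1.9, 2.5), noise_sd = 0, seed = 3L)
  corr <- preprocess_stack(gen$stack, lm)
  bs <- biomass_timeseries(corr, lm)
  expect_equal(bs$b_tot, bs$b_tp + bs$b_dep, tolerance = 1e-12)
  scaled <- corr
  scaled$frames <- lapply(corr$frames, function(f) 3.7 * f)
  rc <- retention_curve(corr, lm); rcs <- retention_curve(scaled, lm)
  expect_equal(rcs$ratio, rc$ratio, tolerance = 1e-12)
  bss <- biomass_timeseries(scaled, lm)
  expect_equal(bss$b_tot, 3.7 * bs$b_tot, tolerance = 1e-12)
  expect_equal(bss$dep_partition, bs$dep_partition, tolerance = 1e-12)
})

test_that("all biomass inside DEPs gives partition one", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  dm <- dim(lm$grid)
  bg <- 20000
  f <- matrix(bg, dm[1L], dm[2L])
  f[lm$grid == 1L] <- bg - 500
  st <- image_stack(list(matrix(bg, dm[1L], dm[2L]), f), c(0, 600),
                    pixel_size = lm$pixel_size)
  bs <- biomass_timeseries(preprocess_stack(st, lm), lm)
  expect_equal(bs$dep_partition[2L], 1)
})

test_that("colony mass density integrates to one and tracks growth", {
  cl <- tibble::tibble(
    time_s = rep(c(0, 600, 1200), each = 40),
    mass_per_area = c(stats::rlnorm(40, log(10), 0.2),
                      stats::rlnorm(40, log(25), 0.2),
                      stats::rlnorm(40, log(60), 0.2)))
  pdf <- colony_mass_pdf(cl, bins = 32)
  for (t in unique(pdf$time_s)) {
    sub <- pdf[pdf$time_s == t, ]
    brk_w <- diff(exp(seq(log(min(cl$mass_per_area) * 0.999),
                          log(max(cl$mass_per_area) * 1.001),
                          length.out = 33)))
    expect_equal(sum(sub$density * brk_w), 1, tolerance = 1e-6)
  }
  modes <- vapply(split(pdf, pdf$time_s), function(s)
    s$mass_per_area[which.max(s$density)], numeric(1))
  expect_true(all(diff(modes[order(as.numeric(names(modes)))]) > 0))
  # identical clusters: degenerate density flagged
  expect_warning(colony_mass_pdf(tibble::tibble(time_s = 0,
                                                mass_per_area = rep(5, 4))),
                 "degenerate")
})

test_that("replicate stacks are aggregated with mean and sd", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  times <- c(0, 600, 1200)
  reps <- lapply(1:3, function(k)
    preprocess_stack(generate_biomass_stack(lm, times, c(1, 1.5, 2),
                                            noise_sd = 10, seed = 5L,
                                            noise_seed = k)$stack, lm))
  rc <- retention_curve(reps, lm)
  expect_true(all(c("ratio", "ratio_sd") %in% names(rc)))
  expect_true(all(rc$ratio_sd[-1L] > 0))
  expect_equal(rc$ratio[-1L], c(1.5, 2), tolerance = 0.05)
})
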