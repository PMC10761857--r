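test_that("maximum inscribed disk map equals brute-force nearest-solid distance", {
  set.seed(42)
  for (k in 1:4) {
    g <- matrix(rbinom(64 * 64, 1, 0.7), 64, 64)
    if (all(g == 1L)) g[1, 1] <- 0L
    m <- pore_mask(g, pixel_size = 1.3)
    dm <- max_inscribed_disk_map(m)
    expect_equal(dm$radius_px, brute_nearest_solid(m), tolerance = 1e-12)
    expect_true(all(dm$radius_um[m$grid == 0L] == 0))
  }
  # closed forms: straight channel and circular pore
  ch <- channel_mask(w = 21L, len = 40L)
  dm <- max_inscribed_disk_map(ch)
  centre_row <- 4L + 11L
  expect_equal(max(dm$radius_px[centre_row, 20L]), 11)  # (w+1)/2 = w/2 + half px
  circ <- matrix(0L, 41, 41)
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 15^2) circ[i, j] <- 1L
  dmc <- max_inscribed_disk_map(pore_mask(circ, 1))
  expect_true(abs(dmc$radius_px[21, 21] - 15.5) <= 1)  # R to R + 1 px (solid centres)
})

test_that("grain labelling matches an independent flood fill and handles degenerate input", {
  g <- matrix(1L, 40, 40)
  g[5:10, 5:10] <- 0L; g[25:32, 20:30] <- 0L
  gl <- label_grains(pore_mask(g, 1))
  expect_equal(gl$n_grains, 2L)
  frame <- matrix(0L, 20, 20); frame[8:12, 3:18] <- 1L
  expect_equal(label_grains(pore_mask(frame, 1))$n_grains, 1L)
  expect_error(label_grains(pore_mask(matrix(1L, 10, 10), 1)), "degenerate")
  expect_error(label_grains(pore_mask(matrix(0L, 10, 10), 1)), "degenerate")
  sc <- test_scene()
  expect_equal(sc$disc$grains$n_grains,
               brute_component_count(sc$gen$mask$grid == 0L))
})

test_that("skeleton is 1 px wide, preserves connectivity and measures arc length", {
  ch <- channel_mask(w = 15L, len = 50L)
  sk <- skeletonize_pores(ch)
  # centreline: one skeleton pixel per column away from the end spurs,
  # on the middle row
  mid_cols <- 14:36
  expect_true(all(colSums(sk$grid[, mid_cols]) == 1))
  rows <- apply(sk$grid[, mid_cols], 2, which.max)
  expect_true(all(abs(rows - (4 + 8)) <= 1))
  # topology: skeleton components = pore components
  g <- matrix(0L, 60, 60)
  g[5:15, 5:55] <- 1L; g[35:45, 5:55] <- 1L      # two disjoint channels
  m2 <- pore_mask(g, 1)
  sk2 <- skeletonize_pores(m2)
  sk_comp <- attr(cpp_label(matrix(as.integer(sk2$grid), 60, 60), 8L), "n")
  pore_comp <- attr(cpp_label(m2$grid, 4L), "n")
  expect_equal(sk_comp, pore_comp)
  # L-shaped channel: arc length ~ sum of leg lengths
  gL <- matrix(0L, 80, 80)
  gL[10:20, 10:70] <- 1L; gL[10:70, 10:20] <- 1L
  skL <- skeletonize_pores(pore_mask(gL, 1))
  pts <- which(skL$grid)
  ends <- pts[c(which.max(arrayInd(pts, dim(gL))[, 2L]),
                which.max(arrayInd(pts, dim(gL))[, 1L]))]
  dist <- cpp_geodesic(skL$grid, ends[1L])
  arc <- dist[ends[2L]]
  ij1 <- arrayInd(ends[1L], dim(gL)); ij2 <- arrayInd(ends[2L], dim(gL))
  legs <- abs(ij2[1L] - ij1[1L]) + abs(ij2[2L] - ij1[2L])
  expect_lt(abs(arc - legs), 8)  # corner diagonal shortcut
})

test_that("segregation index separates single-grain cavities from channels", {
  # channel between two distinct grains: zeta = 2 on the centreline
  ch <- channel_mask(w = 15L, len = 60L)
  d <- discretize_pores(ch)
  mid <- d$skeleton$points[d$skeleton$points$j > 10 & d$skeleton$points$j < 50, ]
  expect_true(all(mid$zeta_seg >= 2))
  # cavity carved inside one grain: zeta = 1 inside the cavity
  cc <- channel_with_cavity()
  dd <- discretize_pores(cc$mask)
  pts <- dd$skeleton$points
  incav <- pts$i > cc$cavity_rows[1L] + 12
  expect_true(all(pts$zeta_seg[incav] == 1))
})

test_that("classification labels a deep side cavity DEP and a plain channel TP", {
  ch <- channel_mask(w = 15L, len = 60L)
  d <- discretize_pores(ch)
  expect_equal(sum(d$label_map$grid == 1L), 0L)
  expect_equal(sum(d$label_map$grid == 2L), sum(ch$grid))
  cc <- channel_with_cavity(cav_depth = 60L, cav_w = 20L)
  dd <- discretize_pores(cc$mask)
  expect_equal(length(dd$label_map$dep_regions), 1L)
  # cavity interior (away from the mouth) is all DEP; channel far from the
  # mouth is all TP
  grid <- dd$label_map$grid
  cav_core <- grid[(cc$cavity_rows[1L] + 25):(cc$cavity_rows[2L] - 2),
                   (cc$cavity_cols[1L] + 2):(cc$cavity_cols[2L] - 2)]
  expect_true(all(cav_core == 1L))
  chan_far <- grid[cc$channel_rows[1L]:cc$channel_rows[2L], 1:30]
  expect_true(all(chan_far == 2L))
})

test_that("classification commutes with rotation and mirroring of the mask", {
  # raster thinning is not exactly isotropic, so agreement is required on
  # all but a sliver of mouth-boundary pixels
  cc <- channel_with_cavity(cav_depth = 50L, cav_w = 18L, len = 90L)
  based <- discretize_pores(cc$mask)
  base <- based$label_map$grid
  # mask of pixels within one cavity width of the mouth line, where the
  # DEP/TP boundary legitimately wiggles with orientation
  mouth <- matrix(FALSE, nrow(base), ncol(base))
  mouth[(cc$cavity_rows[1L] - 19L):(cc$cavity_rows[1L] + 19L),
        (cc$cavity_cols[1L] - 19L):(cc$cavity_cols[2L] + 19L)] <- TRUE
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  rotd <- discretize_pores(pore_mask(rot90(cc$mask$grid), 1))
  ref <- rot90(base); refmouth <- rot90(mouth)
  away <- ref > 0L & !refmouth
  expect_identical(rotd$label_map$grid > 0L, ref > 0L)
  expect_true(all(rotd$label_map$grid[away] == ref[away]))
  expect_equal(nrow(rotd$label_map$deps), nrow(based$label_map$deps))
  mir <- discretize_pores(pore_mask(cc$mask$grid[, ncol(cc$mask$grid):1], 1))
  refm <- base[, ncol(base):1]
  awaym <- refm > 0L & !mouth[, ncol(mouth):1]
  expect_true(all(mir$label_map$grid[awaym] == refm[awaym]))
})

test_that("pore statistics recover construction quantities", {
  ch <- channel_mask(w = 20L, len = 60L, pixel_size = 2)
  d <- discretize_pores(ch)
  st <- d$stats
  # lambda_m = channel width (within the half-pixel tangency convention)
  expect_equal(st$lambda_m_um, 20 * 2, tolerance = 0.08)
  # constructed 60 px cavity at 1 um/px: depth within 2 px
  cc <- channel_with_cavity(cav_depth = 100L, cav_w = 24L, len = 140L,
                            pixel_size = 0.65)
  dd <- discretize_pores(cc$mask)
  expect_equal(nrow(dd$label_map$deps), 1L)
  expect_equal(dd$label_map$deps$depth_mm * 1000, 100 * 0.65, tolerance = 4 * 0.65)
  # closed loop with the generator: DEP fraction near target, pure geometry
  sc <- test_scene()
  expect_lt(abs(sc$disc$stats$dep_volume_fraction - 0.08), 0.035)
  expect_equal(sc$disc$stats$porosity, porosity(sc$gen$mask))
})

test_that("label partition covers the grid and is disjoint", {
  sc <- test_scene()
  lm <- sc$disc$label_map
  expect_true(all(lm$grid %in% 0:2))
  expect_equal(sum(lm$grid > 0L), sum(sc$gen$mask$grid == 1L))
  # every DEP region touches TP at its entrance
  for (reg in lm$dep_regions) {
    expect_false(reg$unreachable)
    expect_gt(length(reg$entrance), 0L)
  }
})
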