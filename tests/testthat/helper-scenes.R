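# Shared fixtures, built once per test run.

.scene_cache <- new.env(parent = emptyenv())

# Default synthetic scene used across modules: 300 x 400 px at 2.6 um/px,
# one ~0.2 mm deep cavity, fully discretized.
test_scene <- function() {
  if (is.null(.scene_cache$scene)) {
    gp <- geometry_params(domain_size_px = c(300L, 400L), pixel_size = 2.6,
                          seed = 1L)
    g <- generate_geometry(gp)
    d <- discretize_pores(g$mask)
    .scene_cache$scene <- list(gen = g, disc = d)
  }
  .scene_cache$scene
}

# Straight horizontal channel of width w (rows), length len, 1 um/px.
channel_mask <- function(w = 20L, len = 60L, pad = 4L, pixel_size = 1) {
  g <- matrix(0L, w + 2L * pad, len)
  g[(pad + 1L):(pad + w), ] <- 1L
  pore_mask(g, pixel_size = pixel_size)
}

# Horizontal channel with one rectangular side cavity (depth x width px)
# carved downward from the channel floor.
channel_with_cavity <- function(chan_w = 16L, len = 120L, cav_depth = 60L,
                                cav_w = 20L, pixel_size = 1) {
  nr <- chan_w + cav_depth + 16L
  g <- matrix(0L, nr, len)
  g[5:(4L + chan_w), ] <- 1L                       # channel
  j0 <- len %/% 2L - cav_w %/% 2L
  g[(4L + chan_w + 1L):(4L + chan_w + cav_depth), j0:(j0 + cav_w - 1L)] <- 1L
  list(mask = pore_mask(g, pixel_size = pixel_size),
       cavity_rows = c(4L + chan_w + 1L, 4L + chan_w + cav_depth),
       cavity_cols = c(j0, j0 + cav_w - 1L),
       channel_rows = c(5L, 4L + chan_w))
}

# O(N^2) brute-force Euclidean distance from every pixel to the nearest
# solid pixel (the independent oracle for the disk map).
brute_nearest_solid <- function(mask) {
  g <- mask$grid
  solid <- which(g == 0L)
  ij_s <- arrayInd(solid, dim(g))
  out <- matrix(0, nrow(g), ncol(g))
  for (p in which(g == 1L)) {
    ij <- arrayInd(p, dim(g))
    out[p] <- sqrt(min((ij_s[, 1L] - ij[1L])^2 + (ij_s[, 2L] - ij[2L])^2))
  }
  out
}

# Independent flood-fill component count (8-connectivity).
brute_component_count <- function(binary) {
  lab <- matrix(0L, nrow(binary), ncol(binary))
  n <- 0L
  for (start in which(binary & lab == 0L)) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      ij <- arrayInd(p, dim(binary))
      for (di in -1:1) for (dj in -1:1) {
        qi <- ij[1L] + di; qj <- ij[2L] + dj
        if (qi < 1L || qi > nrow(binary) || qj < 1L || qj > ncol(binary)) next
        q <- qi + (qj - 1L) * nrow(binary)
        if (binary[q] && lab[q] == 0L) { lab[q] <- n; queue <- c(queue, q) }
      }
    }
  }
  n
}
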