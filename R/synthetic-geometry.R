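#' Parameters for the synthetic geometry generator
#'
#' Defaults mirror the reference microfluidic medium: 0.65 um pixels, mean
#' pore size 0.04 mm, dead-end cavities 0.2 mm deep occupying ~8% of the
#' pore volume, and cavities deeper than wide (aspect > 1) so that they
#' classify as dead-end pores under the inscribed-disk rule.
#'
#' @param domain_size_px Integer pair (rows, cols).
#' @param pixel_size Micrometres per pixel.
#' @param target_porosity Pore fraction of the domain the channel lattice
#'   aims for.
#' @param target_dep_fraction Target DEP share of pore pixels.
#' @param mean_pore_size Mean transmitting-pore width, mm.
#' @param mean_dep_depth Mean cavity depth, mm.
#' @param cavity_aspect Cavity depth/width ratio (> 1).
#' @param seed Integer seed; identical seeds give bit-identical masks.
#' @return A `geometry_params` list.
#' @export
geometry_params <- function(domain_size_px = c(960L, 1408L),
                            pixel_size = 0.65,
                            target_porosity = 0.28,
                            target_dep_fraction = 0.08,
                            mean_pore_size = 0.04,
                            mean_dep_depth = 0.2,
                            cavity_aspect = 2.5,
                            seed = 1L) {
  p <- list(domain_size_px = as.integer(domain_size_px),
            pixel_size = pixel_size,
            target_porosity = target_porosity,
            target_dep_fraction = target_dep_fraction,
            mean_pore_size = mean_pore_size,
            mean_dep_depth = mean_dep_depth,
            cavity_aspect = cavity_aspect,
            seed = as.integer(seed))
  if (any(p$domain_size_px < 256L))
    stop("domain must be at least 256 x 256 px")
  if (p$target_porosity <= 0 || p$target_porosity >= 1)
    stop("target_porosity must lie in (0, 1)")
  if (p$target_dep_fraction <= 0 || p$target_dep_fraction >= p$target_porosity)
    stop("target_dep_fraction must be positive and below the porosity proxy")
  if (p$cavity_aspect <= 1)
    stop("cavity_aspect must exceed 1 (cavities deeper than wide)")
  if (p$pixel_size <= 0) stop("pixel_size must be positive")
  class(p) <- "geometry_params"
  p
}

# Evaluate `expr` under a locally seeded RNG, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# Stadium (rounded-end slot) rasterization: pixels within `radius` of the
# segment (i0,j0)-(i1,j1). Returns a logical matrix sized like dm.
stadium_pixels <- function(dm, i0, j0, i1, j1, radius) {
  lo_i <- max(1L, floor(min(i0, i1) - radius)); hi_i <- min(dm[1L], ceiling(max(i0, i1) + radius))
  lo_j <- max(1L, floor(min(j0, j1) - radius)); hi_j <- min(dm[2L], ceiling(max(j0, j1) + radius))
  out <- matrix(FALSE, dm[1L], dm[2L])
  if (lo_i > hi_i || lo_j > hi_j) return(out)
  ii <- lo_i:hi_i; jj <- lo_j:hi_j
  I <- matrix(ii, length(ii), length(jj))
  J <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  vx <- i1 - i0; vy <- j1 - j0
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((I - i0) * vx + (J - j0) * vy) / len2))
  d2 <- (I - (i0 + t * vx))^2 + (J - (j0 + t * vy))^2
  out[cbind(as.vector(I), as.vector(J))] <- as.vector(d2 <= radius^2)
  out
}

#' Generate a synthetic porous geometry with known DEP/TP truth
#'
#' Builds a jittered lattice of solid grain blocks separated by transmitting
#' channels (mean width = `mean_pore_size`), bounded by solid frame bars at
#' the top and bottom walls, and carves stadium-shaped cavities (depth/width
#' = `cavity_aspect`) into grains, opening into a channel. Carved pixels are
#' recorded at construction time, so the ground-truth label map comes for
#' free. Cavities are added until the DEP share of pore pixels is within
#' 0.02 of `target_dep_fraction`.
#'
#' @param params A [geometry_params()].
#' @return List with `mask` (a [pore_mask()]) and `truth`, a list holding
#'   `label_grid` (0 solid / 1 DEP / 2 TP), `dep_fraction`, `porosity`,
#'   `cavities` (tibble: per-cavity mouth position, depth and width in px
#'   and mm), `entrance_idx` (list of per-cavity mouth pixel indices) and
#'   the generating `params`.
#' @export
generate_geometry <- function(params = geometry_params()) {
  stopifnot(inherits(params, "geometry_params"))
  with_local_seed(params$seed, generate_geometry_impl(params))
}

generate_geometry_impl <- function(params) {
  dm <- params$domain_size_px
  nr <- dm[1L]; nc <- dm[2L]
  w_c <- params$mean_pore_size * 1000 / params$pixel_size       # channel width, px
  d_px <- params$mean_dep_depth * 1000 / params$pixel_size      # cavity depth, px
  cav_w <- d_px / params$cavity_aspect                          # cavity width, px
  if (w_c < 3) stop("mean_pore_size below 3 px at this pixel_size")
  phi <- params$target_porosity
  g <- w_c * (1 / (1 - sqrt(1 - phi)) - 1)                      # grain size, px
  tb <- max(3L, round(w_c / 2))                                 # frame bar thickness

  # horizontal channel stripes: frame | channel | grain | channel | ... | frame
  interior <- nr - 2L * tb
  n_bands <- max(1L, floor((interior - w_c) / (g + w_c)))       # grain bands
  # rows: n_bands grain bands, n_bands + 1 channels
  widths_ch <- pmax(3, round(w_c * stats::runif(n_bands + 1L, 0.85, 1.15)))
  gh_total <- interior - sum(widths_ch)
  if (gh_total < n_bands * 4) stop("domain too small for this porosity/pore size")
  gh <- diff(round(seq(0, gh_total, length.out = n_bands + 1L)))
  gh <- pmax(4L, gh)

  grid <- matrix(0L, nr, nc)                                    # start all solid
  pos <- tb
  bands <- list()                                               # grain bands (row ranges)
  for (b in seq_len(n_bands + 1L)) {
    ch <- widths_ch[b]
    grid[(pos + 1L):(pos + ch), ] <- 1L                         # horizontal channel
    pos <- pos + ch
    if (b <= n_bands) {
      bands[[b]] <- c(pos + 1L, pos + gh[b])
      pos <- pos + gh[b]
    }
  }
  # vertical channels inside each grain band, staggered
  blocks <- list()
  for (b in seq_len(n_bands)) {
    r0 <- bands[[b]][1L]; r1 <- bands[[b]][2L]
    n_v <- max(1L, round((nc - g) / (g + w_c)))
    offs <- stats::runif(1, 0, (nc - 1) / (n_v + 1L) * 0.5)
    centers <- round(offs + (nc) * seq_len(n_v) / (n_v + 1L))
    wv <- pmax(3L, round(w_c * stats::runif(n_v, 0.85, 1.15)))
    prev <- 1L
    for (v in seq_len(n_v)) {
      j0 <- max(1L, centers[v] - wv[v] %/% 2L)
      j1 <- min(nc, j0 + wv[v] - 1L)
      grid[r0:r1, j0:j1] <- 1L
      if (j0 - 1L >= prev)
        blocks[[length(blocks) + 1L]] <- c(r0, r1, prev, j0 - 1L)
      prev <- j1 + 1L
    }
    if (prev <= nc)
      blocks[[length(blocks) + 1L]] <- c(r0, r1, prev, nc)
  }

  pore0 <- sum(grid == 1L)
  f <- params$target_dep_fraction
  area_target <- f / (1 - f) * pore0                            # total cavity pixels wanted
  area_one <- d_px * cav_w * 0.95                               # approx stadium area

  # candidate carves: one per block, opening north or south into a channel
  ord <- sample(seq_along(blocks))
  truth <- grid * 2L                                            # 2 = TP for now
  cav_rows <- list(); entrance_idx <- list()
  carved <- 0
  for (bi in ord) {
    remaining <- area_target - carved
    if (remaining < area_one * 0.25) break
    blk <- blocks[[bi]]
    r0 <- blk[1L]; r1 <- blk[2L]; c0 <- blk[3L]; c1 <- blk[4L]
    depth <- d_px * stats::runif(1, 0.9, 1.1)
    # shrink the last cavity so the total DEP area lands on target
    if (remaining < 0.8 * area_one) {
      depth_fit <- sqrt(remaining * params$cavity_aspect / 0.95)
      depth <- max(depth_fit, 0.5 * d_px)
    }
    width <- depth / params$cavity_aspect
    if ((r1 - r0 + 1L) < depth + 4) next                        # back wall >= 4 px
    if ((c1 - c0 + 1L) < width + 18) next                       # side walls >= 8 px
    side <- sample(c("N", "S"), 1L)
    cj <- stats::runif(1, c0 + width / 2 + 8, c1 - width / 2 - 8)
    if (side == "N") { i0 <- r0; i1 <- r0 + depth - width / 2 } else
                     { i0 <- r1; i1 <- r1 - depth + width / 2 }
    slot <- stadium_pixels(c(nr, nc), i0, cj, i1, cj, width / 2)
    # clip the mouth cap at the grain face: flush opening, rounded tip only
    if (side == "N") slot[seq_len(min(nr, max(0L, r0 - 1L))), ] <- FALSE else
      if (r1 < nr) slot[(r1 + 1L):nr, ] <- FALSE
    new_pore <- slot & grid == 0L
    n_new <- sum(new_pore)
    if (n_new < 10) next
    grid[new_pore] <- 1L
    truth[new_pore] <- 1L                                       # 1 = DEP truth
    # mouth pixels: carved pixels on the channel-facing row of the block
    mouth_row <- if (side == "N") r0 else r1
    mouth <- which(new_pore[mouth_row, ])
    entrance_idx[[length(entrance_idx) + 1L]] <-
      mouth_row + (mouth - 1L) * nr
    carved <- carved + n_new
    cav_rows[[length(cav_rows) + 1L]] <- tibble::tibble(
      block = bi, side = side,
      mouth_i = mouth_row, mouth_j = round(cj),
      depth_px = depth, width_px = width,
      depth_mm = depth * params$pixel_size / 1000,
      area_px = n_new)
  }
  achieved <- carved / sum(grid == 1L)
  if (abs(achieved - f) > 0.02)
    stop(sprintf(paste0("infeasible target_dep_fraction: achieved %.3f vs ",
                        "target %.3f (domain too small or porosity too high ",
                        "for the requested cavity size)"), achieved, f))

  mask <- pore_mask(grid, pixel_size = params$pixel_size)
  if (!percolates(mask)) stop("generated mask does not percolate inlet-to-outlet")
  cavities <- if (length(cav_rows)) do.call(rbind, cav_rows) else
    tibble::tibble(block = integer(), side = character(), mouth_i = integer(),
                   mouth_j = integer(), depth_px = numeric(),
                   width_px = numeric(), depth_mm = numeric(),
                   area_px = integer())
  list(mask = mask,
       truth = list(label_grid = truth, dep_fraction = achieved,
                    porosity = mean(grid == 1L), cavities = cavities,
                    entrance_idx = entrance_idx, params = params))
}
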