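#' Generate a synthetic bright-field biomass stack with known truth
#'
#' Renders biomass as additive attenuation of a constant bright background
#' (cells darken the image) with optional Gaussian read noise. Biomass is
#' deposited as flat circular colonies planted inside the DEP and TP
#' regions; per frame, the colony intensities are scaled so that the
#' area-normalized mean intensity ratio `C_dep / C_tp` equals the imposed
#' truth curve exactly (before noise). Frame 1 is the pre-injection
#' background frame.
#'
#' @param label_map A [classify_pores()] result (or the generator's truth
#'   label grid wrapped via [label_map_from_truth()]).
#' @param times Frame times in seconds (frame 1 = background).
#' @param ratio_curve DEP/TP concentration ratio per frame (recycled if
#'   scalar); entry 1 is ignored.
#' @param amplitude Mean TP intensity per frame (recycled); entry 1 ignored.
#'   Default: linear ramp to 500 intensity units.
#' @param clusters_per_dep,clusters_tp Number of planted colonies.
#' @param cluster_radius_px Colony radius.
#' @param fill `"colonies"` (flat circular colonies) or `"uniform"` (fill
#'   each pore class uniformly; useful for reporter scenes and closed-loop
#'   checks).
#' @param background Bright-field background level (default 20000).
#' @param noise_sd Gaussian read-noise standard deviation in intensity units
#'   (default 0; the reference noise level is not reported, so it is fully
#'   configurable).
#' @param seed Integer seed for colony placement.
#' @param noise_seed Separate seed for the read noise (default `seed + 1000`),
#'   so one placement can be replicated under independent noise draws.
#' @return List with `stack` (raw [image_stack()]), and `truth`: `ratio`
#'   (per frame), `amplitude`, `centers` (tibble: colony positions, region,
#'   per-frame mass scale), `signal` (list of noiseless deposited-signal
#'   frames), `noise_sd`, `saturated` (logical).
#' @export
generate_biomass_stack <- function(label_map, times, ratio_curve,
                                   amplitude = NULL,
                                   clusters_per_dep = 3, clusters_tp = 12,
                                   cluster_radius_px = 6,
                                   fill = c("colonies", "uniform"),
                                   background = 20000, noise_sd = 0,
                                   seed = 1L, noise_seed = NULL) {
  fill <- match.arg(fill)
  if (is.null(noise_seed)) noise_seed <- seed + 1000L
  stopifnot(inherits(label_map, "pore_label_map"))
  nf <- length(times)
  if (nf < 2L) stop("need at least a background frame and one signal frame")
  ratio <- rep_len(ratio_curve, nf)
  if (is.null(amplitude)) amplitude <- seq(0, 500, length.out = nf)
  amp <- rep_len(amplitude, nf)
  ratio[1L] <- NA_real_; amp[1L] <- 0
  dm <- dim(label_map$grid)
  dep <- which(label_map$grid == 1L); tp <- which(label_map$grid == 2L)
  if (!length(dep) || !length(tp)) stop("label map must contain both classes")

  with_local_seed(seed, {
    plant <- function(region_idx, k, r) {
      # colony centres at least r+1 px inside the region
      inreg <- matrix(FALSE, dm[1L], dm[2L]); inreg[region_idx] <- TRUE
      dedge <- sqrt(cpp_edt(!inreg)$dist2)
      cand <- region_idx[dedge[region_idx] >= r + 1]
      if (!length(cand)) { cand <- region_idx; r <- 1 }
      centers <- sample(cand, min(k, length(cand)))
      pat <- matrix(0, dm[1L], dm[2L])
      for (cc in centers) {
        ij <- arrayInd(cc, dm)
        disk <- stadium_pixels(dm, ij[1L], ij[2L], ij[1L], ij[2L], r)
        pat[disk & inreg] <- 1
      }
      list(pattern = pat, centers = centers, radius = r)
    }
    if (fill == "uniform") {
      ptp <- matrix(0, dm[1L], dm[2L]); ptp[tp] <- 1
      pdep <- matrix(0, dm[1L], dm[2L]); pdep[dep] <- 1
      pat_tp <- list(pattern = ptp, centers = integer(0))
      pat_dep <- list(pattern = pdep, centers = integer(0))
    } else {
      pat_tp <- plant(tp, clusters_tp, cluster_radius_px)
      pat_dep <- list(pattern = matrix(0, dm[1L], dm[2L]),
                      centers = integer(0), radius = cluster_radius_px)
      for (reg in label_map$dep_regions) {
        p <- plant(reg$pixels, clusters_per_dep, cluster_radius_px)
        pat_dep$pattern <- pmax(pat_dep$pattern, p$pattern)
        pat_dep$centers <- c(pat_dep$centers, p$centers)
      }
    }
    s_tp <- sum(pat_tp$pattern); s_dep <- sum(pat_dep$pattern)
    if (s_tp == 0 || s_dep == 0) stop("failed to plant colonies")

    saturated <- FALSE
    signal <- vector("list", nf)
    frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      if (f == 1L) {
        sig <- matrix(0, dm[1L], dm[2L])
      } else {
        a_tp <- amp[f] * length(tp) / s_tp
        a_dep <- amp[f] * ratio[f] * length(dep) / s_dep
        sig <- a_tp * pat_tp$pattern + a_dep * pat_dep$pattern
        if (max(sig) > background) saturated <- TRUE
      }
      signal[[f]] <- sig
      frames[[f]] <- background - sig
    }
    if (noise_sd > 0) {
      frames <- with_local_seed(noise_seed, lapply(frames, function(fr)
        fr + matrix(stats::rnorm(prod(dm), 0, noise_sd), dm[1L], dm[2L])))
    }
    frames <- lapply(frames, function(fr) pmin(pmax(fr, 0), 65535))
    if (saturated)
      warning("requested biomass exceeds background attenuation capacity")
    centers <- tibble::tibble(
      idx = c(pat_tp$centers, pat_dep$centers),
      region = rep(c("tp", "dep"),
                   c(length(pat_tp$centers), length(pat_dep$centers))))
    ij <- arrayInd(centers$idx, dm)
    centers$y <- ij[, 1L]; centers$x <- ij[, 2L]
    list(stack = image_stack(frames, times, channel = "brightfield",
                             pixel_size = label_map$pixel_size),
         truth = list(ratio = ratio, amplitude = amp, centers = centers,
                      signal = signal, noise_sd = noise_sd,
                      cluster_radius_px = cluster_radius_px,
                      saturated = saturated))
  })
}

#' Wrap a generator truth label grid as a pore label map
#'
#' Builds the per-DEP region records (entrances, geodesic depth maps) from a
#' ground-truth {0 solid, 1 DEP, 2 TP} grid, so generated scenes can be
#' quantified against their own construction truth without running the
#' classifier.
#'
#' @param truth A `generate_geometry()` truth list (or a 0/1/2 grid).
#' @param pixel_size Micrometres per pixel (taken from the truth params when
#'   available).
#' @return A `pore_label_map`.
#' @export
label_map_from_truth <- function(truth, pixel_size = NULL) {
  grid <- if (is.matrix(truth)) truth else truth$label_grid
  if (is.null(pixel_size))
    pixel_size <- if (!is.matrix(truth)) truth$params$pixel_size else 0.65
  dm <- dim(grid)
  mask <- pore_mask(grid > 0L, pixel_size = pixel_size)
  skeleton <- skeletonize_pores(mask)
  dep_lab <- cpp_label(matrix(as.integer(grid == 1L), dm[1L], dm[2L]), 4L)
  px_mm <- pixel_size / 1000
  dep_regions <- list()
  for (k in seq_len(attr(dep_lab, "n"))) {
    pix <- which(dep_lab == k)
    reg <- measure_dep_region(pix, grid, skeleton, dm)
    reg$dep_id <- length(dep_regions) + 1L
    reg$depth_mm <- reg$depth_px * px_mm
    dep_regions[[reg$dep_id]] <- reg
  }
  deps <- tibble::tibble(
    dep_id = seq_along(dep_regions),
    area_px = vapply(dep_regions, function(r) r$area_px, integer(1)),
    depth_mm = vapply(dep_regions, function(r) r$depth_mm, numeric(1)),
    entrance_x = NA_real_, entrance_y = NA_real_,
    unreachable = vapply(dep_regions, function(r) r$unreachable, logical(1)))
  structure(list(grid = grid, dep_regions = dep_regions, deps = deps,
                 pixel_size = pixel_size),
            class = "pore_label_map")
}

#' Generate a synthetic QS-reporter (GFP) stack
#'
#' The reporter signal equals the biomass signal multiplied by a sigmoidal
#' activation along each DEP: low near the entrance, high beyond the
#' activation front at depth `front_depth_mm`. Activation in transmitting
#' pores is zero (QS stays repressed under flow).
#'
#' @param label_map The [classify_pores()] / [label_map_from_truth()] map.
#' @param biomass A `generate_biomass_stack()` result (its noiseless signal
#'   frames are used).
#' @param front_depth_mm Activation front depth from the DEP entrance, mm;
#'   scalar or one value per DEP. 0 activates the whole DEP.
#' @param steepness Sigmoid steepness in 1/mm (default 200: ~10 um wide
#'   transition).
#' @param background GFP background level (default 400).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return List with `stack` (raw gfp [image_stack()]) and `truth`
#'   (`front_depth_mm` per DEP, `activation` map).
#' @export
generate_reporter_stack <- function(label_map, biomass, front_depth_mm,
                                    steepness = 200, background = 400,
                                    noise_sd = 0, seed = 1L) {
  stopifnot(inherits(label_map, "pore_label_map"))
  n_dep <- length(label_map$dep_regions)
  front <- rep_len(front_depth_mm, n_dep)
  dm <- dim(label_map$grid)
  px_mm <- label_map$pixel_size / 1000
  act <- matrix(0, dm[1L], dm[2L])
  skipped <- integer(0)
  for (k in seq_len(n_dep)) {
    reg <- label_map$dep_regions[[k]]
    if (front[k] > reg$depth_mm)
      stop("front_depth exceeds DEP depth for dep_id ", k)
    if (!length(reg$pixels)) { skipped <- c(skipped, k); next }
    depth_mm <- reg$depth_map_px[reg$pixels] * px_mm
    act[reg$pixels] <- 1 / (1 + exp(-(depth_mm - front[k]) * steepness))
  }
  with_local_seed(seed, {
    frames <- lapply(biomass$truth$signal, function(sig) {
      fr <- background + sig * act
      if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(prod(dm), 0, noise_sd),
                                          dm[1L], dm[2L])
      pmin(pmax(fr, 0), 65535)
    })
    list(stack = image_stack(frames, biomass$stack$times, channel = "gfp",
                             pixel_size = label_map$pixel_size),
         truth = list(front_depth_mm = front, activation = act,
                      skipped = skipped, noise_sd = noise_sd))
  })
}

#' Render a tracer simulation as a 16-bit image stack
#'
#' @param mask The [pore_mask()] the simulation ran on.
#' @param series A [simulate_tracer()] result.
#' @param scale Intensity corresponding to concentration 1 (default 50000).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return A raw tracer [image_stack()] (no background frame: frame 1 is the
#'   initial condition).
#' @export
generate_tracer_stack <- function(mask, series, scale = 50000, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(inherits(series, "tracer_series"))
  dm <- dim(series$frames[[1L]])
  with_local_seed(seed, {
    frames <- lapply(series$frames, function(cm) {
      fr <- cm * scale
      if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(prod(dm), 0, noise_sd),
                                          dm[1L], dm[2L])
      pmin(pmax(fr, 0), 65535)
    })
    times <- series$times
    if (any(diff(times) <= 0)) times <- seq_along(frames)
    image_stack(frames, times, channel = "tracer",
                pixel_size = series$pixel_size)
  })
}
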