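#' Time-lapse image stack
#'
#' @param frames List of numeric matrices (16-bit intensities), constant
#'   shape, ordered in time. Frame 1 is the pre-injection background frame.
#' @param times Acquisition times in seconds, strictly increasing.
#' @param channel One of `"brightfield"`, `"gfp"`, `"mcherry"`, `"tracer"`.
#' @param pixel_size Micrometres per pixel.
#' @return An `image_stack`.
#' @export
image_stack <- function(frames, times, channel = "brightfield",
                        pixel_size = 0.65) {
  if (!is.list(frames) || !length(frames)) stop("`frames` must be a non-empty list")
  dm <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), dm), logical(1))))
    stop("all frames must share the same shape")
  if (length(times) != length(frames)) stop("one time per frame required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  channel <- match.arg(channel, c("brightfield", "gfp", "mcherry", "tracer"))
  structure(list(frames = frames, times = as.numeric(times), channel = channel,
                 pixel_size = pixel_size, corrected = FALSE),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames (%s), %d x %d px%s\n",
              length(x$frames), x$channel, nrow(x$frames[[1L]]),
              ncol(x$frames[[1L]]),
              if (isTRUE(x$corrected)) ", background-corrected" else ""))
  invisible(x)
}

#' Background-correct and mask an image stack
#'
#' Removes the pre-injection background by subtracting frame 1 from every
#' frame, converts bright-field attenuation to a positive biomass signal
#' (cells darken the bright background, so the signal is background minus
#' frame), clips negatives to zero and zeroes all solid pixels.
#'
#' @param stack An [image_stack()]; frame 1 must be the background frame.
#' @param label_map A [classify_pores()] result aligned with the stack (or a
#'   [pore_mask()]).
#' @return The corrected `image_stack` (`corrected = TRUE`; frame 1 becomes
#'   all zero).
#' @export
preprocess_stack <- function(stack, label_map) {
  stopifnot(inherits(stack, "image_stack"))
  pore <- pore_matrix_of(label_map)
  if (!identical(dim(stack$frames[[1L]]), dim(pore)))
    stop("stack and mask shapes differ: registration error")
  bg <- stack$frames[[1L]]
  stack$frames <- lapply(stack$frames, function(f) {
    s <- if (stack$channel == "brightfield") bg - f else f - bg
    s[s < 0] <- 0
    s[!pore] <- 0
    s
  })
  stack$corrected <- TRUE
  stack
}

pore_matrix_of <- function(x) {
  if (inherits(x, "pore_label_map")) x$grid > 0L
  else if (inherits(x, "pore_mask")) x$grid == 1L
  else stop("need a pore_label_map or pore_mask")
}

#' Detect biomass clusters in a corrected frame
#'
#' Implements the regional-maxima thresholding rule: the frame is median
#' smoothed (3x3) to locate 8-connected regional maxima within the region;
#' the detection threshold is `multiplier` times the mean intensity of those
#' maxima; clusters are the connected components of region pixels whose
#' (unsmoothed) intensity reaches the threshold.
#'
#' @param frame A background-corrected intensity matrix.
#' @param region Pixel indices (linear) of the region to process, e.g. one
#'   DEP or the whole TP class.
#' @param pixel_size Micrometres per pixel.
#' @param multiplier Threshold scale factor (default 1: the mean of the
#'   regional maxima, as in the reference analysis).
#' @param smooth Logical: median-smooth before maxima detection.
#' @param noise_floor Intensities at or below this value are ignored when
#'   looking for maxima (default 0).
#' @return A tibble (`cluster_set`): `cluster_id`, `area_px`, `area_um2`,
#'   `intensity` (integrated), `mass_per_area`, plus attributes `pixels`
#'   (list of pixel indices) and `threshold`.
#' @export
detect_clusters <- function(frame, region, pixel_size = 0.65, multiplier = 1,
                            smooth = TRUE, noise_floor = 0) {
  if (!length(region)) stop("empty region")
  dm <- dim(frame)
  sm <- if (smooth) cpp_median3(frame) else frame
  inreg <- matrix(FALSE, dm[1L], dm[2L]); inreg[region] <- TRUE
  # 8-connected regional maxima of the smoothed image, restricted to region
  mx <- matrix(-Inf, dm[1L] + 2L, dm[2L] + 2L)
  mx[2:(dm[1L] + 1L), 2:(dm[2L] + 1L)] <- sm
  best <- matrix(-Inf, dm[1L], dm[2L])
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    best <- pmax(best, mx[(2:(dm[1L] + 1L)) + di, (2:(dm[2L] + 1L)) + dj])
  }
  is_max <- inreg & sm >= best & sm > noise_floor
  empty <- tibble::tibble(cluster_id = integer(), area_px = integer(),
                          area_um2 = numeric(), intensity = numeric(),
                          mass_per_area = numeric())
  if (!any(is_max)) {
    attr(empty, "pixels") <- list(); attr(empty, "threshold") <- NA_real_
    class(empty) <- c("cluster_set", class(empty))
    return(empty)
  }
  thr <- multiplier * mean(sm[is_max])
  above <- matrix(0L, dm[1L], dm[2L])
  above[region] <- as.integer(frame[region] >= thr & frame[region] > 0)
  lab <- cpp_label(above, 8L)
  n <- attr(lab, "n")
  if (n == 0L) {
    attr(empty, "pixels") <- list(); attr(empty, "threshold") <- thr
    class(empty) <- c("cluster_set", class(empty))
    return(empty)
  }
  pix <- split(which(lab > 0L), lab[lab > 0L])
  out <- tibble::tibble(
    cluster_id = seq_len(n),
    area_px = vapply(pix, length, integer(1)),
    area_um2 = vapply(pix, length, integer(1)) * pixel_size^2,
    intensity = vapply(pix, function(p) sum(frame[p]), numeric(1)))
  out$mass_per_area <- out$intensity / out$area_px
  attr(out, "pixels") <- pix
  attr(out, "threshold") <- thr
  class(out) <- c("cluster_set", class(out))
  out
}

#' Detect clusters in every DEP and the TP class of a stack
#'
#' Each dead-end pore is processed independently; the transmitting-pore
#' class is processed as one region.
#'
#' @param stack A corrected [image_stack()].
#' @param label_map The matching [classify_pores()] result.
#' @param frames Frame indices to process (default: all but the background).
#' @param ... Passed to [detect_clusters()].
#' @return Tibble with one row per cluster: `frame`, `time_s`, `region`
#'   (`"dep"` or `"tp"`), `dep_id` and the [detect_clusters()] columns.
#' @export
detect_clusters_stack <- function(stack, label_map,
                                  frames = seq_along(stack$frames)[-1L], ...) {
  stopifnot(inherits(stack, "image_stack"), isTRUE(stack$corrected),
            inherits(label_map, "pore_label_map"))
  tp <- which(label_map$grid == 2L)
  res <- list()
  for (fi in frames) {
    fr <- stack$frames[[fi]]
    for (reg in label_map$dep_regions) {
      cl <- detect_clusters(fr, reg$pixels, label_map$pixel_size, ...)
      if (nrow(cl))
        res[[length(res) + 1L]] <- tibble::tibble(
          frame = fi, time_s = stack$times[fi], region = "dep",
          dep_id = reg$dep_id, as.data.frame(cl))
    }
    cl <- detect_clusters(fr, tp, label_map$pixel_size, ...)
    if (nrow(cl))
      res[[length(res) + 1L]] <- tibble::tibble(
        frame = fi, time_s = stack$times[fi], region = "tp",
        dep_id = NA_integer_, as.data.frame(cl))
  }
  if (!length(res)) return(tibble::tibble())
  do.call(rbind, res)
}

#' Probability density of colony mass per area
#'
#' Normalized density of `mass_per_area` over logarithmic bins, per time
#' point, comparable across frames (common binning over the observed range).
#'
#' @param clusters A tibble of clusters with `time_s` and `mass_per_area`
#'   (e.g. from [detect_clusters_stack()]).
#' @param bins Number of logarithmic bins (default 64).
#' @return Tibble: `time_s`, `mass_per_area` (bin midpoint), `density`;
#'   within each time the density integrates to 1.
#' @export
colony_mass_pdf <- function(clusters, bins = 64) {
  if (!nrow(clusters)) stop("no clusters")
  m <- clusters$mass_per_area
  if (any(m <= 0)) stop("mass_per_area must be positive")
  rng <- range(m)
  if (rng[1L] == rng[2L]) {            # degenerate: all clusters identical
    warning("degenerate density: single mass_per_area value")
    rng <- rng * c(0.99, 1.01)
  }
  brk <- exp(seq(log(rng[1L] * 0.999), log(rng[2L] * 1.001),
                 length.out = bins + 1L))
  mids <- sqrt(brk[-1L] * brk[-(bins + 1L)])
  widths <- diff(brk)
  out <- lapply(split(m, clusters$time_s), function(v) {
    h <- stats::na.omit(graphics::hist(v, breaks = brk, plot = FALSE)$counts)
    d <- h / sum(h) / widths
    tibble::tibble(mass_per_area = mids, density = d)
  })
  res <- do.call(rbind, Map(function(t, df)
    tibble::tibble(time_s = as.numeric(t), df), names(out), out))
  res
}

#' Retention curve: DEP / TP concentration ratio over time
#'
#' Per frame, the area-normalized mean intensity over each pore class and
#' their ratio `C_dep / C_tp`. With several replicate stacks the mean and
#' standard deviation across replicates are reported.
#'
#' @param stack A corrected [image_stack()], or a list of replicate stacks
#'   sharing frame times.
#' @param label_map The matching [classify_pores()] result.
#' @param floor Frames whose `C_tp` does not exceed this are reported as
#'   `NA` (ratio undefined).
#' @return Tibble (`retention_curve`): `time_s`, `c_dep`, `c_tp`, `ratio`
#'   (and `ratio_sd` for replicates).
#' @export
retention_curve <- function(stack, label_map, floor = 0) {
  stopifnot(inherits(label_map, "pore_label_map"))
  stacks <- if (inherits(stack, "image_stack")) list(stack) else stack
  dep <- which(label_map$grid == 1L); tp <- which(label_map$grid == 2L)
  one <- function(st) {
    stopifnot(inherits(st, "image_stack"), isTRUE(st$corrected))
    cd <- vapply(st$frames, function(f) mean(f[dep]), numeric(1))
    ct <- vapply(st$frames, function(f) mean(f[tp]), numeric(1))
    tibble::tibble(time_s = st$times, c_dep = cd, c_tp = ct,
                   ratio = ifelse(ct > floor, cd / ct, NA_real_))
  }
  curves <- lapply(stacks, one)
  out <- curves[[1L]]
  if (length(curves) > 1L) {
    rmat <- vapply(curves, function(cv) cv$ratio, numeric(nrow(out)))
    out$ratio <- rowMeans(rmat)
    out$ratio_sd <- apply(rmat, 1L, stats::sd)
    out$c_dep <- rowMeans(vapply(curves, function(cv) cv$c_dep, numeric(nrow(out))))
    out$c_tp <- rowMeans(vapply(curves, function(cv) cv$c_tp, numeric(nrow(out))))
  }
  class(out) <- c("retention_curve", class(out))
  out
}

#' Biomass accumulation time series per pore class
#'
#' Class-summed background-subtracted intensities per frame: `b_tp`, `b_dep`,
#' `b_tot = b_tp + b_dep` and the DEP partition `b_dep / b_tot`.
#'
#' @param stack A corrected [image_stack()].
#' @param label_map The matching [classify_pores()] result.
#' @return Tibble (`biomass_series`): `time_s`, `b_tp`, `b_dep`, `b_tot`,
#'   `dep_partition`.
#' @export
biomass_timeseries <- function(stack, label_map) {
  stopifnot(inherits(stack, "image_stack"), isTRUE(stack$corrected),
            inherits(label_map, "pore_label_map"))
  dep <- which(label_map$grid == 1L); tp <- which(label_map$grid == 2L)
  bd <- vapply(stack$frames, function(f) sum(f[dep]), numeric(1))
  bt <- vapply(stack$frames, function(f) sum(f[tp]), numeric(1))
  out <- tibble::tibble(time_s = stack$times, b_tp = bt, b_dep = bd,
                        b_tot = bt + bd,
                        dep_partition = ifelse(bt + bd > 0, bd / (bt + bd),
                                               NA_real_))
  class(out) <- c("biomass_series", class(out))
  out
}
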