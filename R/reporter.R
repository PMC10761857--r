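#' Biomass-normalized reporter activity map
#'
#' Ratio of the background-corrected reporter intensity to the
#' background-corrected biomass intensity, valid only where biomass is above
#' a floor.
#'
#' @param reporter_frame,biomass_frame Co-registered, background-corrected
#'   intensity matrices.
#' @param floor Minimum biomass intensity for a valid ratio (must be > 0).
#' @return An `activity_map`: list with `activity` (matrix, `NA` where
#'   invalid) and `valid` (logical matrix).
#' @export
normalize_activity <- function(reporter_frame, biomass_frame, floor = 1) {
  if (!is.numeric(floor) || floor <= 0) stop("floor must be positive")
  if (!identical(dim(reporter_frame), dim(biomass_frame)))
    stop("frames are not co-registered (shape mismatch)")
  valid <- biomass_frame >= floor
  act <- matrix(NA_real_, nrow(reporter_frame), ncol(reporter_frame))
  act[valid] <- reporter_frame[valid] / biomass_frame[valid]
  structure(list(activity = act, valid = valid), class = "activity_map")
}

#' Depth profiles of activity and biomass along each DEP
#'
#' Samples every `step_px` (default 10) pixels of arc length along each
#' dead-end pore, from the entrance (s = 0) to the tip, averaging activity
#' and biomass within the maximum inscribed disk centred at the sampled
#' skeleton point, clipped to the DEP's own pixels (TP and solid excluded).
#'
#' @param activity An [normalize_activity()] result.
#' @param label_map The matching [classify_pores()] result.
#' @param skeleton The matching annotated skeleton.
#' @param disks The matching [max_inscribed_disk_map()].
#' @param biomass_frame Optional corrected biomass frame to profile alongside.
#' @param step_px Sampling step along the skeleton, pixels.
#' @return Tibble (`depth_profile`): `dep_id`, `s_um` (arc length from the
#'   entrance), `activity`, `biomass`, `n_px` (disk pixels averaged),
#'   `flagged` (single-point profiles).
#' @export
dep_depth_profile <- function(activity, label_map, skeleton, disks,
                              biomass_frame = NULL, step_px = 10) {
  stopifnot(inherits(activity, "activity_map"),
            inherits(label_map, "pore_label_map"),
            inherits(skeleton, "pore_skeleton"))
  dm <- dim(activity$activity)
  px <- label_map$pixel_size
  out <- list()
  for (reg in label_map$dep_regions) {
    sk_idx <- reg$skeleton_idx
    sk_s <- reg$skeleton_depth_px
    keep <- is.finite(sk_s)
    sk_idx <- sk_idx[keep]; sk_s <- sk_s[keep]
    if (!length(sk_idx)) next
    ord <- order(sk_s)
    sk_idx <- sk_idx[ord]; sk_s <- sk_s[ord]
    targets <- seq(0, max(sk_s), by = step_px)
    flagged <- length(targets) < 2L
    sel <- vapply(targets, function(s) which.min(abs(sk_s - s)), integer(1))
    sel <- unique(sel)
    for (q in sel) {
      idx <- sk_idx[q]
      ij <- arrayInd(idx, dm)
      r <- disks$radius_px[idx]
      disk <- stadium_pixels(dm, ij[1L], ij[2L], ij[1L], ij[2L], max(r, 1))
      pix <- intersect(which(disk), reg$pixels)
      a <- activity$activity[pix]
      a <- a[!is.na(a)]
      out[[length(out) + 1L]] <- tibble::tibble(
        dep_id = reg$dep_id, s_um = sk_s[q] * px,
        activity = if (length(a)) mean(a) else NA_real_,
        biomass = if (!is.null(biomass_frame)) mean(biomass_frame[pix]) else
          NA_real_,
        n_px = length(pix), flagged = flagged)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    tibble::tibble(dep_id = integer(), s_um = numeric(), activity = numeric(),
                   biomass = numeric(), n_px = integer(), flagged = logical())
  class(res) <- c("depth_profile", class(res))
  res
}

#' Extract the activation front position from a depth profile
#'
#' The front is the smallest arc length `s` at which the activity reaches
#' `frac` (default 80%) of the profile's own maximum, linearly interpolated
#' between samples. A constant positive profile therefore has its front at
#' the entrance (s = 0).
#'
#' @param profile A [dep_depth_profile()] tibble (one or several DEPs).
#' @param frac Fraction of the per-profile maximum (default 0.8).
#' @return Tibble: `dep_id`, `zeta_mm` (`NA` with `detected = FALSE` for
#'   all-zero profiles).
#' @export
extract_front <- function(profile, frac = 0.8) {
  stopifnot(is.data.frame(profile))
  res <- lapply(split(profile, profile$dep_id), function(pr) {
    pr <- pr[order(pr$s_um), ]
    a <- pr$activity; s <- pr$s_um
    ok <- !is.na(a)
    a <- a[ok]; s <- s[ok]
    if (length(a) < 1L || max(a) <= 0)
      return(tibble::tibble(dep_id = pr$dep_id[1L], zeta_mm = NA_real_,
                            detected = FALSE))
    thr <- frac * max(a)
    i <- which(a >= thr)[1L]
    z <- if (i == 1L) s[1L] else {
      # linear interpolation between the first crossing pair
      s[i - 1L] + (thr - a[i - 1L]) / (a[i] - a[i - 1L]) * (s[i] - s[i - 1L])
    }
    tibble::tibble(dep_id = pr$dep_id[1L], zeta_mm = z / 1000, detected = TRUE)
  })
  do.call(rbind, res)
}
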