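#' Label solid grains
#'
#' Connected components of the solid phase (8-connected, the complementary
#' pair to the 4-connected pore phase) receive dense ids `1..n_grains`.
#'
#' @param mask A [pore_mask()].
#' @return A `grain_label_map`: list with `grid` (0 = pore, k >= 1 = grain id)
#'   and `n_grains`.
#' @export
label_grains <- function(mask) {
  validate_mask(mask)
  solid <- matrix(as.integer(mask$grid == 0L), nrow(mask$grid), ncol(mask$grid))
  lab <- cpp_label(solid, 8L)
  structure(list(grid = lab, n_grains = attr(lab, "n")),
            class = "grain_label_map")
}

#' Maximum inscribed disk map
#'
#' For every pore pixel, the radius of the largest disk centred there that
#' stays inside the pore space, defined as the Euclidean distance to the
#' nearest solid pixel (disk-tangency definition on the raster grid).
#'
#' @param mask A [pore_mask()].
#' @return A `disk_map`: list with `radius_um` (matrix, micrometres; 0 on
#'   solid), `radius_px` and `pixel_size`.
#' @export
max_inscribed_disk_map <- function(mask) {
  validate_mask(mask)
  solid <- mask$grid == 0L
  ft <- cpp_edt(solid)
  r_px <- sqrt(ft$dist2)
  r_px[solid] <- 0
  structure(list(radius_um = r_px * mask$pixel_size, radius_px = r_px,
                 pixel_size = mask$pixel_size),
            class = "disk_map")
}

#' Skeletonize the pore space
#'
#' Thins the pore phase to a 1-pixel-wide, connectivity-preserving medial
#' representation (Zhang-Suen), and annotates every skeleton point with its
#' maximum-inscribed-disk radius.
#'
#' @param mask A [pore_mask()].
#' @param disks Optional precomputed [max_inscribed_disk_map()].
#' @return A `pore_skeleton`: list with `points` (tibble: `i`, `j` 1-based
#'   pixel coordinates, `idx` linear index, `radius_um`, `radius_px`),
#'   `grid` (logical matrix) and `pixel_size`.
#' @export
skeletonize_pores <- function(mask, disks = NULL) {
  validate_mask(mask)
  if (is.null(disks)) disks <- max_inscribed_disk_map(mask)
  sk <- cpp_thin(mask$grid == 1L)
  idx <- which(sk)
  ij <- arrayInd(idx, dim(sk))
  structure(list(
    points = tibble::tibble(
      i = ij[, 1L], j = ij[, 2L], idx = idx,
      radius_px = disks$radius_px[idx],
      radius_um = disks$radius_um[idx]),
    grid = sk, pixel_size = mask$pixel_size),
    class = "pore_skeleton")
}

#' Segregation index along the skeleton
#'
#' For each skeleton point, counts the distinct grains touched by its maximal
#' inscribed disk: solid pixels whose centre lies within `band` pixels of the
#' disk boundary are tangency candidates, and the number of distinct grain
#' ids among them is the segregation index. A value of 1 (disk confined by a
#' single grain) marks dead-end pore locations; values > 1 mark transmitting
#' pores.
#'
#' @param skeleton A [skeletonize_pores()] result.
#' @param disks The matching [max_inscribed_disk_map()].
#' @param grains The matching [label_grains()] result.
#' @param band Tangency band half-width in pixels (default 1.5).
#' @return The skeleton with a `zeta_seg` column added to `points`.
#' @export
segregation_index <- function(skeleton, disks, grains, band = 1.5) {
  stopifnot(inherits(skeleton, "pore_skeleton"),
            inherits(disks, "disk_map"),
            inherits(grains, "grain_label_map"))
  p <- skeleton$points
  z <- cpp_seg_index(grains$grid, p$i - 1L, p$j - 1L, p$radius_px, band)
  if (any(z == 0L))
    warning(sum(z == 0L), " skeleton point(s) found no tangent solid ",
            "within the search band (boundary effect); coded zeta_seg = 1")
  z[z == 0L] <- 1L
  skeleton$points$zeta_seg <- z
  skeleton
}

#' Classify pore space into dead-end and transmitting pores
#'
#' Skeleton points with segregation index 1 seed dead-end-pore (DEP) regions,
#' points with index > 1 seed transmitting-pore (TP) regions; every pore
#' pixel takes the label of its nearest seeding skeleton point (geodesic
#' within the pore space, ties to TP so DEP entrances are conservative).
#' Connected DEP regions are
#' extracted with their entrance pixels (DEP pixels 4-adjacent to TP) and
#' depth L, the geodesic arc length from the entrance to the farthest DEP
#' skeleton point.
#'
#' @param skeleton A [segregation_index()]-annotated skeleton.
#' @param grains The matching [label_grains()] result.
#' @param mask The originating [pore_mask()].
#' @return A `pore_label_map`: list with `grid` (0 solid, 1 DEP, 2 TP),
#'   `dep_regions` (list of per-DEP records: `dep_id`, `pixels`, `entrance`,
#'   `skeleton_idx`, `skeleton_depth_px`, `depth_px`, `depth_mm`,
#'   `depth_map_px` (geodesic depth of every region pixel), `unreachable`),
#'   `deps` (tibble summary) and `pixel_size`.
#' @export
classify_pores <- function(skeleton, grains, mask) {
  stopifnot(inherits(skeleton, "pore_skeleton"))
  if (is.null(skeleton$points$zeta_seg))
    stop("skeleton must be annotated with segregation_index() first")
  validate_mask(mask)
  dm <- dim(mask$grid)
  pore <- mask$grid == 1L

  seeds_dep <- skeleton$points$idx[skeleton$points$zeta_seg == 1L]
  seeds_tp  <- skeleton$points$idx[skeleton$points$zeta_seg >  1L]

  # Distances are geodesic within the pore space so that a skeleton point on
  # the far side of a thin solid wall can never claim a pixel.
  d_tp  <- if (length(seeds_tp))  cpp_geodesic(pore, seeds_tp)  else
    matrix(Inf, dm[1L], dm[2L])
  d_dep <- if (length(seeds_dep)) cpp_geodesic(pore, seeds_dep) else
    matrix(Inf, dm[1L], dm[2L])

  grid <- matrix(0L, dm[1L], dm[2L])
  grid[pore] <- ifelse(d_tp[pore] <= d_dep[pore], 2L, 1L)

  # Inscribed radii, for the deeper-than-wide region filter below.
  r_px <- sqrt(cpp_edt(mask$grid == 0L)$dist2)

  # DEP candidate regions; a region qualifies as a dead-end pore only if it
  # is deeper than wide (the defining cavity property); shallow pockets that
  # arise at channel junctions are folded back into the TP class.
  dep_lab <- cpp_label(matrix(as.integer(grid == 1L), dm[1L], dm[2L]), 4L)
  n_cand <- attr(dep_lab, "n")
  px_mm <- mask$pixel_size / 1000
  dep_regions <- list()
  for (k in seq_len(n_cand)) {
    pix <- which(dep_lab == k)
    reg <- measure_dep_region(pix, grid, skeleton, dm)
    width_px <- 2 * max(r_px[pix])
    if (!reg$unreachable && reg$depth_px <= width_px) {
      grid[pix] <- 2L                       # shallow pocket, not a cavity
      next
    }
    reg$dep_id <- length(dep_regions) + 1L
    reg$width_px <- width_px
    reg$depth_mm <- reg$depth_px * px_mm
    dep_regions[[reg$dep_id]] <- reg
  }
  n_dep <- length(dep_regions)
  deps <- tibble::tibble(
    dep_id = seq_len(n_dep),
    area_px = vapply(dep_regions, function(r) r$area_px, integer(1)),
    depth_mm = vapply(dep_regions, function(r) r$depth_mm, numeric(1)),
    entrance_x = vapply(dep_regions, function(r)
      if (length(r$entrance)) round(mean(arrayInd(r$entrance, dm)[, 2L])) else
        NA_real_, numeric(1)),
    entrance_y = vapply(dep_regions, function(r)
      if (length(r$entrance)) round(mean(arrayInd(r$entrance, dm)[, 1L])) else
        NA_real_, numeric(1)),
    unreachable = vapply(dep_regions, function(r) r$unreachable, logical(1)))
  structure(list(grid = grid, dep_regions = dep_regions, deps = deps,
                 pixel_size = mask$pixel_size),
            class = "pore_label_map")
}

# Entrance pixels, geodesic depth map and depth of one DEP candidate region.
# Depth is the geodesic arc length from the entrance interface to the
# farthest region pixel (the medial skeleton stops half a cavity width short
# of the tip, so region pixels, not skeleton points, set the depth).
measure_dep_region <- function(pix, grid, skeleton, dm) {
  ij <- arrayInd(pix, dm)
  tp_mask <- grid == 2L
  is_entr <- logical(length(pix))
  for (s in 1:4) {
    di <- c(-1L, 1L, 0L, 0L)[s]; dj <- c(0L, 0L, -1L, 1L)[s]
    qi <- ij[, 1L] + di; qj <- ij[, 2L] + dj
    ok <- qi >= 1L & qi <= dm[1L] & qj >= 1L & qj <= dm[2L]
    nb <- rep(FALSE, length(pix))
    nb[ok] <- tp_mask[cbind(qi[ok], qj[ok])]
    is_entr <- is_entr | nb
  }
  entrance <- pix[is_entr]
  unreachable <- length(entrance) == 0L
  region <- matrix(FALSE, dm[1L], dm[2L]); region[pix] <- TRUE
  seeds <- if (unreachable) pix[which.min(ij[, 2L])] else entrance
  depth_map <- cpp_geodesic(region, seeds)
  fin <- depth_map[pix][is.finite(depth_map[pix])]
  sk_in <- intersect(skeleton$points$idx, pix)
  list(pixels = pix, entrance = entrance,
       skeleton_idx = sk_in, skeleton_depth_px = depth_map[sk_in],
       depth_map_px = depth_map,
       depth_px = if (length(fin)) max(fin) else 0,
       area_px = length(pix), unreachable = unreachable)
}

#' @export
print.pore_label_map <- function(x, ...) {
  n_pore <- sum(x$grid > 0L)
  cat(sprintf(
    "<pore_label_map> %d x %d px, %d DEP region(s), DEP fraction %.3f\n",
    nrow(x$grid), ncol(x$grid), length(x$dep_regions),
    if (n_pore) sum(x$grid == 1L) / n_pore else NA_real_))
  invisible(x)
}

#' Pore-space statistics
#'
#' Local pore size lambda is twice the inscribed-disk radius, sampled at every
#' skeleton point; the DEP volume fraction is the DEP share of pore pixels.
#'
#' @param label_map A [classify_pores()] result.
#' @param skeleton The matching annotated skeleton.
#' @param disks The matching disk map.
#' @return A `pore_stats` list: `lambda_um` (samples), `lambda_m_um`,
#'   `lambda_m_mm`, `dep_volume_fraction`, `porosity`, `dep_depths` (tibble)
#'   and `n_dep`.
#' @export
pore_stats <- function(label_map, skeleton, disks) {
  stopifnot(inherits(label_map, "pore_label_map"),
            inherits(skeleton, "pore_skeleton"))
  lambda <- 2 * skeleton$points$radius_um
  n_pore <- sum(label_map$grid > 0L)
  structure(list(
    lambda_um = lambda,
    lambda_m_um = mean(lambda),
    lambda_m_mm = mean(lambda) / 1000,
    dep_volume_fraction = sum(label_map$grid == 1L) / n_pore,
    porosity = n_pore / length(label_map$grid),
    dep_depths = label_map$deps[, c("dep_id", "depth_mm", "area_px")],
    n_dep = length(label_map$dep_regions)),
    class = "pore_stats")
}

#' @export
print.pore_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<pore_stats> lambda_m = %.3g um, DEP fraction = %.3f, porosity = %.3f,",
    " %d DEP(s)\n"), x$lambda_m_um, x$dep_volume_fraction, x$porosity, x$n_dep))
  invisible(x)
}

#' Discretize a mask end to end
#'
#' Convenience wrapper chaining [label_grains()], [max_inscribed_disk_map()],
#' [skeletonize_pores()], [segregation_index()] and [classify_pores()].
#'
#' @param mask A [pore_mask()].
#' @param band Tangency band (pixels) for [segregation_index()].
#' @return List with `grains`, `disks`, `skeleton`, `label_map`, `stats`.
#' @export
discretize_pores <- function(mask, band = 1.5) {
  grains <- label_grains(mask)
  disks <- max_inscribed_disk_map(mask)
  skeleton <- skeletonize_pores(mask, disks)
  skeleton <- segregation_index(skeleton, disks, grains, band = band)
  label_map <- classify_pores(skeleton, grains, mask)
  list(grains = grains, disks = disks, skeleton = skeleton,
       label_map = label_map,
       stats = pore_stats(label_map, skeleton, disks))
}

#' Write a pore label map to disk
#'
#' The PNG uses the palette solid = 0, DEP = 1/2 grey, TP = white; the CSV
#' holds one row per DEP (`dep_id,entrance_x,entrance_y,depth_mm,area_px`).
#'
#' @param label_map A [classify_pores()] result.
#' @param png_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_label_map <- function(label_map, png_path = NULL, csv_path = NULL) {
  stopifnot(inherits(label_map, "pore_label_map"))
  if (!is.null(png_path)) write_image_file(label_map$grid, png_path, max_value = 2)
  if (!is.null(csv_path)) {
    df <- label_map$deps[, c("dep_id", "entrance_x", "entrance_y",
                             "depth_mm", "area_px")]
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(c(png = png_path, csv = csv_path))
}
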