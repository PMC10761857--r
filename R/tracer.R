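#' Characteristic diffusive time across a length scale
#'
#' `T_d = L^2 / D`: the time for molecular diffusion to traverse a distance
#' `L`. For the reference dead-end pore depth L = 0.2 mm and the fluorescein
#' tracer D = 6e-4 mm^2/s this is about one minute.
#'
#' @param L_mm Length scale in mm.
#' @param D Diffusion coefficient in mm^2/s.
#' @return Time in seconds.
#' @examples
#' diffusive_time(0.2, 6e-4)  # ~67 s
#' @export
diffusive_time <- function(L_mm, D) {
  if (any(L_mm < 0) || any(D <= 0)) stop("L_mm must be >= 0 and D > 0")
  L_mm^2 / D
}

#' Pore-volume elution time
#'
#' Time to elute `n_pv` pore volumes at flow rate `Q`. With the reference
#' device (pore volume such that 1 PV elutes in 24 min at Q = 0.1 uL/min),
#' homogeneous filling takes 5 PV = 2 h.
#'
#' @param pore_volume_uL Device pore volume in microlitres.
#' @param Q Flow rate in microlitres/minute.
#' @param n_pv Number of pore volumes.
#' @return Elution time in minutes.
#' @examples
#' elution_time(2.4, 0.1, n_pv = 5)  # 120 min
#' @export
elution_time <- function(pore_volume_uL, Q = 0.1, n_pv = 1) {
  if (pore_volume_uL <= 0 || Q <= 0 || n_pv <= 0) stop("all inputs must be positive")
  n_pv * pore_volume_uL / Q
}

#' Pore-volume time of a simulated scene
#'
#' Ratio of the scene's pore area to the simulated inlet flux: the time to
#' elute one pore volume of the 2D domain.
#'
#' @param mask A [pore_mask()].
#' @param field The matching [solve_stokes()] result.
#' @return Time in seconds.
#' @export
scene_pv_time <- function(mask, field) {
  stopifnot(inherits(field, "velocity_field"))
  px_mm <- mask$pixel_size / 1000
  area <- sum(field$pore) * px_mm^2                     # mm^2
  influx <- sum(field$u_face[, 1L]) / 1000 * px_mm      # mm^2/s
  if (influx <= 0) stop("no net inlet flux; cannot define a pore volume time")
  area / influx
}

#' Simulate passive tracer advection-diffusion on a pore geometry
#'
#' Finite-volume transport on the Stokes face velocities: explicit
#' first-order upwind advection (sub-stepped at the CFL limit, monotone at
#' sharp fronts) operator-split with implicit (backward Euler) diffusion,
#' which is unconditionally stable. Solid boundaries are no-flux; the inlet
#' edge holds a fixed concentration (`inlet_value`) both advectively and
#' diffusively unless `inlet = "sealed"`; the outlet is advective outflow.
#'
#' @param mask A [pore_mask()].
#' @param field The matching [solve_stokes()] result (`NULL` for pure
#'   diffusion with zero velocity).
#' @param D Molecular diffusion coefficient, mm^2/s (default 6e-4, the
#'   fluorescein value).
#' @param t_end Simulated time, s.
#' @param dt Macro time step (diffusion step), s; advection is sub-stepped
#'   within it. Default `min(1, t_end / 100)`.
#' @param init Initial concentration: scalar or matrix (resident solution
#'   = 1 by convention).
#' @param inlet_value Concentration of the invading fluid at the inlet.
#' @param inlet `"dirichlet"` (displacement) or `"sealed"` (closed system).
#' @param record_times Times at which to store frames (default: ~60 evenly
#'   spaced, always including 0 and `t_end`).
#' @return A `tracer_series`: list with `frames` (list of concentration
#'   matrices, 0 on solid), `times` (s), `mass` (total tracer per frame, in
#'   concentration * mm^2), `D`, `pixel_size`, `pore`.
#' @export
simulate_tracer <- function(mask, field = NULL, D = 6e-4, t_end,
                            dt = NULL, init = 1, inlet_value = 0,
                            inlet = c("dirichlet", "sealed"),
                            record_times = NULL) {
  validate_mask(mask, require_both_phases = FALSE)
  inlet <- match.arg(inlet)
  if (D <= 0) stop("D must be positive")
  dm <- dim(mask$grid); nr <- dm[1L]; nc <- dm[2L]
  px_mm <- mask$pixel_size / 1000
  # Work in grid units: dx = 1, velocities in px/s, D in px^2/s.
  if (is.null(field)) {
    pore <- mask$grid == 1L
    uf <- matrix(0, nr, nc + 1L); vf <- matrix(0, nr + 1L, nc)
  } else {
    stopifnot(inherits(field, "velocity_field"))
    pore <- field$pore
    uf <- field$u_face / mask$pixel_size   # um/s -> px/s
    vf <- field$v_face / mask$pixel_size
  }
  D_px <- D * 1e6 / mask$pixel_size^2      # mm^2/s -> px^2/s

  if (is.null(dt)) dt <- min(1, t_end / 100)
  umax <- max(abs(uf), abs(vf), 1e-12)
  n_sub <- max(1L, ceiling(dt * umax / 0.8))    # advective CFL 0.8
  dt_a <- dt / n_sub

  if (is.null(record_times)) {
    record_times <- unique(c(0, seq(0, t_end, length.out = 61)))
  }
  record_times <- sort(unique(pmin(record_times, t_end)))

  c0 <- if (is.matrix(init)) init else matrix(init, nr, nc)
  c0[!pore] <- 0
  cmat <- c0

  # implicit diffusion operator over pore cells
  pidx <- which(pore)
  np <- length(pidx)
  pnum <- matrix(0L, nr, nc); pnum[pidx] <- seq_len(np)
  th <- dt * D_px
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(np)
  for (s in 1:4) {
    di <- c(-1L, 1L, 0L, 0L)[s]; dj <- c(0L, 0L, -1L, 1L)[s]
    ij <- arrayInd(pidx, dm)
    qi <- ij[, 1L] + di; qj <- ij[, 2L] + dj
    ok <- qi >= 1L & qi <= nr & qj >= 1L & qj <= nc
    nb <- rep(0L, np)
    nb[ok] <- pnum[cbind(qi[ok], qj[ok])]
    has <- nb > 0L
    ii <- c(ii, seq_len(np)[has]); jj <- c(jj, nb[has]); xx <- c(xx, rep(-th, sum(has)))
    diag_acc <- diag_acc + as.numeric(has)
  }
  rhs_dir <- numeric(np)
  if (inlet == "dirichlet") {
    at_in <- which(arrayInd(pidx, dm)[, 2L] == 1L)
    diag_acc[at_in] <- diag_acc[at_in] + 1
    rhs_dir[at_in] <- th * inlet_value
  }
  ii <- c(ii, seq_len(np)); jj <- c(jj, seq_len(np)); xx <- c(xx, 1 + th * diag_acc)
  Adiff <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(np, np))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Adiff), LDL = FALSE)

  advect <- function(cm) {
    cL <- cbind(if (inlet == "dirichlet") rep(inlet_value, nr) else cm[, 1L], cm)
    cR <- cbind(cm, cm[, nc])
    Fu <- uf * ifelse(uf > 0, cL, cR)
    if (inlet == "sealed") Fu[, 1L] <- 0
    cT <- rbind(cm[1L, ], cm); cB <- rbind(cm, cm[nr, ])
    Fv <- vf * ifelse(vf > 0, cT, cB)
    div <- (Fu[, 2:(nc + 1L), drop = FALSE] - Fu[, 1:nc, drop = FALSE]) +
      (Fv[2:(nr + 1L), , drop = FALSE] - Fv[1:nr, , drop = FALSE])
    cm2 <- cm - dt_a * div
    cm2[!pore] <- 0
    cm2
  }

  frames <- list(); times <- numeric(0); mass <- numeric(0)
  rec_i <- 1L
  push <- function(cm, t) {
    frames[[length(frames) + 1L]] <<- cm
    times[[length(times) + 1L]] <<- t
    mass[[length(mass) + 1L]] <<- sum(cm[pidx]) * px_mm^2
  }
  t <- 0
  if (record_times[1L] <= 0) { push(cmat, 0); rec_i <- 2L }
  n_steps <- ceiling(t_end / dt - 1e-9)
  for (k in seq_len(n_steps)) {
    for (s in seq_len(n_sub)) cmat <- advect(cmat)
    b <- cmat[pidx] + rhs_dir
    cmat[pidx] <- as.numeric(Matrix::solve(ch, b))
    t <- t + dt
    while (rec_i <= length(record_times) && record_times[rec_i] <= t + 1e-9) {
      push(cmat, t)
      rec_i <- rec_i + 1L
    }
  }
  structure(list(frames = frames, times = times, mass = mass, D = D,
                 pixel_size = mask$pixel_size, pore = pore,
                 inlet = inlet, inlet_value = inlet_value),
            class = "tracer_series")
}

#' @export
print.tracer_series <- function(x, ...) {
  cat(sprintf("<tracer_series> %d frames over %.4g s, D = %.3g mm^2/s\n",
              length(x$frames), max(x$times), x$D))
  invisible(x)
}

#' Persistence of DEP-entrance concentration gradients
#'
#' For each dead-end pore, the concentration difference across the entrance
#' is tracked as the mean over DEP pixels within the entrance window minus
#' the mean over TP pixels within the same distance of the entrance. The
#' persistence time is the last recorded time at which this difference
#' exceeds `threshold` times the reference contrast.
#'
#' @param series A [simulate_tracer()] result.
#' @param label_map The matching [classify_pores()] result.
#' @param threshold Detection threshold as a fraction of the reference
#'   contrast (default 0.1).
#' @param strip_um Width of the entrance window in micrometres on each side
#'   of the entrance. The default (`NULL`) scales the window to each DEP's
#'   own aperture (its width, twice the largest inscribed radius): the
#'   mouth gradient separates the cavity reservoir from the channel, and
#'   its natural inner scale is the aperture, not the imaging resolution.
#' @param reference `"contrast"` (initial resident-minus-invading contrast,
#'   the natural choice for displacement runs), `"initial"` (the entrance
#'   difference in the first frame), or a number.
#' @return Tibble: `dep_id`, `persistence_s`, `max_abs_diff`, `reference`,
#'   `detected` (`FALSE` if the gradient never exceeded threshold).
#' @export
gradient_persistence <- function(series, label_map, threshold = 0.1,
                                 strip_um = NULL, reference = "contrast") {
  stopifnot(inherits(series, "tracer_series"),
            inherits(label_map, "pore_label_map"))
  dm <- dim(series$frames[[1L]])
  out <- vector("list", length(label_map$dep_regions))
  tp_mask <- label_map$grid == 2L
  for (k in seq_along(label_map$dep_regions)) {
    reg <- label_map$dep_regions[[k]]
    strip_px <- if (!is.null(strip_um)) strip_um / label_map$pixel_size
      else if (!is.null(reg$width_px)) reg$width_px
      else 40 / label_map$pixel_size
    inside <- reg$pixels[reg$depth_map_px[reg$pixels] <= strip_px]
    ent <- matrix(FALSE, dm[1L], dm[2L]); ent[reg$entrance] <- TRUE
    d_out <- sqrt(cpp_edt(ent)$dist2)
    outside <- which(tp_mask & d_out <= strip_px)
    if (!length(inside) || !length(outside)) {
      out[[k]] <- tibble::tibble(dep_id = reg$dep_id, persistence_s = 0,
                                 max_abs_diff = NA_real_, reference = NA_real_,
                                 detected = FALSE)
      next
    }
    diff_t <- vapply(series$frames, function(fr)
      mean(fr[inside]) - mean(fr[outside]), numeric(1))
    ref <- if (is.numeric(reference)) reference
      else if (reference == "initial") abs(diff_t[1L])
      else max(abs(series$frames[[1L]][series$pore] - series$inlet_value))
    if (!is.finite(ref) || ref <= 0) ref <- 1
    above <- abs(diff_t) >= threshold * ref
    pers <- if (any(above)) max(series$times[above]) else 0
    out[[k]] <- tibble::tibble(dep_id = reg$dep_id, persistence_s = pers,
                               max_abs_diff = max(abs(diff_t)),
                               reference = ref, detected = any(above))
  }
  do.call(rbind, out)
}
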