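#' Flow configuration
#'
#' @param Q Imposed volumetric flow rate, microlitres per minute (default
#'   0.1, the experimental syringe-pump setting).
#' @param h Chip thickness in mm (default 0.05).
#' @param u_m_target Optional mean pore velocity to rescale the solution to,
#'   in micrometres/second. When `NULL`, the field is scaled so the inlet
#'   flux matches the 2D flux `Q / h` over the inlet width.
#' @param viscosity Dynamic viscosity in arbitrary units; it scales out of
#'   the normalized velocity field.
#' @return A `flow_config` list.
#' @export
flow_config <- function(Q = 0.1, h = 0.05, u_m_target = NULL, viscosity = 1) {
  if (Q <= 0) stop("Q must be positive")
  if (h <= 0) stop("h must be positive")
  structure(list(Q = Q, h = h, u_m_target = u_m_target,
                 viscosity = viscosity), class = "flow_config")
}

#' Solve 2D steady incompressible Stokes flow on a pore mask
#'
#' Staggered-grid (MAC) finite differences: velocities live on cell faces,
#' pressures at pore-cell centres, and the momentum + continuity equations
#' are assembled into one sparse saddle-point system solved directly. No-slip
#' is imposed on all solid boundaries and the top/bottom domain walls via
#' ghost reflection; a unit pressure drop is imposed between the left (inlet)
#' and right (outlet) edges and the resulting field is rescaled to the
#' requested flux or mean pore velocity (Stokes flow is linear, so the
#' rescaling is exact).
#'
#' @param mask A percolating [pore_mask()].
#' @param config A [flow_config()].
#' @return A `velocity_field`: list with `u`, `v` (cell-centred components,
#'   micrometres/s; 0 on solid), `speed`, `u_face`, `v_face` (staggered face
#'   velocities used by the transport solver), `u_m` (mean pore speed,
#'   micrometres/s), `div_max` (largest continuity residual relative to the
#'   mean face speed), `pixel_size` and `config`.
#' @export
solve_stokes <- function(mask, config = flow_config()) {
  validate_mask(mask)
  if (!percolates(mask)) stop("mask does not percolate inlet-to-outlet: no flow")
  dm <- dim(mask$grid)
  nr <- dm[1L]; nc <- dm[2L]

  # restrict to pore components reaching the inlet or outlet edge; isolated
  # components have no pressure anchor and carry no flow
  lab <- cpp_label(mask$grid, 4L)
  keep <- setdiff(unique(c(lab[, 1L], lab[, nc])), 0L)
  pore <- matrix(lab %in% keep, nr, nc)

  asm <- cpp_stokes_assemble(pore, 1, 0)
  A <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                            dims = c(asm$n_tot, asm$n_tot))
  sol <- tryCatch(as.numeric(Matrix::solve(A, asm$rhs)),
                  error = function(e) stop("singular Stokes system: ",
                                           conditionMessage(e)))
  uid <- asm$uid; vid <- asm$vid

  uface <- matrix(0, nr, nc + 1L)
  uface[uid > 0L] <- sol[uid[uid > 0L]]
  vface <- matrix(0, nr + 1L, nc)                          # walls padded with 0
  vcore <- matrix(0, nr - 1L, nc)
  vcore[vid > 0L] <- sol[vid[vid > 0L]]
  vface[2:nr, ] <- vcore

  # cell-centred field
  u <- (uface[, 1:nc, drop = FALSE] + uface[, 2:(nc + 1L), drop = FALSE]) / 2
  v <- (vface[1:nr, , drop = FALSE] + vface[2:(nr + 1L), , drop = FALSE]) / 2
  u[!pore] <- 0; v[!pore] <- 0
  speed <- sqrt(u^2 + v^2)

  # divergence residual per cell, relative to mean face speed
  div <- uface[, 2:(nc + 1L), drop = FALSE] - uface[, 1:nc, drop = FALSE] +
    vface[2:(nr + 1L), , drop = FALSE] - vface[1:nr, , drop = FALSE]
  div[!pore] <- 0
  scale0 <- mean(abs(uface[uid > 0L]))
  div_max <- if (scale0 > 0) max(abs(div)) / scale0 else 0

  # physical rescaling ------------------------------------------------------
  u_m_raw <- mean(speed[pore])
  if (!is.null(config$u_m_target)) {
    fac <- config$u_m_target / u_m_raw                     # -> um/s
  } else {
    px_mm <- mask$pixel_size / 1000
    q2 <- config$Q / 60 / config$h                         # 2D flux, mm^2/s
    flux_raw <- sum(uface[, 1L])                           # raw px^2/time
    fac <- 1000 * q2 / (px_mm * flux_raw)                  # raw -> um/s
  }
  structure(list(u = u * fac, v = v * fac, speed = speed * fac,
                 u_face = uface * fac, v_face = vface * fac,
                 u_m = u_m_raw * fac, div_max = div_max,
                 pore = pore, pixel_size = mask$pixel_size, config = config),
            class = "velocity_field")
}


#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d px, u_m = %.3g um/s, max div = %.2e\n",
              nrow(x$u), ncol(x$u), x$u_m, x$div_max))
  invisible(x)
}

#' Average shear rate
#'
#' The bulk shear estimate `u_m / h` across the chip thickness.
#'
#' @param field A [solve_stokes()] result, or a number taken as the mean pore
#'   velocity in micrometres/second.
#' @param config A [flow_config()] supplying the chip thickness `h` (mm).
#' @return Shear rate in 1/s.
#' @examples
#' shear_rate(20, flow_config(h = 0.05))  # 0.4 s^-1
#' @export
shear_rate <- function(field, config = flow_config()) {
  u_m <- if (inherits(field, "velocity_field")) field$u_m else as.numeric(field)
  if (config$h <= 0) stop("h must be positive")
  (u_m / 1000) / config$h
}
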