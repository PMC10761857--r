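#' Autoinducer-2 diffusivity from the Stokes-Einstein relation
#'
#' With hydrodynamic radius scaling as the cube root of molecular mass,
#' `D_A = D_G * (M_G / M_A)^(1/3)`.
#'
#' @param D_G Glucose diffusivity, mm^2/s.
#' @param M_G Glucose molecular mass, g/mol (180.16).
#' @param M_A AI-2 molecular mass, g/mol (default 132.11, the DPD precursor;
#'   configurable since the sensed species is not settled).
#' @return AI-2 diffusivity, mm^2/s.
#' @examples
#' stokes_einstein_diffusivity(6e-4, 180.16, 132.11)
#' @export
stokes_einstein_diffusivity <- function(D_G, M_G = 180.16, M_A = 132.11) {
  if (any(c(D_G, M_G, M_A) <= 0)) stop("all arguments must be positive")
  D_G * (M_G / M_A)^(1 / 3)
}

#' Parameters of the coupled glucose / AI-2 model
#'
#' One-dimensional consumption-diffusion of glucose along a dead-end pore
#' (Dirichlet `c_0` at the DEP-TP juncture, no-flux at the tip) coupled to
#' AI-2 production/uptake, with the uptake gated by a glucose threshold
#' (catabolite repression: AI-2 is only internalized once glucose is
#' depleted).
#'
#' @param L DEP depth, mm (default 0.2).
#' @param D_G Glucose diffusivity, mm^2/s (default 6e-4).
#' @param D_A AI-2 diffusivity, mm^2/s; default derived from `D_G` via
#'   [stokes_einstein_diffusivity()].
#' @param U_1c Glucose uptake rate per dry mass, mMol s^-1 g^-1 (default 10).
#' @param c_0 Glucose concentration at the juncture, mM (default 5).
#' @param k_Aplus,k_Aminus AI-2 production/uptake rate constants,
#'   mM L g^-1 s^-1 (defaults 1e-3 and 0.1; not reported, chosen so that
#'   induced uptake is much faster than production, localizing the AI-2
#'   depletion front).
#' @param theta_G Glucose threshold gating AI-2 uptake, mM (default
#'   `0.1 * c_0`: catabolite repression is relieved below a few tenths of a
#'   millimolar of glucose).
#' @param m_cell Dry mass per cell, g (default 3e-13).
#' @param M_G,M_A Molecular masses, g/mol.
#' @param dx Grid step, mm (default `L / 200`).
#' @param dt Time step, s (default 0.1).
#' @return A `qs_model_params` list.
#' @export
model_params <- function(L = 0.2, D_G = 6e-4, D_A = NULL, U_1c = 10,
                         c_0 = 5, k_Aplus = 1e-3, k_Aminus = 0.1,
                         theta_G = NULL, m_cell = 3e-13,
                         M_G = 180.16, M_A = 132.11,
                         dx = NULL, dt = 0.1) {
  if (is.null(D_A)) D_A <- stokes_einstein_diffusivity(D_G, M_G, M_A)
  if (is.null(theta_G)) theta_G <- 0.1 * c_0
  if (is.null(dx)) dx <- L / 200
  p <- list(L = L, D_G = D_G, D_A = D_A, U_1c = U_1c, c_0 = c_0,
            k_Aplus = k_Aplus, k_Aminus = k_Aminus, theta_G = theta_G,
            m_cell = m_cell, M_G = M_G, M_A = M_A, dx = dx, dt = dt)
  if (any(unlist(p) <= 0)) stop("all model parameters must be positive")
  if (dx > L / 50) stop("dx must not exceed L/50")
  if (theta_G >= c_0) stop("theta_G must be below c_0")
  class(p) <- "qs_model_params"
  p
}

# backward-Euler propagator for one diffusing species on [0, L]:
# left boundary 'dirichlet' (value pinned) or right no-flux; returns the
# dense inverse of (I - dt D L2) with boundary rows built in.
be_propagator <- function(nx, dx, dt, D, left = c("dirichlet", "noflux")) {
  left <- match.arg(left)
  r <- dt * D / dx^2
  A <- diag(1 + 2 * r, nx)
  for (i in 2:nx) { A[i, i - 1] <- -r; A[i - 1, i] <- -r }
  if (left == "dirichlet") {
    A[1, ] <- 0; A[1, 1] <- 1
  } else {
    A[1, 1] <- 1 + r                       # mirror ghost at x = 0
  }
  A[nx, nx] <- 1 + r                       # mirror ghost at x = L (no-flux)
  solve(A)
}

#' Mass-conservation residual of the backward-Euler diffusion step
#'
#' Diagnostic: propagates a profile one step with sealed (no-flux) ends and
#' no reaction, and returns the relative change in total mass. The
#' conservative flux discretization keeps this at machine precision.
#'
#' @param params A [model_params()].
#' @param profile Initial profile on the grid (default: a half-cosine).
#' @param n_steps Number of steps to take (default 100).
#' @return Maximum relative mass change per step.
#' @export
conservation_residual <- function(params, profile = NULL, n_steps = 100) {
  stopifnot(inherits(params, "qs_model_params"))
  nx <- round(params$L / params$dx) + 1L
  if (is.null(profile))
    profile <- 1 + cos(pi * seq(0, 1, length.out = nx))
  P <- be_propagator(nx, params$dx, params$dt, params$D_G, "noflux")
  worst <- 0
  v <- profile
  for (k in seq_len(n_steps)) {
    v2 <- as.numeric(P %*% v)
    worst <- max(worst, abs(sum(v2) - sum(v)) / sum(v))
    v <- v2
  }
  worst
}

#' Solve the coupled glucose consumption-diffusion / AI-2 model
#'
#' Backward-Euler time stepping of glucose diffusion with biomass-
#' proportional consumption (clamped so concentrations stay non-negative:
#' uptake is only active where glucose remains), coupled to AI-2 diffusion
#' with production `k_Aplus * c_B` everywhere and uptake
#' `k_Aminus * f * c_B` where the glucose switch `f` is 1 below `theta_G`
#' and 0 above. Boundary conditions: glucose `c_0` at the juncture (x = 0),
#' no-flux at the tip; AI-2 washed out at the juncture (Dirichlet 0, the TP
#' flow removes it) and no-flux at the tip. The QS reporter proxy is
#' `lsrR = (1 - c_AI2)(1 - c_G)` on normalized fields.
#'
#' @param params A [model_params()].
#' @param biomass Biomass concentration `c_B` along the DEP in g/L: a
#'   scalar, a vector on the grid (piecewise-constant in time), or a
#'   function of x (mm).
#' @param t_end Simulated time, s.
#' @param save_times Times at which profiles are stored (default ~25).
#' @param ai2_norm `"instantaneous"` (divide by the current AI-2 maximum) or
#'   `"production"` (fixed scale `k_Aplus * mean(c_B) * L^2 / D_A`).
#' @return A `qs_model_solution`: list with `x` (mm), `times`, matrices
#'   `c_G` (mM), `c_G_norm`, `c_AI2`, `c_AI2_norm`, `f`, `lsrR` (columns =
#'   saved times), `biomass`, `params`, and `conservation_error` (per-step
#'   mass-balance residual measured with consumption and boundaries off).
#' @export
solve_coupled_model <- function(params, biomass, t_end = 3600,
                                save_times = NULL,
                                ai2_norm = c("instantaneous", "production")) {
  stopifnot(inherits(params, "qs_model_params"))
  ai2_norm <- match.arg(ai2_norm)
  nx <- round(params$L / params$dx) + 1L
  x <- seq(0, params$L, length.out = nx)
  c_B <- if (is.function(biomass)) biomass(x) else rep_len(biomass, nx)
  if (any(c_B < 0)) stop("biomass must be non-negative")
  dt <- params$dt
  if (is.null(save_times)) save_times <- seq(0, t_end, length.out = 25)
  save_times <- sort(unique(pmin(save_times, t_end)))

  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  ns <- length(save_times)
  save_steps <- as.integer(round(save_times / dt))
  res <- cpp_qs_integrate(c_B, params$c_0, params$U_1c,
                          params$k_Aplus, params$k_Aminus, params$theta_G,
                          params$D_G, params$D_A, params$dx, dt,
                          n_steps, save_steps)
  CG <- res$CG; CA <- res$CA
  Fm <- matrix(as.numeric(CG < params$theta_G), nx, ns)
  cg_n <- CG / params$c_0
  ca_scale <- if (ai2_norm == "instantaneous") {
    apply(CA, 2L, function(v) max(v, 1e-300))
  } else rep(params$k_Aplus * mean(c_B) * params$L^2 / params$D_A, ns)
  ca_n <- sweep(CA, 2L, ca_scale, "/")
  ca_n[ca_n > 1] <- 1
  structure(list(x = x, times = save_times, c_G = CG, c_G_norm = cg_n,
                 c_AI2 = CA, c_AI2_norm = ca_n, f = Fm,
                 lsrR = lsr_signal(cg_n, ca_n),
                 biomass = c_B, params = params),
            class = "qs_model_solution")
}

#' @export
print.qs_model_solution <- function(x, ...) {
  cat(sprintf("<qs_model_solution> %d nodes, %d saved times to %.4g s\n",
              length(x$x), length(x$times), max(x$times)))
  invisible(x)
}

#' QS reporter proxy from normalized fields
#'
#' `lsrR = (1 - c_AI2)(1 - c_G)`: the reporter is high where glucose is
#' depleted (catabolite repression lifted) and AI-2 has been internalized.
#'
#' @param c_G_norm,c_AI2_norm Fields normalized to `[0, 1]`.
#' @param tol Allowed overshoot outside `[0, 1]`.
#' @return The elementwise product, same shape as the inputs.
#' @export
lsr_signal <- function(c_G_norm, c_AI2_norm, tol = 1e-6) {
  rng <- range(c_G_norm, c_AI2_norm)
  if (rng[1L] < -tol || rng[2L] > 1 + tol)
    stop("inputs must be normalized to [0, 1]")
  (1 - c_AI2_norm) * (1 - c_G_norm)
}

#' Glucose-limitation length from the consumption/diffusion balance
#'
#' The time for the biomass to consume the local glucose is
#' `tau_U = c_0 / U_T` with `U_T = U_1c * mean(c_B)`; equating it with the
#' diffusion time across a distance `zeta` gives the glucose-limitation
#' length `zeta = sqrt(D_G * tau_U)`, clipped to the DEP depth.
#'
#' @param params A [model_params()].
#' @param biomass DEP biomass `c_B` (g/L): scalar, vector, or function of x.
#' @return A tibble: `U_T` (mM/s), `tau_U` (s), `zeta_scaling` (mm),
#'   `tau_D` (s, `zeta^2 / D_G` after clipping), `clipped`, `no_depletion`.
#' @export
predict_zeta_scaling <- function(params, biomass) {
  stopifnot(inherits(params, "qs_model_params"))
  nx <- round(params$L / params$dx) + 1L
  x <- seq(0, params$L, length.out = nx)
  c_B <- if (is.function(biomass)) biomass(x) else rep_len(biomass, nx)
  cb <- mean(c_B)
  if (cb <= 0) {
    return(tibble::tibble(U_T = 0, tau_U = Inf, zeta_scaling = params$L,
                          tau_D = params$L^2 / params$D_G, clipped = TRUE,
                          no_depletion = TRUE))
  }
  U_T <- params$U_1c * cb
  tau_U <- params$c_0 / U_T
  zeta_raw <- sqrt(params$D_G * tau_U)
  clipped <- zeta_raw > params$L
  zeta <- min(zeta_raw, params$L)
  tibble::tibble(U_T = U_T, tau_U = tau_U, zeta_scaling = zeta,
                 tau_D = zeta^2 / params$D_G, clipped = clipped,
                 no_depletion = FALSE)
}

#' Extract the simulated glucose-limitation length
#'
#' The smallest position where the simulated lsrR signal reaches 80% of its
#' own maximum at time `t`, linearly interpolated between grid nodes.
#'
#' @param solution A [solve_coupled_model()] result.
#' @param t Time (s); the nearest saved time is used (default: last).
#' @param frac Fraction of the maximum (default 0.8).
#' @return `zeta_sim` in mm (`NA` if the signal is identically zero).
#' @export
extract_zeta_sim <- function(solution, t = NULL, frac = 0.8) {
  stopifnot(inherits(solution, "qs_model_solution"))
  ti <- if (is.null(t)) length(solution$times) else
    which.min(abs(solution$times - t))
  sig <- solution$lsrR[, ti]
  if (max(sig) <= 0) {
    warning("lsrR signal is identically zero; front undefined")
    return(NA_real_)
  }
  thr <- frac * max(sig)
  i <- which(sig >= thr)[1L]
  if (i == 1L) return(solution$x[1L])
  x <- solution$x
  x[i - 1L] + (thr - sig[i - 1L]) / (sig[i] - sig[i - 1L]) * (x[i] - x[i - 1L])
}
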