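#' @importFrom stats sd
NULL

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package 'ggplot2' is required for plotting")
}

#' Plot a retention curve
#'
#' @param object A [retention_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object: `C_dep / C_tp` against time, with a reference
#'   line at 1 (homogeneous occupancy).
#' @export
autoplot.retention_curve <- function(object, ...) {
  need_ggplot()
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 3600,
                                            y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = expression(C[dep] / C[tp]),
                  title = "Retention curve")
  if ("ratio_sd" %in% names(object))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ratio - .data$ratio_sd,
                   ymax = .data$ratio + .data$ratio_sd), alpha = 0.2)
  p
}

#' Plot biomass accumulation per pore class
#'
#' @param object A [biomass_timeseries()] tibble.
#' @param ... Unused.
#' @return A ggplot object with TP, DEP and total biomass against time.
#' @export
autoplot.biomass_series <- function(object, ...) {
  need_ggplot()
  long <- rbind(
    data.frame(time_s = object$time_s, biomass = object$b_tp, class = "TP"),
    data.frame(time_s = object$time_s, biomass = object$b_dep, class = "DEP"),
    data.frame(time_s = object$time_s, biomass = object$b_tot, class = "total"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 3600,
                                     y = .data$biomass,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(TP = "cyan3", DEP = "red3",
                                            total = "grey40")) +
    ggplot2::labs(x = "time (h)", y = "biomass (intensity units)",
                  title = "Biomass accumulation")
}

#' Plot reporter depth profiles along DEPs
#'
#' @param object A [dep_depth_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object: activity against depth, one line per DEP.
#' @export
autoplot.depth_profile <- function(object, ...) {
  need_ggplot()
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_um, y = .data$activity,
                                       group = .data$dep_id,
                                       colour = factor(.data$dep_id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth from entrance (um)",
                  y = "normalized reporter activity",
                  colour = "DEP", title = "Reporter activity along DEPs")
}

#' Plot a pore label map
#'
#' @param x A [classify_pores()] result.
#' @param ... Unused.
#' @return A ggplot raster: solid grey, DEP red, TP cyan (the conventional
#'   palette for this discretization).
#' @export
plot_label_map <- function(x, ...) {
  need_ggplot()
  stopifnot(inherits(x, "pore_label_map"))
  df <- expand.grid(y = seq_len(nrow(x$grid)), x = seq_len(ncol(x$grid)))
  df$class <- factor(c("solid", "DEP", "TP")[as.vector(x$grid) + 1L],
                     levels = c("solid", "DEP", "TP"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(solid = "grey30", DEP = "red3",
                                          TP = "cyan3")) +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(title = "Pore discretization", x = NULL, y = NULL)
}

#' Plot the velocity magnitude field
#'
#' @param x A [solve_stokes()] result.
#' @param log10_floor Smallest speed (relative to the mean) shown on the
#'   log colour scale.
#' @param ... Unused.
#' @return A ggplot raster of `log10(|u| / <|u|>)`, the conventional view
#'   that makes DEP stagnation visible.
#' @export
plot_velocity <- function(x, log10_floor = -4, ...) {
  need_ggplot()
  stopifnot(inherits(x, "velocity_field"))
  rel <- x$speed / x$u_m
  rel[!x$pore] <- NA
  rel <- pmax(rel, 10^log10_floor)
  df <- expand.grid(y = seq_len(nrow(rel)), x = seq_len(ncol(rel)))
  df$logspeed <- log10(as.vector(rel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$logspeed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(fill = expression(log[10](u / u[m])),
                  title = "Stokes velocity modulus", x = NULL, y = NULL)
}

#' Tidy a coupled-model solution into long format
#'
#' @param x A [solve_coupled_model()] result.
#' @param ... Unused.
#' @return Tibble: `x_mm`, `t_s`, `c_G`, `c_G_norm`, `c_AI2_norm`, `lsrR`.
#' @export
tidy.qs_model_solution <- function(x, ...) {
  nt <- length(x$times)
  tibble::tibble(
    x_mm = rep(x$x, nt),
    t_s = rep(x$times, each = length(x$x)),
    c_G = as.vector(x$c_G),
    c_G_norm = as.vector(x$c_G_norm),
    c_AI2_norm = as.vector(x$c_AI2_norm),
    lsrR = as.vector(x$lsrR))
}

#' One-row summary of a coupled-model solution
#'
#' @param x A [solve_coupled_model()] result.
#' @param ... Unused.
#' @return Tibble with the final-time front position, the scaling
#'   prediction and the consumption/diffusion time scales.
#' @export
glance.qs_model_solution <- function(x, ...) {
  zs <- predict_zeta_scaling(x$params, x$biomass)
  tibble::tibble(
    t_end_s = max(x$times),
    zeta_sim_mm = extract_zeta_sim(x),
    zeta_scaling_mm = zs$zeta_scaling,
    tau_U_s = zs$tau_U, tau_D_s = zs$tau_D,
    U_T = zs$U_T)
}

#' @export
autoplot.qs_model_solution <- function(object, ...) {
  need_ggplot()
  df <- tidy.qs_model_solution(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$lsrR,
                                   group = .data$t_s,
                                   colour = .data$t_s)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "depth from DEP entrance (mm)", y = "lsrR signal",
                  colour = "time (s)",
                  title = "Simulated QS reporter along the DEP")
}

# autoplot/tidy/glance generics: use ggplot2's / generics' when available,
# otherwise define local S3 generics so the methods are callable.
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
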