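#' Run the end-to-end synthetic colonization pipeline
#'
#' Orchestrates geometry generation, pore classification, Stokes flow,
#' tracer displacement, biomass and reporter quantification and the coupled
#' glucose/AI-2 model, writing CSV/PNG artifacts and a JSON manifest
#' (seeds, parameter hash, per-stage status) to `outdir`. A single global
#' seed expands deterministically into per-module seeds, so one number
#' reproduces a whole run.
#'
#' @param config A named list (see Details) or the path to a YAML file.
#' @param outdir Output directory (default `config$outdir` or a tempdir).
#' @param dry_run Validate the configuration and return the resolved stage
#'   plan without computing.
#' @details Recognised blocks: `geometry` (fields of [geometry_params()];
#'   required unless `mask` gives a mask image path), `flow`
#'   ([flow_config()] fields), `tracer` (`t_end_pv`, `dt`), `biomass`
#'   (`n_frames`, `interval_s`, `ratio_from`, `ratio_to`, `amplitude_max`,
#'   `noise_sd`, cluster settings), `reporter` (`front_depth_mm`,
#'   `steepness`), `model` ([model_params()] fields plus `c_B`, `t_end`),
#'   `stages` (subset of simulate, classify, flow, tracer, quantify,
#'   profile, model), `seed`, `scenario`.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, outdir = NULL, dry_run = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("package 'yaml' required to read config files")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  all_stages <- c("simulate", "classify", "flow", "tracer", "quantify",
                  "profile", "model")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$geometry) && is.null(config$mask))
    stop("configuration error: missing block 'geometry' (or 'mask')")
  seed <- as.integer(config$seed %||% 1L)
  seeds <- seed + c(geometry = 101L, biomass = 202L, reporter = 303L,
                    tracer = 404L)
  outdir <- outdir %||% config$outdir %||% file.path(tempdir(), "porescape-run")
  manifest <- list(
    scenario = config$scenario %||% "unnamed",
    package_version = as.character(utils::packageVersion("porescape")),
    seed = seed, module_seeds = as.list(seeds),
    config_hash = config_hash(config),
    stages = stages, status = list(), outputs = character(0))
  if (dry_run) return(invisible(manifest))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  emit <- function(name) {
    manifest$outputs <<- c(manifest$outputs, name)
    file.path(outdir, name)
  }
  done <- function(st) manifest$status[[st]] <<- "ok"
  state <- new.env(parent = emptyenv())

  run_stage <- function(st, fn) {
    if (!(st %in% stages)) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status[[st]] <<- paste("failed:", conditionMessage(res))
      manifest$aborted_after <<- st
      write_manifest(manifest, outdir)
      stop("stage '", st, "' failed: ", conditionMessage(res))
    }
    done(st)
  }

  run_stage("simulate", function() {
    gp <- do.call(geometry_params,
                  utils::modifyList(config$geometry %||% list(),
                                    list(seed = seeds[["geometry"]])))
    state$scene <- generate_geometry(gp)
    write_pore_mask(state$scene$mask, emit("mask.png"))
    utils::write.csv(state$scene$truth$cavities, emit("cavities_truth.csv"),
                     row.names = FALSE)
  })
  run_stage("classify", function() {
    d <- discretize_pores(state$scene$mask)
    state$disc <- d
    write_label_map(d$label_map, emit("label_map.png"), emit("deps.csv"))
    st <- d$stats
    utils::write.csv(
      data.frame(lambda_m_um = st$lambda_m_um,
                 dep_volume_fraction = st$dep_volume_fraction,
                 porosity = st$porosity, n_dep = st$n_dep),
      emit("pore_stats.csv"), row.names = FALSE)
  })
  run_stage("flow", function() {
    fc <- do.call(flow_config, config$flow %||% list())
    state$field <- solve_stokes(state$scene$mask, fc)
    utils::write.csv(
      data.frame(u_m_um_s = state$field$u_m,
                 divergence_max = state$field$div_max,
                 shear_rate_s = shear_rate(state$field, fc)),
      emit("velocity_summary.csv"), row.names = FALSE)
  })
  run_stage("tracer", function() {
    tc <- config$tracer %||% list()
    pv <- scene_pv_time(state$scene$mask, state$field)
    series <- simulate_tracer(state$scene$mask, state$field,
                              D = tc$D %||% 6e-4,
                              t_end = (tc$t_end_pv %||% 3) * pv,
                              dt = tc$dt %||% 1)
    pers <- gradient_persistence(series, state$disc$label_map)
    pers$persistence_pv <- pers$persistence_s / pv
    utils::write.csv(pers, emit("gradient_persistence.csv"), row.names = FALSE)
    state$tracer <- series
  })
  run_stage("quantify", function() {
    bc <- config$biomass %||% list()
    nf <- bc$n_frames %||% 13L
    times <- seq(0, by = bc$interval_s %||% 3600, length.out = nf)
    ratio <- seq(bc$ratio_from %||% 1, bc$ratio_to %||% 2.5, length.out = nf)
    gen <- generate_biomass_stack(
      state$disc$label_map, times, ratio,
      amplitude = seq(0, bc$amplitude_max %||% 400, length.out = nf),
      clusters_per_dep = bc$clusters_per_dep %||% 2,
      clusters_tp = bc$clusters_tp %||% 8,
      noise_sd = bc$noise_sd %||% 50,
      seed = seeds[["biomass"]])
    state$biomass_gen <- gen
    corr <- preprocess_stack(gen$stack, state$disc$label_map)
    state$biomass_corr <- corr
    utils::write.csv(retention_curve(corr, state$disc$label_map),
                     emit("retention_curve.csv"), row.names = FALSE)
    utils::write.csv(biomass_timeseries(corr, state$disc$label_map),
                     emit("biomass_series.csv"), row.names = FALSE)
    cl <- detect_clusters_stack(corr, state$disc$label_map)
    utils::write.csv(cl[, setdiff(names(cl), "pixels")],
                     emit("clusters.csv"), row.names = FALSE)
  })
  run_stage("profile", function() {
    rc <- config$reporter %||% list()
    front <- rc$front_depth_mm %||% 0.1
    front <- pmin(front, vapply(state$disc$label_map$dep_regions,
                                function(r) r$depth_mm, numeric(1)) * 0.9)
    rep_gen <- generate_reporter_stack(
      state$disc$label_map, state$biomass_gen, front,
      steepness = rc$steepness %||% 200,
      noise_sd = rc$noise_sd %||% 5, seed = seeds[["reporter"]])
    corr_rep <- preprocess_stack(rep_gen$stack, state$disc$label_map)
    nf <- length(corr_rep$frames)
    act <- normalize_activity(corr_rep$frames[[nf]],
                              state$biomass_corr$frames[[nf]],
                              floor = 1)
    prof <- dep_depth_profile(act, state$disc$label_map,
                              state$disc$skeleton, state$disc$disks,
                              biomass_frame = state$biomass_corr$frames[[nf]])
    utils::write.csv(prof, emit("profiles.csv"), row.names = FALSE)
    utils::write.csv(extract_front(prof), emit("fronts.csv"), row.names = FALSE)
  })
  run_stage("model", function() {
    mc <- config$model %||% list()
    c_B <- mc$c_B %||% 0.02
    pars <- do.call(model_params,
                    mc[intersect(names(mc), names(formals(model_params)))])
    soln <- solve_coupled_model(pars, c_B, t_end = mc$t_end %||% 1800)
    long <- do.call(rbind, lapply(seq_along(soln$times), function(ti)
      data.frame(x_mm = soln$x, t_s = soln$times[ti],
                 c_G = soln$c_G[, ti], c_AI2 = soln$c_AI2[, ti],
                 lsrR = soln$lsrR[, ti])))
    utils::write.csv(long, emit("model_solution.csv"), row.names = FALSE)
    zs <- predict_zeta_scaling(pars, c_B)
    zeta <- data.frame(t_s = soln$times,
                       zeta_sim_mm = vapply(soln$times, function(t)
                         if (t <= 0) NA_real_ else extract_zeta_sim(soln, t),
                         numeric(1)),
                       zeta_scaling_mm = zs$zeta_scaling,
                       tau_U_s = zs$tau_U)
    utils::write.csv(zeta, emit("zeta.csv"), row.names = FALSE)
  })
  write_manifest(manifest, outdir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

write_manifest <- function(manifest, outdir) {
  path <- file.path(outdir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(manifest, file = sub("json$", "txt", path))
  }
  invisible(path)
}
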