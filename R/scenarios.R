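# Scenario orchestration: configuration, run phases, metrics, reports.

.SCENARIOS <- c("homeostasis", "ulcer", "recovery", "knockout", "pouchitis")

#' Build a scenario configuration
#'
#' Assembles and validates everything a run needs: scenario name, pouch
#' geometry (anatomic cylinder dimensions plus the desk-scale run lattice
#' actually simulated), rule/network/stool parameter overrides,
#' scenario-specific perturbation settings, seed, workers, step count and
#' output options. The configuration round-trips losslessly through YAML
#' (see [write_scenario_config()]).
#'
#' The run lattice is a coarse sub-sampling of the anatomic unit lattice:
#' the simulated axial rows are spread over the full pouch length so axial
#' positions (and the stool fill map) span the anatomy, while the number of
#' units stays desk-scale. The anatomic lattice implied by the cylinder
#' dimensions is reported in the resolved configuration.
#'
#' @param scenario one of homeostasis, ulcer, recovery, knockout, pouchitis.
#' @param geometry list: `diameter_cm`, `length_cm`, `unit_spacing_mm`,
#'   `run_n_axial`, `run_n_circ`, and `template` (villus_height, crypt_depth,
#'   face_width). Missing entries take scenario defaults.
#' @param n_steps total steps to run.
#' @param equilibration steps before the scenario perturbation; excluded
#'   from steady-state metrics.
#' @param seed integer master seed.
#' @param workers logical worker count.
#' @param rules,signaling,stool partial parameter overrides (merged over
#'   [default_params()]).
#' @param ulcer,recovery,knockout scenario-specific settings.
#' @param out_dir optional output directory (CSV series, metrics, resolved
#'   config, dumps, log).
#' @param dump_every write a per-site state dump every this many steps
#'   (0 = never).
#' @param dump_fields mediators included in state dumps.
#' @param debug enable per-step invariant checks.
#' @return a `scenario_config` object.
#' @export
scenario_config <- function(scenario = "homeostasis",
                            geometry = list(),
                            n_steps = 2000L,
                            equilibration = 500L,
                            seed = 1L,
                            workers = 1L,
                            rules = list(),
                            signaling = list(),
                            stool = list(),
                            ulcer = list(),
                            recovery = list(),
                            knockout = list(),
                            out_dir = NULL,
                            dump_every = 0L,
                            dump_fields = c("WNT", "BMP", "TLR_ACT", "ROS"),
                            debug = FALSE) {
  if (!scenario %in% .SCENARIOS)
    stop(sprintf("scenario: must be one of %s (got \"%s\")",
                 paste(.SCENARIOS, collapse = ", "), scenario), call. = FALSE)
  gdef <- list(diameter_cm = 3.5, length_cm = 6, unit_spacing_mm = 0.5,
               run_n_axial = if (scenario == "pouchitis") 10L else 8L,
               run_n_circ = if (scenario == "pouchitis") 4L else 8L,
               template = list(villus_height = 50L, crypt_depth = 12L,
                               face_width = 6L))
  geometry <- utils::modifyList(gdef, geometry)
  for (f in c("diameter_cm", "length_cm", "unit_spacing_mm")) {
    v <- geometry[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stop(sprintf("geometry$%s: must be a single positive number", f),
           call. = FALSE)
  }
  for (f in c("run_n_axial", "run_n_circ")) {
    v <- geometry[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop(sprintf("geometry$%s: must be a positive integer", f),
           call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop("n_steps: must be a positive integer", call. = FALSE)
  equilibration <- as.integer(equilibration)
  if (is.na(equilibration) || equilibration < 0L || equilibration > n_steps)
    stop("equilibration: must be an integer in [0, n_steps]", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed: must be a single integer", call. = FALSE)
  if (!is.numeric(workers) || length(workers) != 1 || workers < 1)
    stop("workers: must be a positive integer", call. = FALSE)
  udef <- list(center = NULL, radius_sites = 6L, bolus_tnfa = 2, bolus_ros = 2)
  rdef <- list(ros_magnitude = 3, duration = 100L, axial_rows = NULL)
  kdef <- list(mediator = "WNT")
  ulcer <- utils::modifyList(udef, ulcer)
  recovery <- utils::modifyList(rdef, recovery)
  knockout <- utils::modifyList(kdef, knockout)
  if (!toupper(knockout$mediator) %in% mediator_ids())
    stop(sprintf("knockout$mediator: unknown mediator \"%s\"",
                 knockout$mediator), call. = FALSE)
  if (scenario == "pouchitis") stool <- utils::modifyList(stool, list())
  cfg <- structure(list(
    scenario = scenario, geometry = geometry,
    n_steps = n_steps, equilibration = equilibration,
    seed = as.integer(seed), workers = as.integer(workers),
    rules = rules, signaling = signaling, stool = stool,
    ulcer = ulcer, recovery = recovery, knockout = knockout,
    out_dir = out_dir, dump_every = as.integer(dump_every),
    dump_fields = dump_fields, debug = isTRUE(debug)),
    class = "scenario_config")
  # fail now, with field-level messages, rather than after compute starts
  .resolve_config(cfg)
  cfg
}

# fully-materialized configuration: anatomic lattice, run lattice, all
# parameter defaults merged in -- this is what gets echoed beside outputs
.resolve_config <- function(cfg) {
  g <- cfg$geometry
  anat <- build_pouch(g$diameter_cm, g$length_cm, g$unit_spacing_mm,
                      do.call(crypt_villus_unit, g$template))
  params <- default_params(rules = cfg$rules, signaling = cfg$signaling,
                           stool = cfg$stool, debug = cfg$debug)
  run_spacing <- g$length_cm * 10 / g$run_n_axial
  list(scenario = cfg$scenario,
       geometry = list(diameter_cm = g$diameter_cm, length_cm = g$length_cm,
                       unit_spacing_mm = g$unit_spacing_mm,
                       n_axial = anat$n_axial, n_circ = anat$n_circ,
                       n_sites = n_sites(anat),
                       run_n_axial = as.integer(g$run_n_axial),
                       run_n_circ = as.integer(g$run_n_circ),
                       run_unit_spacing_mm = run_spacing,
                       template = g$template),
       n_steps = cfg$n_steps, equilibration = cfg$equilibration,
       seed = cfg$seed, workers = cfg$workers,
       params = params,
       ulcer = cfg$ulcer, recovery = cfg$recovery, knockout = cfg$knockout,
       dump_every = cfg$dump_every, dump_fields = cfg$dump_fields)
}

.run_geometry <- function(cfg) {
  g <- cfg$geometry
  lattice_pouch(g$run_n_axial, g$run_n_circ,
                do.call(crypt_villus_unit, g$template),
                unit_spacing_mm = g$length_cm * 10 / g$run_n_axial)
}

#' Run a scenario
#'
#' Executes init -> equilibration -> perturbation -> recovery/observation and
#' collects the population time series, final tissue metrics and (optionally)
#' on-disk outputs: `population.csv`, `metrics.csv`, `resolved_config.yaml`,
#' periodic per-site dumps and a line-oriented log. A fixed (config, seed)
#' pair determines every output byte; the worker count does not affect any
#' result.
#'
#' Perturbations at the end of equilibration: `ulcer` applies a circular
#' ulcer; `recovery` holds a ROS patch on part of the tissue for a configured
#' duration, then removes it; `knockout` silences a mediator; `pouchitis`
#' switches on the stool cycle. `homeostasis` runs unperturbed.
#'
#' @param config a `scenario_config`.
#' @return a `pouchsim_run` object: list with `config` (resolved), `series`
#'   (tibble), `metrics` (see [compute_metrics()]), `state` (final
#'   `tissue_state`) and `out_dir`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  rcfg <- .resolve_config(config)
  geom <- .run_geometry(config)
  ts <- init_tissue(geom, rcfg$params, seed = rcfg$seed,
                    workers = rcfg$workers)
  out <- config$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_resolved_config(rcfg, file.path(out, "resolved_config.yaml"))
    if (rcfg$dump_every > 0)
      dir.create(file.path(out, "dumps"), showWarnings = FALSE)
  }
  eq <- rcfg$equilibration
  n <- rcfg$n_steps
  recov <- rcfg$recovery
  ros_until <- -1L
  ros_sites <- integer(0)
  rows <- vector("list", n)
  log <- character(0)
  for (k in seq_len(n)) {
    if (k == eq + 1L) {
      # perturbation phase
      if (rcfg$scenario == "ulcer") {
        ts <- apply_ulcer(ts, center = rcfg$ulcer$center,
                          radius_sites = rcfg$ulcer$radius_sites,
                          bolus_tnfa = rcfg$ulcer$bolus_tnfa,
                          bolus_ros = rcfg$ulcer$bolus_ros)
        log <- c(log, sprintf("step %d: ulcer radius %d removed %d agents",
                              ts$step, rcfg$ulcer$radius_sites,
                              ts$last_ulcer$removed))
      } else if (rcfg$scenario == "recovery") {
        ax <- recov$axial_rows
        if (is.null(ax)) {
          mid <- geom$n_axial %/% 2
          ax <- unique(pmin(pmax(c(mid - 1L, mid), 0L), geom$n_axial - 1L))
        }
        ros_sites <- which(ts$idx$axial %in% ax & ts$idx$comp == .VILLUS)
        ros_until <- eq + as.integer(recov$duration)
        log <- c(log, sprintf(
          "step %d: sustained ROS %.3g applied on axial rows %s until step %d",
          ts$step, recov$ros_magnitude, paste(ax, collapse = ","), ros_until))
      } else if (rcfg$scenario == "knockout") {
        ts$params <- apply_knockout(ts$params, rcfg$knockout$mediator)
        for (i in seq_along(ts$dec$workers))
          ts$dec$workers[[i]] <- .prepare_worker_static(
            ts$dec$workers[[i]], ts$params, ts$seed)
        log <- c(log, sprintf("step %d: knockout of %s",
                              ts$step, toupper(rcfg$knockout$mediator)))
      } else if (rcfg$scenario == "pouchitis") {
        ts <- enable_stool(ts)
        log <- c(log, sprintf("step %d: stool cycle enabled (delta_ip %.4g)",
                              ts$step, ts$params$stool$delta_ip))
      }
    }
    if (ros_until >= 0L && ts$step < ros_until && length(ros_sites))
      ts <- .inject_field(ts, ros_sites, "ROS", recov$ros_magnitude)
    ts <- tissue_step(ts)
    cnt <- agent_counts(ts)
    rows[[k]] <- c(step = ts$step, cnt, births = ts$last_stats$births,
                   deaths = ts$last_stats$deaths,
                   sheds = ts$last_stats$sheds)
    if (!is.null(out) && rcfg$dump_every > 0 &&
        ts$step %% rcfg$dump_every == 0L)
      write_state_dump(ts, file.path(out, "dumps",
                                     sprintf("step_%06d.csv", ts$step)),
                       fields = rcfg$dump_fields)
  }
  m <- do.call(rbind, rows)
  series <- tibble::as_tibble(as.data.frame(m))
  series$sim_hours <- series$step * 0.25
  series <- series[, c("step", "sim_hours", "total", "crypt", "villus",
                       "stem", "progenitor", "enterocyte", "metaplastic",
                       "births", "deaths", "sheds")]
  names(series) <- c("step", "sim_hours", "n_total", "n_crypt", "n_villus",
                     "n_stem", "n_progenitor", "n_enterocyte",
                     "n_metaplastic", "births", "deaths", "sheds")
  metrics <- compute_metrics(ts, series = series, equilibration = eq)
  log <- c(log, ts$log)
  if (!is.null(out)) {
    utils::write.csv(series, file.path(out, "population.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(metrics$axial_bins, file.path(out, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(log, file.path(out, "log.txt"))
  }
  structure(list(config = rcfg, series = series, metrics = metrics,
                 state = ts, out_dir = out, log = log),
            class = "pouchsim_run")
}

#' @export
print.pouchsim_run <- function(x, ...) {
  cat(sprintf("<pouchsim_run> %s, %d steps on %dx%d units (seed %d, %d workers)\n",
              x$config$scenario, x$config$n_steps,
              x$config$geometry$run_n_axial, x$config$geometry$run_n_circ,
              x$config$seed, x$config$workers))
  cat(sprintf("  final population %d, villus:crypt ratio %.3g\n",
              utils::tail(x$series$n_total, 1),
              x$metrics$villus_crypt_ratio))
  invisible(x)
}

# additive field injection at owned sites (used by the recovery stimulus)
.inject_field <- function(ts, sites, mediator, amount) {
  for (i in seq_along(ts$dec$workers)) {
    w <- ts$dec$workers[[i]]
    hit <- which(w$gid %in% sites & seq_len(w$n_local) <= w$n_owned)
    if (length(hit)) {
      w$fields[[mediator]][hit] <- w$fields[[mediator]][hit] + amount
      ts$dec$workers[[i]] <- w
    }
  }
  ts$med_max[[mediator]] <- max(ts$med_max[[mediator]], amount)
  ts
}

#' Tissue metrics
#'
#' Villus:crypt population ratio, per-axial-bin mean villus height and
#' metaplastic unit fraction (up to 10 bins covering the pouch axis
#' exactly), and -- when a population series is supplied -- steady-state
#' statistics over the post-equilibration window.
#'
#' @param ts a `tissue_state`.
#' @param series optional population series tibble (from [run_scenario()]).
#' @param equilibration steps to exclude from steady-state statistics.
#' @return a `tissue_metrics` list: `villus_crypt_ratio` (NA with a message
#'   when the crypt population is zero), `counts`, `axial_bins` (tibble with
#'   `bin`, `axial_mm_mid`, `mean_villus_height`, `metaplastic_fraction`),
#'   and `steady` (mean/CV of total population, births and sheds per step).
#' @export
compute_metrics <- function(ts, series = NULL, equilibration = 0L) {
  stopifnot(inherits(ts, "tissue_state"))
  cnt <- agent_counts(ts)
  ratio <- if (cnt[["crypt"]] == 0) {
    message("crypt population is zero: villus:crypt ratio undefined")
    NA_real_
  } else cnt[["villus"]] / cnt[["crypt"]]
  un <- ts$geom$units
  nb <- min(10L, ts$geom$n_axial)
  grp <- findInterval(un$axial, seq(0, ts$geom$n_axial, length.out = nb + 1),
                      rightmost.closed = TRUE)
  axial_mm <- (un$axial + 0.5) * ts$geom$unit_spacing_mm
  bins <- tibble::tibble(
    bin = seq_len(nb),
    axial_mm_mid = as.numeric(tapply(axial_mm, grp, mean)),
    mean_villus_height = as.numeric(tapply(un$villus_height, grp, mean)),
    metaplastic_fraction = as.numeric(tapply(ts$meta_flag, grp, mean)))
  steady <- NULL
  if (!is.null(series)) {
    post <- series[series$step > equilibration, ]
    steady <- list(
      n_mean = mean(post$n_total),
      n_cv = stats::sd(post$n_total) / mean(post$n_total),
      births_per_step = mean(post$births),
      sheds_per_step = mean(post$sheds),
      deaths_per_step = mean(post$deaths))
  }
  structure(list(villus_crypt_ratio = as.numeric(ratio),
                 counts = cnt, axial_bins = bins, steady = steady),
            class = "tissue_metrics")
}

#' @export
print.tissue_metrics <- function(x, ...) {
  cat(sprintf("<tissue_metrics> villus:crypt ratio %.3g, %d agents\n",
              x$villus_crypt_ratio, x$counts[["total"]]))
  if (!is.null(x$steady))
    cat(sprintf("  steady state: mean %0.1f cells, CV %.3g%%, births %.2f/step, sheds %.2f/step\n",
                x$steady$n_mean, 100 * x$steady$n_cv,
                x$steady$births_per_step, x$steady$sheds_per_step))
  invisible(x)
}

#' Pouchitis gradient report
#'
#' Summarizes the axial distribution of metaplasia after a pouchitis run:
#' per-axial-bin final mean villus height and metaplastic unit fraction,
#' plus a Spearman test of unit villus height against axial position. The
#' `gradient_toward_terminal` flag is TRUE when heights decrease
#' significantly toward the terminal (distal) end (rho < 0, p < 0.05).
#'
#' @param x a `pouchsim_run` or `tissue_state`.
#' @return list with `table` (the per-bin tibble), `spearman_rho`,
#'   `p_value`, `gradient_toward_terminal`.
#' @export
pouchitis_gradient_report <- function(x) {
  ts <- if (inherits(x, "pouchsim_run")) x$state else x
  stopifnot(inherits(ts, "tissue_state"))
  m <- compute_metrics(ts)
  un <- ts$geom$units
  sp <- suppressWarnings(stats::cor.test(un$axial, un$villus_height,
                                         method = "spearman",
                                         alternative = "less"))
  rho <- unname(sp$estimate)
  list(table = m$axial_bins,
       spearman_rho = rho,
       p_value = sp$p.value,
       gradient_toward_terminal = is.finite(rho) && rho < 0 &&
         sp$p.value < 0.05)
}

#' Calibrate the stool inflammatory-potential increment
#'
#' Bisects `delta_ip` until the metaplastic unit fraction in the terminal
#' quartile of the pouch reaches the target, running the (reduced-scale)
#' pouchitis scenario once per candidate. Terminal metaplasia is monotone
#' non-decreasing in `delta_ip`, so bisection converges; each run is fully
#' deterministic under the configured seed, making the calibration
#' reproducible bit for bit.
#'
#' @param target_metaplasia_fraction target fraction in `[0, 1]`; 0 returns
#'   the lower bound immediately.
#' @param bounds numeric `c(lower, upper)` search interval for `delta_ip`.
#' @param config a pouchitis `scenario_config` (reduced scale recommended).
#' @param tol absolute tolerance on `delta_ip`.
#' @param max_iter maximum bisection iterations.
#' @return list with `delta_ip` (smallest value reaching the target within
#'   tolerance) and `trace` (tibble of evaluated candidates and fractions).
#' @export
calibrate_delta_ip <- function(target_metaplasia_fraction,
                               bounds = c(0, 0.5),
                               config,
                               tol = 1e-3, max_iter = 12L) {
  stopifnot(inherits(config, "scenario_config"),
            config$scenario == "pouchitis",
            length(bounds) == 2, bounds[1] >= 0, bounds[2] > bounds[1],
            target_metaplasia_fraction >= 0,
            target_metaplasia_fraction <= 1)
  trace <- list()
  eval_frac <- function(d) {
    cfg <- config
    cfg$stool <- utils::modifyList(cfg$stool, list(delta_ip = d))
    run <- run_scenario(cfg)
    un <- run$state$geom$units
    term <- un$axial >= max(un$axial) * 0.75
    frac <- mean(run$state$meta_flag[term])
    trace[[length(trace) + 1L]] <<- c(delta_ip = d, terminal_fraction = frac)
    frac
  }
  done <- function(d) list(delta_ip = d,
                           trace = tibble::as_tibble(as.data.frame(
                             do.call(rbind, trace))))
  if (target_metaplasia_fraction == 0) {
    trace[[1L]] <- c(delta_ip = bounds[1], terminal_fraction = 0)
    return(done(bounds[1]))
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_hi <- eval_frac(hi)
  if (f_hi < target_metaplasia_fraction) {
    tr <- done(NA_real_)$trace
    stop(paste0(
      sprintf("target %.3g unreachable within bounds [%.4g, %.4g]: ",
              target_metaplasia_fraction, lo, hi),
      sprintf("upper bound gives %.3g; trace: %s", f_hi,
              paste(sprintf("(%.4g -> %.3g)", tr$delta_ip,
                            tr$terminal_fraction), collapse = " "))),
      call. = FALSE)
  }
  for (it in seq_len(max_iter)) {
    if (hi - lo <= tol) break
    mid <- (lo + hi) / 2
    if (eval_frac(mid) >= target_metaplasia_fraction) hi <- mid else lo <- mid
  }
  done(hi)
}
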