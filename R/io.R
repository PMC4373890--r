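# Structured-text I/O: YAML configs, CSV dumps, PLY meshes.

#' Write a scenario configuration to YAML
#'
#' @param config a `scenario_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$out_dir <- if (is.null(x$out_dir)) "" else x$out_dir
  x$ulcer$center <- if (is.null(x$ulcer$center)) "" else x$ulcer$center
  x$recovery$axial_rows <- if (is.null(x$recovery$axial_rows)) ""
    else x$recovery$axial_rows
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path a YAML file written by [write_scenario_config()] (or by hand
#'   with the same fields).
#' @return a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  blank_null <- function(v) if (is.null(v) || identical(v, "")) NULL else v
  scenario_config(
    scenario = x$scenario,
    geometry = x$geometry,
    n_steps = x$n_steps,
    equilibration = x$equilibration,
    seed = x$seed,
    workers = x$workers,
    rules = if (is.null(x$rules)) list() else x$rules,
    signaling = if (is.null(x$signaling)) list() else x$signaling,
    stool = if (is.null(x$stool)) list() else x$stool,
    ulcer = utils::modifyList(if (is.null(x$ulcer)) list() else x$ulcer,
                              list(center = blank_null(x$ulcer$center))),
    recovery = utils::modifyList(
      if (is.null(x$recovery)) list() else x$recovery,
      list(axial_rows = blank_null(x$recovery$axial_rows))),
    knockout = if (is.null(x$knockout)) list() else x$knockout,
    out_dir = blank_null(x$out_dir),
    dump_every = if (is.null(x$dump_every)) 0L else x$dump_every,
    dump_fields = x$dump_fields,
    debug = isTRUE(x$debug))
}

#' Write the fully resolved configuration beside run outputs
#'
#' The resolved configuration materializes every default: the anatomic unit
#' lattice implied by the cylinder dimensions, the run lattice, and the
#' complete parameter set (the signaling edge table is flattened to
#' `source/target/sign/weight` records).
#'
#' @param rcfg resolved configuration (as stored in a `pouchsim_run`).
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(rcfg, path) {
  x <- rcfg
  x$params$signaling$edges <- lapply(
    seq_len(nrow(rcfg$params$signaling$edges)),
    function(i) as.list(rcfg$params$signaling$edges[i, ]))
  x$ulcer$center <- if (is.null(x$ulcer$center)) "" else x$ulcer$center
  x$recovery$axial_rows <- if (is.null(x$recovery$axial_rows)) ""
    else x$recovery$axial_rows
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a per-site state dump
#'
#' CSV with one row per occupied site: coordinates, lineage, cell id, cycle
#' clock, health, accumulated exposure and the selected mediator
#' concentrations. Deterministic byte-for-byte for a fixed state.
#'
#' @param ts a `tissue_state`.
#' @param path output CSV file.
#' @param fields mediators to include.
#' @return `path`, invisibly.
#' @export
write_state_dump <- function(ts, path, fields = c("WNT", "BMP", "TLR_ACT",
                                                  "ROS")) {
  st <- gather_state(ts, fields = fields, occupied_only = TRUE)
  utils::write.csv(st, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.LINEAGE_RGB <- matrix(c(
  178, 34, 34,     # STEM: firebrick
  255, 165, 0,     # PROGENITOR: orange
  60, 179, 113,    # ENTEROCYTE: medium sea green
  106, 90, 205),   # METAPLASTIC: slate blue
  ncol = 3, byrow = TRUE,
  dimnames = list(c("STEM", "PROGENITOR", "ENTEROCYTE", "METAPLASTIC"),
                  c("red", "green", "blue")))

#' Export occupied sites as a PLY surface point mesh
#'
#' One vertex per occupied site at its [to_3d()] coordinates, colored by
#' lineage (ASCII PLY 1.0, re-readable with [read_mesh_ply()]). Large runs
#' are typically exported as sub-region cutouts via `units`.
#'
#' @param ts a `tissue_state`.
#' @param path output `.ply` file.
#' @param units optional 0-based unit indices to restrict the cutout.
#' @param cell_diameter_um cell diameter used by the embedding.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(ts, path, units = NULL, cell_diameter_um = 10) {
  stopifnot(inherits(ts, "tissue_state"))
  G <- .gather_arrays(ts)
  idx <- ts$idx
  sel <- which(G$lin != .EMPTY)
  if (!is.null(units)) sel <- sel[idx$unit[sel] %in% units]
  xyz <- if (length(sel)) to_3d(idx, sel, cell_diameter_um)
  else matrix(numeric(0), 0, 3)
  rgb <- .LINEAGE_RGB[G$lin[sel], , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply",
               "format ascii 1.0",
               "comment crypt-villus tissue cutout",
               sprintf("element vertex %d", length(sel)),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue",
               "end_header"), con)
  if (length(sel))
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d",
                       xyz[, 1], xyz[, 2], xyz[, 3],
                       rgb[, 1], rgb[, 2], rgb[, 3]), con)
  invisible(path)
}

#' Read an ASCII PLY point mesh
#'
#' @param path a `.ply` file written by [export_mesh()] (or any ASCII PLY
#'   with x/y/z float and red/green/blue uchar vertex properties).
#' @return tibble with columns `x`, `y`, `z`, `red`, `green`, `blue`.
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "ply" ||
      !grepl("^format ascii", lines[2]))
    stop("not an ASCII PLY file", call. = FALSE)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("PLY header not terminated", call. = FALSE)
  nv_line <- grep("^element vertex ", lines[seq_len(hdr_end)], value = TRUE)
  nv <- as.integer(sub("^element vertex ", "", nv_line[1]))
  if (nv == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          red = integer(0), green = integer(0),
                          blue = integer(0)))
  body <- lines[(hdr_end + 1):(hdr_end + nv)]
  m <- do.call(rbind, lapply(strsplit(body, " ", fixed = TRUE), as.numeric))
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3],
                 red = as.integer(m[, 4]), green = as.integer(m[, 5]),
                 blue = as.integer(m[, 6]))
}

#' Write a gradient profile to CSV
#'
#' Columns `row` (axis row from the crypt base), `mediator`,
#' `mean_concentration`; the format used for gradient validation outputs.
#'
#' @param profiles named list of profile tibbles from [gradient_profile()]
#'   (names are mediator ids), or a single tibble with `mediator` set.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_gradient_csv <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(row = p$axis_row,
               mediator = if (!is.null(names(profiles)[i]) &&
                              nzchar(names(profiles)[i]))
                 names(profiles)[i] else p$mediator,
               mean_concentration = p$mean_concentration)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
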