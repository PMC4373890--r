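# Exported single-rule steps and localized perturbations.
#
# Each step_* function advances the simulation clock by one step but applies
# only its own rule -- the full schedule lives in tissue_step(). They share
# the engine's two-phase kernels, so a rule exercised in isolation behaves
# exactly as it does inside a full step (including ghost exchanges and
# counter-based RNG draws), which is what the rule-level tests rely on.

#' Division rule for one timestep
#'
#' Advances cycle clocks, then lets every stem or progenitor cell whose
#' clock has reached its cycle length divide, provided the local
#' proliferation drive (Wnt plus the STAT3 coupling) is at least
#' `theta_wnt` and an empty neighbour site exists (contact inhibition
#' otherwise). The daughter is placed on an empty neighbour chosen
#' deterministically via the site RNG; competing placements onto one site
#' are resolved by the destination owner. Stem daughters placed in the
#' crypt base rows remain stem, all others become progenitors; both clocks
#' reset on success.
#'
#' @param ts a `tissue_state`.
#' @return the updated state (`last_stats$births` holds the division count).
#' @export
step_division <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  t <- ts$step + 1L
  ts$step <- t
  ts <- .phase_clocks(ts)
  .phase_division(ts, t)
}

#' Differentiation rule for one timestep
#'
#' Progenitors become enterocytes when local BMP reaches `theta_bmp` or when
#' their site lies in the villus component (positional rule); irreversible
#' except through metaplastic conversion.
#'
#' @param ts a `tissue_state`.
#' @return the updated state.
#' @export
step_differentiation <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  ts$step <- ts$step + 1L
  ts <- .phase_differentiation(ts)
  exchange_ghosts(ts, "agents")
}

#' Migration rule for one timestep
#'
#' Non-stem agents attempt one move toward higher rank along the
#' crypt-base -> villus-tip axis (crypt mouth, across the inter-unit flat,
#' villus base, tip) into an empty neighbour site; conflicts are resolved
#' deterministically by the destination owner. The net effect is the
#' conveyor-belt flux from crypt to tip; in a fully confluent tissue nothing
#' moves.
#'
#' @param ts a `tissue_state`.
#' @return the updated state.
#' @export
step_migration <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  t <- ts$step + 1L
  ts$step <- t
  .phase_migration(ts, t)
}

#' Shedding rule for one timestep
#'
#' Enterocytes and metaplastic cells in the shed zone (top `shed_rows`
#' villus rows plus the tip cap; extended down to the reduced target height
#' in metaplastic units) are removed with probability `p_shed` per step.
#'
#' @param ts a `tissue_state`.
#' @return the updated state (`last_stats$sheds` holds the count).
#' @export
step_shedding <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  t <- ts$step + 1L
  ts$step <- t
  ts <- .phase_shedding(ts, t)
  exchange_ghosts(ts, "agents")
}

#' Inflammation-mediated death rule for one timestep
#'
#' Every agent dies with probability
#' `1 - exp(-(a_ros * ROS + a_tnfa * TNFA))` evaluated at its site: zero in
#' clean tissue and monotone non-decreasing in both mediators.
#'
#' @param ts a `tissue_state`.
#' @return the updated state (`last_stats$deaths` holds the count).
#' @export
step_death <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  t <- ts$step + 1L
  ts$step <- t
  ts <- .phase_death(ts, t)
  exchange_ghosts(ts, "agents")
}

#' Exposure accumulation and metaplastic conversion for one timestep
#'
#' Agents in stool-contacted units accumulate `TLR_ACT * IP` exposure; when
#' a unit's mean exposure crosses the metaplasia threshold the unit is
#' flagged, resident enterocytes convert to the metaplastic phenotype and
#' the unit's villus target height drops (monotone in exposure, floor >= 1).
#' At the periodic resize check, empty rows above the target are removed.
#'
#' @param ts a `tissue_state`.
#' @return the updated state.
#' @export
step_metaplasia <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  t <- ts$step + 1L
  ts$step <- t
  .phase_metaplasia(ts, t)
}

# ball of graph distance <= radius around `center` on the folded surface
.graph_ball <- function(idx, center, radius) {
  visited <- logical(idx$N)
  visited[center] <- TRUE
  frontier <- center
  r <- 0L
  while (r < radius && length(frontier)) {
    nb <- idx$nbr[frontier, , drop = FALSE]
    nb <- unique(nb[!is.na(nb)])
    frontier <- nb[!visited[nb]]
    visited[frontier] <- TRUE
    r <- r + 1L
  }
  which(visited)
}

#' Apply a circular ulcer
#'
#' Removes every agent within the given folded-graph distance of the centre
#' site and deposits an inflammatory bolus (TNF-alpha and ROS) on the wound
#' bed. With a zero bolus the wound simply re-epithelializes by division and
#' migration; with a bolus it spreads slightly before healing.
#'
#' @param ts a `tissue_state`.
#' @param center a site id, or a one-row coordinate data frame (see
#'   [coord_to_site()]). Default: villus base of the central unit.
#' @param radius_sites integer graph-distance radius (0 removes exactly the
#'   centre site's agent).
#' @param bolus_tnfa,bolus_ros concentration added at each wound site.
#' @return the updated state; `ts$last_ulcer` lists the wound sites and the
#'   number of agents removed.
#' @export
apply_ulcer <- function(ts, center = NULL, radius_sites = 6L,
                        bolus_tnfa = 2, bolus_ros = 2) {
  stopifnot(inherits(ts, "tissue_state"))
  idx <- ts$idx
  if (is.null(center)) {
    mid_unit <- idx$geom$units$unit[ceiling(nrow(idx$geom$units) / 2)]
    center <- which(idx$unit == mid_unit & idx$comp == .VILLUS &
                      !idx$is_cap & idx$row == 0L & idx$col == 0L)[1]
  } else if (is.data.frame(center)) {
    center <- coord_to_site(idx, center)
  }
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > idx$N)
    stop("invalid ulcer centre", call. = FALSE)
  if (radius_sites < 0) stop("radius_sites must be >= 0", call. = FALSE)
  ball <- .graph_ball(idx, center, as.integer(radius_sites))
  removed <- 0L
  for (i in seq_along(ts$dec$workers)) {
    w <- ts$dec$workers[[i]]
    hit <- which(w$gid %in% ball & seq_len(w$n_local) <= w$n_owned)
    if (!length(hit)) next
    removed <- removed + sum(w$lin[hit] != .EMPTY)
    w$lin[hit] <- .EMPTY
    w$clock[hit] <- 0L
    w$health[hit] <- 0
    w$expo[hit] <- 0
    w$cell_id[hit] <- 0
    if (bolus_tnfa > 0) w$fields$TNFA[hit] <- w$fields$TNFA[hit] + bolus_tnfa
    if (bolus_ros > 0) w$fields$ROS[hit] <- w$fields$ROS[hit] + bolus_ros
    ts$dec$workers[[i]] <- w
  }
  if (bolus_tnfa > 0) ts$med_max[["TNFA"]] <- max(ts$med_max[["TNFA"]], bolus_tnfa)
  if (bolus_ros > 0) ts$med_max[["ROS"]] <- max(ts$med_max[["ROS"]], bolus_ros)
  ts <- exchange_ghosts(ts, c("fields", "agents"))
  ts$last_ulcer <- list(sites = ball, removed = removed)
  ts
}
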