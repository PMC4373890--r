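# Simulation engine: tissue state and the per-step update schedule.
#
# All state lives in per-worker arrays over owned + ghost sites. Every rule
# is two-phase (reads the previous sub-phase's state, writes the next), every
# stochastic decision draws from the counter-based site RNG, and ghost
# buffers are refreshed before any cross-boundary read, so the trajectory is
# a function of (geometry, parameters, seed) alone -- independent of the
# worker count.
#
# Step schedule (one step = 15 simulated minutes):
#   1. stool cycle advance + per-unit TLR drive
#   2. morphogen emission -> field exchange -> diffusion -> network update
#   3. cycle clocks; differentiation; inflammatory death; shedding
#   4. division (propose -> exchange -> owner-resolve -> exchange)
#   5. migration (same proposal machinery)
#   6. exposure accumulation, metaplastic conversion, periodic grid resize
#   7. bookkeeping (population counts, flux counters)
# Cross-boundary placement conflicts are resolved by the owner of the
# destination site with a deterministic site-RNG tie-break.

.id_mult <- function(idx) 2^ceiling(log2(max(idx$key) + 1))

# static per-worker annotations derived from parameters
.prepare_worker_static <- function(w, params, seed) {
  rl <- params$rules
  w$h_base <- .site_hash_base(w$key, seed)
  w$stem_zone <- w$comp == .CRYPT & (w$is_cap | w$row < rl$stem_rows)
  w$shed_zone <- w$comp == .VILLUS &
    (w$is_cap | w$row >= w$height - rl$shed_rows)
  w$luminal <- w$comp == .VILLUS
  own <- seq_len(w$n_owned)
  w$shed_sites <- own[w$shed_zone[own]]
  w$lum_sites <- own[w$luminal[own]]
  w$crypt_sites <- own[w$comp[own] == .CRYPT]
  w$villus_sites <- own[w$comp[own] == .VILLUS]
  # neighbour columns as plain vectors (hot path: avoids matrix slicing)
  w$nb1 <- w$nbrf_local[, 1]; w$nb2 <- w$nbrf_local[, 2]
  w$nb3 <- w$nbrf_local[, 3]; w$nb4 <- w$nbrf_local[, 4]
  w$src <- lapply(params$signaling$mediators, function(p) {
    if (p$source == "crypt_base")
      own[w$comp[own] == .CRYPT &
            (w$is_cap[own] | w$row[own] < p$source_rows)]
    else if (p$source == "villus_tip")
      own[w$comp[own] == .VILLUS &
            (w$is_cap[own] | w$row[own] >= w$height[own] - p$source_rows)]
    else integer(0)
  })
  w
}

# owned sites adjacent to at least one empty site (owned or ghost); every
# division or migration this step starts from one of these
.near_empty_candidates <- function(w) {
  own <- seq_len(w$n_owned)
  empt_o <- own[w$lin[own] == .EMPTY]
  cand <- integer(0)
  if (length(empt_o))
    cand <- c(w$nb1[empt_o], w$nb2[empt_o], w$nb3[empt_o], w$nb4[empt_o])
  if (length(w$grev_from)) {
    gsel <- w$lin[w$grev_from] == .EMPTY
    if (any(gsel)) cand <- c(cand, w$grev_to[gsel])
  }
  cand <- unique(cand)
  cand[cand <= w$n_owned]
}

.blank_worker_dynamic <- function(w) {
  n <- w$n_local
  w$lin <- integer(n)
  w$clock <- integer(n)
  w$health <- numeric(n)
  w$expo <- numeric(n)
  w$cell_id <- numeric(n)
  w$prop <- numeric(n)
  w$acc <- numeric(n)
  w$fields <- stats::setNames(
    lapply(.MEDIATORS, function(m) numeric(n)), .MEDIATORS)
  w
}

#' Initialize a tissue state
#'
#' Builds the site index, decomposes the lattice over `workers` congruent
#' sections, and populates the epithelium: stem cells in the crypt base rows
#' (and valley cap), progenitors in the rest of the crypt, enterocytes on the
#' villus. Cycle clocks are staggered deterministically by site key so the
#' initial population does not divide in lockstep. Mediator fields start at
#' zero and equilibrate during the run.
#'
#' @param geom a `pouch_geometry`.
#' @param params parameter list from [default_params()].
#' @param seed integer master seed (drives every stochastic rule).
#' @param workers number of logical workers (see [decompose()]).
#' @param occupancy `"full"` (homeostatic start) or `"empty"` (no agents;
#'   useful for toy experiments).
#' @return A `tissue_state` object.
#' @export
init_tissue <- function(geom, params = default_params(), seed = 1L,
                        workers = 1L, occupancy = c("full", "empty")) {
  occupancy <- match.arg(occupancy)
  idx <- site_index(geom)
  dec <- decompose(idx, workers)
  rl <- params$rules
  for (i in seq_along(dec$workers)) {
    w <- .prepare_worker_static(dec$workers[[i]], params, seed)
    w <- .blank_worker_dynamic(w)
    if (occupancy == "full") {
      w$lin <- ifelse(w$comp == .CRYPT,
                      ifelse(w$stem_zone, .STEM, .PROGENITOR),
                      .ENTEROCYTE)
      cyc <- ifelse(w$lin == .STEM, rl$cycle_len_stem,
                    rl$cycle_len_progenitor)
      w$clock <- as.integer(w$key %% cyc)
      w$health <- rep(1, w$n_local)
      w$cell_id <- w$key
    }
    dec$workers[[i]] <- w
  }
  hv <- idx$geom$units$villus_height
  ts <- structure(list(
    geom = idx$geom, idx = idx, dec = dec, params = params,
    seed = as.integer(seed), n_workers = as.integer(workers),
    step = 0L, id_mult = .id_mult(idx),
    hv0 = hv, villus_target = hv,
    meta_flag = rep(FALSE, nrow(idx$geom$units)),
    unit_expo = rep(0, nrow(idx$geom$units)),
    med_max = stats::setNames(rep(0, length(.MEDIATORS)), .MEDIATORS),
    stool = NULL, last_contact = NULL,
    log = character(0),
    last_stats = list(births = 0L, deaths = 0L, sheds = 0L)),
    class = "tissue_state")
  if (params$stool$enabled) ts <- enable_stool(ts)
  ts
}

#' @export
print.tissue_state <- function(x, ...) {
  n <- agent_counts(x)
  cat(sprintf("<tissue_state> step %d, %d workers, %d sites, %d agents (%d stem, %d progenitor, %d enterocyte, %d metaplastic)\n",
              x$step, x$n_workers, x$idx$N, n[["total"]], n[["stem"]],
              n[["progenitor"]], n[["enterocyte"]], n[["metaplastic"]]))
  invisible(x)
}

#' Switch the stool cycle on
#'
#' Creates a fresh stool state from the current stool parameters; the
#' fill/empty cycle starts at the step this is called.
#'
#' @param ts a `tissue_state`.
#' @return the updated state.
#' @export
enable_stool <- function(ts) {
  sp <- ts$params$stool
  ts$params$stool$enabled <- TRUE
  ts$stool <- stool_state(fill_steps = sp$fill_steps, delta_ip = sp$delta_ip,
                          ip0 = sp$ip0, per_parcel = sp$per_parcel,
                          fill_direction = sp$fill_direction)
  ts
}

#' Agent counts by lineage
#'
#' @param ts a `tissue_state`.
#' @return named numeric vector: total, crypt, villus, stem, progenitor,
#'   enterocyte, metaplastic.
#' @export
agent_counts <- function(ts) {
  cr <- vi <- 0
  byl <- numeric(4)
  for (w in ts$dec$workers) {
    byl <- byl + tabulate(w$lin[seq_len(w$n_owned)], 4L)
    cr <- cr + sum(w$lin[w$crypt_sites] != .EMPTY)
    vi <- vi + sum(w$lin[w$villus_sites] != .EMPTY)
  }
  c(total = cr + vi, crypt = cr, villus = vi,
    stem = byl[1], progenitor = byl[2],
    enterocyte = byl[3], metaplastic = byl[4])
}

# ---- mediator activity tracking ---------------------------------------------

# Mediators that must be updated this step: sources (emission/basal/input)
# plus everything reachable from them through positive edges, plus anything
# still carrying mass from earlier steps.
.active_mediators <- function(ts, tlr_input_present) {
  sig <- ts$params$signaling
  seeds <- names(sig$mediators)[vapply(sig$mediators, function(p)
    p$emission > 0 || p$basal > 0, logical(1))]
  if (tlr_input_present) seeds <- union(seeds, "TLR_ACT")
  seeds <- union(seeds, names(ts$med_max)[ts$med_max > 1e-14])
  e <- sig$edges[sig$edges$weight > 0 & sig$edges$sign > 0, , drop = FALSE]
  act <- seeds
  repeat {
    more <- unique(e$target[e$source %in% act])
    new <- setdiff(more, act)
    if (!length(new)) break
    act <- c(act, new)
  }
  act
}

# ---- field phase -------------------------------------------------------------

.phase_fields <- function(ts, t) {
  sig <- ts$params$signaling
  drive <- NULL
  if (ts$params$stool$enabled && !is.null(ts$stool)) {
    ts$stool <- step_stool(ts$stool)
    ts$last_contact <- .contact_drive(ts$stool, ts$geom,
                                      ts$params$stool$tlr_gain)
    drive <- ts$last_contact$drive
  }
  act <- .active_mediators(ts, !is.null(drive) && any(drive > 0))
  if (!length(act)) return(ts)
  ws <- ts$dec$workers

  # emission at morphogen source sites (owned only)
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    for (m in act) {
      e <- sig$mediators[[m]]$emission
      if (e > 0 && length(w$src[[m]]))
        w$fields[[m]][w$src[[m]]] <- w$fields[[m]][w$src[[m]]] + e
    }
    ws[[i]] <- w
  }
  ws <- .exchange_fields(ws, ts$dec$plan, act)

  edges <- sig$edges[sig$edges$weight > 0 &
                       sig$edges$source %in% act &
                       sig$edges$target %in% act, , drop = FALSE]
  # clamping is only needed where an inhibitory edge can push below zero
  clamp_needed <- stats::setNames(
    act %in% edges$target[edges$sign < 0], act)
  mx <- stats::setNames(numeric(length(act)), act)
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    own <- seq_len(w$n_owned)
    # diffusion + decay (two-phase: reads the exchanged pre-step fields)
    post <- list()
    for (m in act) {
      p <- sig$mediators[[m]]
      v <- w$fields[[m]]
      post[[m]] <- if (p$D > 0)
        (v[own] + p$D * (v[w$nb1] + v[w$nb2] + v[w$nb3] + v[w$nb4] -
                           4 * v[own])) * (1 - p$lam)
      else v[own]
    }
    # synchronous network update from the post-diffusion vectors; diffusing
    # mediators already took their decay above
    for (m in act) {
      p <- sig$mediators[[m]]
      lam_eff <- if (p$D > 0) 0 else p$lam
      er <- edges[edges$target == m, , drop = FALSE]
      has_input <- m == "TLR_ACT" && !is.null(drive)
      if (lam_eff == 0 && p$basal == 0 && nrow(er) == 0 && !has_input) {
        nv <- post[[m]]                      # diffusing, no reactions
      } else {
        accum <- post[[m]] + p$basal - lam_eff * post[[m]]
        if (has_input && length(w$lum_sites)) {
          lum <- w$lum_sites
          accum[lum] <- accum[lum] + drive[w$unit[lum] + 1L]
        }
        for (j in seq_len(nrow(er)))
          accum <- accum + er$sign[j] * er$weight[j] * post[[er$source[j]]]
        nv <- if (clamp_needed[[m]]) pmax(0, accum) else accum
      }
      w$fields[[m]][own] <- nv
      if (length(nv)) mx[[m]] <- max(mx[[m]], max(nv))
    }
    ws[[i]] <- w
  }
  ts$med_max[act] <- mx[act]
  ts$dec$workers <- ws
  ts
}

# ---- simple local agent phases ----------------------------------------------

.phase_clocks <- function(ts) {
  for (i in seq_along(ts$dec$workers)) {
    w <- ts$dec$workers[[i]]
    own <- seq_len(w$n_owned)
    sel <- own[w$lin[own] == .STEM | w$lin[own] == .PROGENITOR]
    w$clock[sel] <- w$clock[sel] + 1L
    ts$dec$workers[[i]] <- w
  }
  ts
}

.phase_differentiation <- function(ts) {
  th <- ts$params$rules$theta_bmp
  for (i in seq_along(ts$dec$workers)) {
    w <- ts$dec$workers[[i]]
    own <- seq_len(w$n_owned)
    pr <- own[w$lin[own] == .PROGENITOR]
    if (length(pr)) {
      become <- w$comp[pr] == .VILLUS | w$fields$BMP[pr] >= th
      w$lin[pr[become]] <- .ENTEROCYTE
      ts$dec$workers[[i]] <- w
    }
  }
  ts
}

.phase_death <- function(ts, t) {
  rl <- ts$params$rules
  if ((ts$med_max[["ROS"]] <= 0 || rl$death_a_ros <= 0) &&
      (ts$med_max[["TNFA"]] <= 0 || rl$death_a_tnfa <= 0)) {
    ts$last_stats$deaths <- 0L
    return(ts)
  }
  deaths <- 0L
  for (i in seq_along(ts$dec$workers)) {
    w <- ts$dec$workers[[i]]
    own <- seq_len(w$n_owned)
    occ <- own[w$lin[own] != .EMPTY]
    if (!length(occ)) next
    p <- 1 - exp(-(rl$death_a_ros * w$fields$ROS[occ] +
                     rl$death_a_tnfa * w$fields$TNFA[occ]))
    sub <- occ[p > 0]
    if (!length(sub)) next
    u <- .rng_from_base(w$h_base[sub], t, .STREAM$death)
    die <- sub[u < p[p > 0]]
    if (length(die)) {
      w$health[die] <- 0
      w$lin[die] <- .EMPTY
      w$clock[die] <- 0L
      w$expo[die] <- 0
      w$cell_id[die] <- 0
      deaths <- deaths + length(die)
      ts$dec$workers[[i]] <- w
    }
  }
  ts$last_stats$deaths <- deaths
  ts
}

.phase_shedding <- function(ts, t) {
  rl <- ts$params$rules
  sheds <- 0L
  any_meta <- any(ts$meta_flag)
  for (i in seq_along(ts$dec$workers)) {
    w <- ts$dec$workers[[i]]
    zone_sites <- w$shed_sites
    if (any_meta) {
      # metaplastic units shed everything above their reduced target height,
      # which is how the villus grid empties before it is shrunk
      vs <- w$villus_sites
      ext <- vs[!w$is_cap[vs] & ts$meta_flag[w$unit[vs] + 1L] &
                  w$row[vs] >= ts$villus_target[w$unit[vs] + 1L]]
      zone_sites <- unique(c(zone_sites, ext))
    }
    cand <- zone_sites[w$lin[zone_sites] == .ENTEROCYTE |
                         w$lin[zone_sites] == .METAPLASTIC]
    if (!length(cand)) next
    u <- .rng_from_base(w$h_base[cand], t, .STREAM$shed)
    out <- cand[u < rl$p_shed]
    if (length(out)) {
      w$lin[out] <- .EMPTY
      w$clock[out] <- 0L
      w$health[out] <- 0
      w$expo[out] <- 0
      w$cell_id[out] <- 0
      sheds <- sheds + length(out)
      ts$dec$workers[[i]] <- w
    }
  }
  ts$last_stats$sheds <- sheds
  ts
}

# ---- proposal / owner-resolution machinery -----------------------------------

# Winners among proposals targeting owned empty sites. A proposal is a
# destination site key stored at the proposing agent's site; candidates for
# an empty site are its <= 4 neighbours (owned or ghost) proposing exactly
# this site; the winner is picked by the destination owner with a
# deterministic site-RNG tie-break on the candidate sites.
.collect_winners <- function(w, t) {
  own <- seq_len(w$n_owned)
  empt <- own[w$lin[own] == .EMPTY]
  if (!length(empt)) return(NULL)
  keyd <- w$key[empt]
  dests <- integer(0); srcs <- integer(0)
  for (k in 1:4) {
    cand <- w$nbrf_local[empt, k]
    pc <- w$prop[cand]
    hit <- which(pc > 0 & pc == keyd)
    if (length(hit)) {
      dests <- c(dests, empt[hit])
      srcs <- c(srcs, cand[hit])
    }
  }
  if (!length(dests)) return(NULL)
  tb <- .rng_from_base(w$h_base[srcs], t, .STREAM$resolve)
  o <- order(dests, tb, w$key[srcs])
  keep <- !duplicated(dests[o])
  list(dest = dests[o][keep], src = srcs[o][keep])
}

# choose the j-th TRUE slot of a 4-column candidate mask, j drawn per row
.pick_slot <- function(mask, u) {
  ncand <- rowSums(mask)
  j <- 1L + floor(u * ncand)
  c1 <- mask[, 1]
  c2 <- c1 + mask[, 2]
  c3 <- c2 + mask[, 3]
  ifelse(j <= c1, 1L, ifelse(j <= c2, 2L, ifelse(j <= c3, 3L, 4L)))
}

.phase_division <- function(ts, t) {
  ws <- ts$dec$workers; plan <- ts$dec$plan
  rl <- ts$params$rules
  w_st <- ts$params$signaling$w_stat3_prolif
  births <- 0L
  info <- vector("list", length(ws))
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    w$prop[] <- 0; w$acc[] <- 0
    # only sites next to a vacancy can place a daughter
    par <- .near_empty_candidates(w)
    l <- w$lin[par]
    par <- par[(l == .STEM & w$clock[par] >= rl$cycle_len_stem) |
                 (l == .PROGENITOR & w$clock[par] >= rl$cycle_len_progenitor)]
    if (length(par)) {
      drive <- w$fields$WNT[par] + w_st * w$fields$STAT3[par]
      par <- par[drive >= rl$theta_wnt]
    }
    if (length(par)) {
      nb <- w$nbrf_local[par, , drop = FALSE]
      emp <- matrix(w$lin[nb] == .EMPTY, nrow = length(par))
      keepP <- rowSums(emp) > 0           # contact inhibition otherwise
      par <- par[keepP]
      if (length(par)) {
        nb <- nb[keepP, , drop = FALSE]; emp <- emp[keepP, , drop = FALSE]
        u <- .rng_from_base(w$h_base[par], t, .STREAM$division_place)
        dest <- nb[cbind(seq_along(par), .pick_slot(emp, u))]
        w$prop[par] <- w$key[dest]
        info[[i]] <- list(par = par, dest = dest)
      }
    }
    ws[[i]] <- w
  }
  ws <- .exchange_array(ws, plan, "prop")
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    win <- .collect_winners(w, t)
    if (!is.null(win)) {
      d <- win$dest; s <- win$src
      stem_d <- w$lin[s] == .STEM & w$stem_zone[d]
      w$lin[d] <- ifelse(stem_d, .STEM, .PROGENITOR)
      w$clock[d] <- 0L
      w$health[d] <- 1
      w$expo[d] <- 0
      w$cell_id[d] <- t * ts$id_mult + w$key[d]
      w$acc[d] <- w$key[s]
      births <- births + length(d)
      ws[[i]] <- w
    }
  }
  ws <- .exchange_array(ws, plan, "acc")
  for (i in seq_along(ws)) {
    if (is.null(info[[i]])) next
    w <- ws[[i]]
    ok <- w$acc[info[[i]]$dest] == w$key[info[[i]]$par]
    w$clock[info[[i]]$par[ok]] <- 0L
    ws[[i]] <- w
  }
  for (nm in .AGENT_ARRAYS) ws <- .exchange_array(ws, plan, nm)
  ts$dec$workers <- ws
  ts$last_stats$births <- births
  ts
}

.phase_migration <- function(ts, t) {
  ws <- ts$dec$workers; plan <- ts$dec$plan
  info <- vector("list", length(ws))
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    w$prop[] <- 0; w$acc[] <- 0
    # only agents next to a vacancy can move
    mov <- .near_empty_candidates(w)
    l <- w$lin[mov]
    mov <- mov[l != .EMPTY & l != .STEM]
    if (length(mov)) {
      nb <- w$nbrf_local[mov, , drop = FALSE]
      cand <- matrix(w$lin[nb] == .EMPTY & w$rank[nb] > w$rank[mov],
                     nrow = length(mov))
      keepM <- rowSums(cand) > 0
      mov <- mov[keepM]
      if (length(mov)) {
        nb <- nb[keepM, , drop = FALSE]; cand <- cand[keepM, , drop = FALSE]
        u <- .rng_from_base(w$h_base[mov], t, .STREAM$migration_choice)
        dest <- nb[cbind(seq_along(mov), .pick_slot(cand, u))]
        w$prop[mov] <- w$key[dest]
        info[[i]] <- list(mov = mov, dest = dest)
      }
    }
    ws[[i]] <- w
  }
  ws <- .exchange_array(ws, plan, "prop")
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    win <- .collect_winners(w, t)
    if (!is.null(win)) {
      d <- win$dest; s <- win$src
      w$lin[d] <- w$lin[s]
      w$clock[d] <- w$clock[s]
      w$health[d] <- w$health[s]
      w$expo[d] <- w$expo[s]
      w$cell_id[d] <- w$cell_id[s]
      w$acc[d] <- w$key[s]
      ws[[i]] <- w
    }
  }
  ws <- .exchange_array(ws, plan, "acc")
  for (i in seq_along(ws)) {
    if (is.null(info[[i]])) next
    w <- ws[[i]]
    ok <- w$acc[info[[i]]$dest] == w$key[info[[i]]$mov]
    gone <- info[[i]]$mov[ok]
    if (length(gone)) {
      w$lin[gone] <- .EMPTY
      w$clock[gone] <- 0L
      w$health[gone] <- 0
      w$expo[gone] <- 0
      w$cell_id[gone] <- 0
      ws[[i]] <- w
    }
  }
  for (nm in .AGENT_ARRAYS) ws <- .exchange_array(ws, plan, nm)
  ts$dec$workers <- ws
  ts
}

# ---- exposure, metaplasia, resize --------------------------------------------

.phase_metaplasia <- function(ts, t) {
  rl <- ts$params$rules
  if (ts$params$stool$enabled && !is.null(ts$last_contact)) {
    ip <- ts$last_contact$ip
    n_units <- length(ts$unit_expo)
    sums <- numeric(n_units); cnts <- numeric(n_units)
    for (i in seq_along(ts$dec$workers)) {
      w <- ts$dec$workers[[i]]
      own <- seq_len(w$n_owned)
      occ <- own[w$lin[own] != .EMPTY]
      if (!length(occ)) next
      add <- rl$k_exposure * w$fields$TLR_ACT[occ] * ip[w$unit[occ] + 1L]
      w$expo[occ] <- w$expo[occ] + add
      ts$dec$workers[[i]] <- w
      agg <- rowsum(w$expo[occ], w$unit[occ])
      uu <- as.integer(rownames(agg)) + 1L
      sums[uu] <- sums[uu] + agg[, 1]
      cnt <- rowsum(rep(1, length(occ)), w$unit[occ])
      cnts[uu] <- cnts[uu] + cnt[, 1]
    }
    has <- cnts > 0
    ts$unit_expo[has] <- sums[has] / cnts[has]
    thr <- rl$metaplasia_exposure_threshold
    if (rl$metaplasia_reversible) {
      ts$meta_flag <- ts$unit_expo >= thr
    } else {
      ts$meta_flag <- ts$meta_flag | ts$unit_expo >= thr
    }
    if (any(ts$meta_flag)) {
      tgt <- villus_target_height(ts$unit_expo, ts$hv0, rl)
      ts$villus_target <- ifelse(ts$meta_flag,
                                 pmin(ts$villus_target, tgt),
                                 ts$villus_target)
    }
  }
  # phenotype conversion follows unit status every step
  if (any(ts$meta_flag) || rl$metaplasia_reversible) {
    for (i in seq_along(ts$dec$workers)) {
      w <- ts$dec$workers[[i]]
      own <- seq_len(w$n_owned)
      fl <- ts$meta_flag[w$unit[own] + 1L]
      conv <- own[fl & w$lin[own] == .ENTEROCYTE]
      w$lin[conv] <- .METAPLASTIC
      if (rl$metaplasia_reversible) {
        back <- own[!fl & w$lin[own] == .METAPLASTIC]
        w$lin[back] <- .ENTEROCYTE
      }
      ts$dec$workers[[i]] <- w
    }
    ts <- exchange_ghosts(ts, "agents")
  }
  if (rl$resize_every > 0 && t %% rl$resize_every == 0L) {
    hv <- ts$geom$units$villus_height
    want <- pmin(hv, pmax(1L, ts$villus_target))
    if (any(want < hv)) ts <- .set_unit_heights(ts, want)
  }
  ts
}

# Rebuild index, decomposition and per-worker arrays after a height change,
# carrying every payload site-for-site on surviving sites. Only empty top
# rows may be deleted: shrink requests are clamped to one row above the
# highest occupied row (and logged).
.set_unit_heights <- function(ts, new_hv) {
  old_idx <- ts$idx
  G <- .gather_arrays(ts)
  # clamp shrinks to preserve occupied rows
  occ <- which(G$lin != .EMPTY & old_idx$comp == .VILLUS & !old_idx$is_cap)
  if (length(occ)) {
    mx <- tapply(old_idx$row[occ], old_idx$unit[occ], max)
    uu <- as.integer(names(mx)) + 1L
    floor_h <- rep(1L, length(new_hv))
    floor_h[uu] <- as.integer(mx) + 1L
    clamped <- new_hv < floor_h
    if (any(clamped)) {
      ts$log <- c(ts$log, sprintf(
        "step %d: shrink clamped on %d unit(s) to keep occupied rows",
        ts$step, sum(clamped)))
      new_hv <- pmax(new_hv, floor_h)
    }
  }
  new_hv <- pmax(1L, as.integer(new_hv))
  if (all(new_hv == ts$geom$units$villus_height)) return(ts)
  geom2 <- ts$geom
  geom2$units$villus_height <- new_hv
  idx2 <- site_index(geom2)
  dec2 <- decompose(idx2, ts$n_workers)
  map <- .match_sites(idx2, old_idx)
  for (i in seq_along(dec2$workers)) {
    w <- .prepare_worker_static(dec2$workers[[i]], ts$params, ts$seed)
    w <- .blank_worker_dynamic(w)
    oldg <- map[w$gid]
    has <- !is.na(oldg)
    w$lin[has] <- G$lin[oldg[has]]
    w$clock[has] <- G$clock[oldg[has]]
    w$health[has] <- G$health[oldg[has]]
    w$expo[has] <- G$expo[oldg[has]]
    w$cell_id[has] <- G$cell_id[oldg[has]]
    for (m in .MEDIATORS) w$fields[[m]][has] <- G$fields[[m]][oldg[has]]
    dec2$workers[[i]] <- w
  }
  ts$geom <- geom2
  ts$idx <- idx2
  ts$dec <- dec2
  ts
}

#' Resize one crypt-villus component between timesteps
#'
#' Grows a component by appending empty rows at the villus tip (or crypt
#' mouth), or shrinks it by deleting empty top rows. Occupied rows are never
#' deleted: a shrink request that would hit one is clamped to one row above
#' the highest occupied row and logged on the state. All payloads (agents
#' and mediator concentrations) are preserved site-for-site on surviving
#' rows; cap sites are re-attached at the new height.
#'
#' @param ts a `tissue_state`.
#' @param unit_index 0-based unit index.
#' @param component `"VILLUS"` or `"CRYPT"` (only villus resizing is used by
#'   the metaplasia rule; crypt resizing works the same way).
#' @param new_height requested height in rows (>= 1).
#' @return the updated `tissue_state`.
#' @export
resize_unit <- function(ts, unit_index, component = "VILLUS", new_height) {
  stopifnot(inherits(ts, "tissue_state"))
  unit_index <- as.integer(unit_index)
  if (unit_index < 0L || unit_index >= nrow(ts$geom$units))
    stop("invalid unit_index", call. = FALSE)
  new_height <- as.integer(new_height)
  if (is.na(new_height) || new_height < 1L)
    stop("new_height must be an integer >= 1", call. = FALSE)
  component <- toupper(component)
  if (component == "VILLUS") {
    hv <- ts$geom$units$villus_height
    hv[unit_index + 1L] <- new_height
    .set_unit_heights(ts, hv)
  } else if (component == "CRYPT") {
    old_idx <- ts$idx
    G <- .gather_arrays(ts)
    occ <- which(G$lin != .EMPTY & old_idx$comp == .CRYPT & !old_idx$is_cap &
                   old_idx$unit == unit_index)
    floor_h <- if (length(occ)) max(old_idx$row[occ]) + 1L else 1L
    if (new_height < floor_h) {
      ts$log <- c(ts$log, sprintf(
        "step %d: crypt shrink on unit %d clamped to %d to keep occupied rows",
        ts$step, unit_index, floor_h))
      new_height <- floor_h
    }
    geom2 <- ts$geom
    geom2$units$crypt_depth[unit_index + 1L] <- new_height
    idx2 <- site_index(geom2)
    dec2 <- decompose(idx2, ts$n_workers)
    map <- .match_sites(idx2, old_idx)
    for (i in seq_along(dec2$workers)) {
      w <- .prepare_worker_static(dec2$workers[[i]], ts$params, ts$seed)
      w <- .blank_worker_dynamic(w)
      oldg <- map[w$gid]
      has <- !is.na(oldg)
      w$lin[has] <- G$lin[oldg[has]]
      w$clock[has] <- G$clock[oldg[has]]
      w$health[has] <- G$health[oldg[has]]
      w$expo[has] <- G$expo[oldg[has]]
      w$cell_id[has] <- G$cell_id[oldg[has]]
      for (m in .MEDIATORS) w$fields[[m]][has] <- G$fields[[m]][oldg[has]]
      dec2$workers[[i]] <- w
    }
    ts$geom <- geom2
    ts$idx <- idx2
    ts$dec <- dec2
    ts
  } else stop("component must be VILLUS or CRYPT", call. = FALSE)
}

# ---- gathering ----------------------------------------------------------------

.gather_arrays <- function(ts) {
  N <- ts$idx$N
  G <- list(lin = integer(N), clock = integer(N), health = numeric(N),
            expo = numeric(N), cell_id = numeric(N),
            fields = stats::setNames(lapply(.MEDIATORS,
                                            function(m) numeric(N)),
                                     .MEDIATORS))
  for (w in ts$dec$workers) {
    own <- seq_len(w$n_owned)
    G$lin[w$owned] <- w$lin[own]
    G$clock[w$owned] <- w$clock[own]
    G$health[w$owned] <- w$health[own]
    G$expo[w$owned] <- w$expo[own]
    G$cell_id[w$owned] <- w$cell_id[own]
    for (m in .MEDIATORS) G$fields[[m]][w$owned] <- w$fields[[m]][own]
  }
  G
}

.gather_field <- function(ts, mediator) {
  stopifnot(mediator %in% .MEDIATORS)
  v <- numeric(ts$idx$N)
  for (w in ts$dec$workers)
    v[w$owned] <- w$fields[[mediator]][seq_len(w$n_owned)]
  v
}

#' Full per-site state as a tibble
#'
#' Collects owned state from every worker into one table: coordinates,
#' agent payloads and (optionally) every mediator concentration. The result
#' is independent of the worker count -- the basis of the serial/partitioned
#' equivalence checks.
#'
#' @param ts a `tissue_state`.
#' @param fields logical or character: FALSE for none, TRUE for all
#'   mediators, or a character vector of mediator names.
#' @param occupied_only keep only sites holding an agent.
#' @return a tibble, one row per site, ordered by site id.
#' @export
gather_state <- function(ts, fields = TRUE, occupied_only = FALSE) {
  stopifnot(inherits(ts, "tissue_state"))
  G <- .gather_arrays(ts)
  idx <- ts$idx
  fsel <- if (isTRUE(fields)) .MEDIATORS
  else if (is.character(fields)) fields
  else character(0)
  out <- tibble::tibble(
    site = seq_len(idx$N),
    unit_index = idx$unit,
    component = ifelse(idx$comp == .VILLUS, "VILLUS", "CRYPT"),
    face = idx$col %/% idx$face_width,
    row = idx$row,
    col = idx$col %% idx$face_width,
    is_cap = idx$is_cap,
    axial = idx$axial,
    lineage = c("EMPTY", .LINEAGES)[G$lin + 1L],
    cell_id = G$cell_id,
    cycle_clock = G$clock,
    health = G$health,
    inflammation_exposure = G$expo)
  for (m in fsel) out[[m]] <- G$fields[[m]]
  if (occupied_only) out <- out[out$lineage != "EMPTY", ]
  out
}

# ---- the step -----------------------------------------------------------------

#' Advance the tissue by whole timesteps
#'
#' Runs the full per-step schedule (stool, fields, cell rules, division,
#' migration, metaplasia, bookkeeping) `n` times. With `debug = TRUE` in the
#' parameters, ghost consistency and the halo access guard are verified
#' every step.
#'
#' @param ts a `tissue_state`.
#' @param n number of steps.
#' @param record if TRUE, returns the per-step population series as
#'   attribute-free tibble in the result's `series` element.
#' @return list with elements `ts` (advanced state) and `series` (tibble,
#'   or NULL when `record = FALSE`).
#' @export
run_steps <- function(ts, n, record = TRUE) {
  stopifnot(inherits(ts, "tissue_state"), n >= 0)
  rows <- if (record) vector("list", n) else NULL
  for (k in seq_len(n)) {
    ts <- tissue_step(ts)
    if (record) {
      cnt <- agent_counts(ts)
      rows[[k]] <- c(step = ts$step, cnt,
                     births = ts$last_stats$births,
                     deaths = ts$last_stats$deaths,
                     sheds = ts$last_stats$sheds)
    }
  }
  series <- NULL
  if (record && n > 0) {
    m <- do.call(rbind, rows)
    series <- tibble::as_tibble(as.data.frame(m))
    series$sim_hours <- series$step * 0.25
    series <- series[, c("step", "sim_hours", "total", "crypt", "villus",
                         "stem", "progenitor", "enterocyte", "metaplastic",
                         "births", "deaths", "sheds")]
    names(series) <- c("step", "sim_hours", "n_total", "n_crypt", "n_villus",
                       "n_stem", "n_progenitor", "n_enterocyte",
                       "n_metaplastic", "births", "deaths", "sheds")
  }
  list(ts = ts, series = series)
}

#' One full simulation timestep
#'
#' @param ts a `tissue_state`.
#' @return the advanced state (with `last_stats` holding this step's birth,
#'   death and shed counts).
#' @export
tissue_step <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  t <- ts$step + 1L
  ts$step <- t
  ts$last_stats <- list(births = 0L, deaths = 0L, sheds = 0L)
  ts <- .phase_fields(ts, t)
  ts <- .phase_clocks(ts)
  ts <- .phase_differentiation(ts)
  ts <- .phase_death(ts, t)
  ts <- .phase_shedding(ts, t)
  ts <- exchange_ghosts(ts, "agents")
  ts <- .phase_division(ts, t)
  ts <- .phase_migration(ts, t)
  ts <- .phase_metaplasia(ts, t)
  if (ts$params$debug) {
    check_partition_invariants(ts)
    ts <- exchange_ghosts(ts, c("fields", "agents"))
    d <- ghost_discrepancy(ts)
    if (d != 0) stop("ghost buffers out of sync: max discrepancy ", d)
  }
  ts
}
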