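# Congruent-section domain decomposition with one-cell ghost buffers.
#
# The unit lattice is tiled by near-equal rectangular blocks of crypt-villus
# units, one per logical worker. Every grid that crosses a block boundary is
# extended by exactly one cell: a worker's ghost set is precisely the set of
# sites owned by other workers that are graph neighbours of its owned sites.
# Ghost values are refreshed by copying from their owners ("exchange") every
# time a rule is about to read across a boundary; together with two-phase
# updates and the counter-based site RNG this makes a run on P workers
# bit-identical to a serial run. Workers are realized as sequential
# sub-domain sweeps inside one process; the exchange plan, not the transport
# mechanism, carries the contract.

.factor_pairs <- function(p) {
  d <- seq_len(p)[p %% seq_len(p) == 0]
  cbind(pa = d, pc = p %/% d)
}

#' Decompose a pouch into congruent sections
#'
#' Splits the unit lattice into `n_workers` near-equal rectangular blocks
#' (axial chunks x circumferential chunks). The circumferential direction
#' wraps: the first and last circumferential blocks are neighbours. Each
#' worker is given the site ids it owns plus its one-cell ghost layer, the
#' local neighbour table restricted to owned + ghost sites, and a static
#' exchange plan with exactly one source per ghost slot.
#'
#' @param x a `pouch_geometry` or `site_index`.
#' @param n_workers positive integer; must factor as `pa * pc` with
#'   `pa <= n_axial` and `pc <= n_circ`.
#' @return A `decomposition` object: list of workers plus the exchange plan.
#' @export
decompose <- function(x, n_workers) {
  idx <- .as_index(x)
  geom <- idx$geom
  n_workers <- as.integer(n_workers)
  stopifnot(length(n_workers) == 1L, n_workers >= 1L)
  na <- geom$n_axial; nc <- geom$n_circ
  fp <- .factor_pairs(n_workers)
  fp <- fp[fp[, "pa"] <= na & fp[, "pc"] <= nc, , drop = FALSE]
  if (nrow(fp) == 0L) {
    valid <- sort(unique(as.vector(outer(seq_len(na), seq_len(nc)))))
    stop(sprintf(
      "n_workers = %d admits no pa x pc grid within the %d x %d unit lattice; valid worker counts: %s",
      n_workers, na, nc, paste(valid, collapse = ", ")), call. = FALSE)
  }
  cost <- ceiling(na / fp[, "pa"]) + ceiling(nc / fp[, "pc"])
  ord <- order(cost, abs(fp[, "pa"] - fp[, "pc"]), fp[, "pa"])
  pa <- fp[ord[1], "pa"]; pc <- fp[ord[1], "pc"]

  chunk <- function(n, p) {
    base <- n %/% p; extra <- n %% p
    sizes <- base + (seq_len(p) <= extra)
    to <- cumsum(sizes)
    cbind(from = to - sizes, to = to - 1L)   # 0-based inclusive ranges
  }
  axr <- chunk(na, pa); cir <- chunk(nc, pc)

  # unit -> worker map (workers numbered row-major over the block grid)
  uax <- idx$geom$units$axial; uci <- idx$geom$units$circ
  ablk <- findInterval(uax, axr[, "from"])
  cblk <- findInterval(uci, cir[, "from"])
  wmap <- (ablk - 1L) * pc + cblk            # 1-based worker per unit
  site_owner <- wmap[idx$unit + 1L]

  workers <- vector("list", n_workers)
  maps <- vector("list", n_workers)          # global -> local, kept for plan
  for (w in seq_len(n_workers)) {
    owned <- which(site_owner == w)
    nb <- idx$nbr[owned, , drop = FALSE]
    nbv <- nb[!is.na(nb)]
    ghosts <- sort(unique(nbv[site_owner[nbv] != w]))
    lall <- c(owned, ghosts)
    map <- integer(idx$N)
    map[lall] <- seq_along(lall)
    loc <- matrix(NA_integer_, nrow(nb), 4L)
    nz <- !is.na(nb)
    loc[nz] <- map[nb[nz]]
    if (any(loc[nz] == 0L))
      stop("internal error: neighbour outside owned + ghost halo")
    locf <- loc
    self <- matrix(rep(seq_along(owned), 4L), ncol = 4L)
    locf[!nz] <- self[!nz]                   # zero-flux: missing -> self
    # reverse adjacency ghost -> owned (lets rules find owned sites next to
    # ghost vacancies without ever reading past the halo)
    gf <- integer(0); gt <- integer(0)
    if (length(ghosts)) {
      isg <- !is.na(loc) & loc > length(owned)
      gf <- loc[isg]
      gt <- self[isg]
    }
    workers[[w]] <- list(
      id = w,
      ax_range = axr[(w - 1L) %/% pc + 1L, ],
      ci_range = cir[(w - 1L) %% pc + 1L, ],
      units = sort(unique(idx$unit[owned])),
      owned = owned, ghosts = ghosts, gid = lall,
      n_owned = length(owned), n_local = length(lall),
      nbr_local = loc, nbrf_local = locf,
      grev_from = gf, grev_to = gt,
      # static per-local-site attributes
      key = idx$key[lall], rank = idx$rank[lall], comp = idx$comp[lall],
      row = idx$row[lall], col = idx$col[lall], is_cap = idx$is_cap[lall],
      unit = idx$unit[lall], axial = idx$axial[lall],
      height = idx$height[lall])
    maps[[w]] <- map
  }

  plan <- list()
  for (d in seq_len(n_workers)) {
    g <- workers[[d]]$ghosts
    if (!length(g)) next
    own <- site_owner[g]
    for (s in sort(unique(own))) {
      sel <- g[own == s]
      plan[[length(plan) + 1L]] <- list(
        src = s, dst = d,
        src_idx = maps[[s]][sel],
        dst_idx = maps[[d]][sel])
    }
  }

  structure(list(idx = idx, n_workers = n_workers, pa = pa, pc = pc,
                 wmap = wmap, site_owner = site_owner,
                 workers = workers, plan = plan),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d workers (%d axial x %d circ blocks), %d transfers\n",
              x$n_workers, x$pa, x$pc, length(x$plan)))
  invisible(x)
}

# Copy one named per-site array from owners into ghost slots.
.exchange_array <- function(workers, plan, name) {
  for (tr in plan)
    workers[[tr$dst]][[name]][tr$dst_idx] <- workers[[tr$src]][[name]][tr$src_idx]
  workers
}

.exchange_fields <- function(workers, plan, mediators) {
  for (tr in plan) {
    fs <- workers[[tr$src]]$fields
    fd <- workers[[tr$dst]]$fields
    for (m in mediators)
      fd[[m]][tr$dst_idx] <- fs[[m]][tr$src_idx]
    workers[[tr$dst]]$fields <- fd
  }
  workers
}

.AGENT_ARRAYS <- c("lin", "clock", "health", "expo", "cell_id")

#' Refresh ghost buffers from their owners
#'
#' Copies mediator concentrations and/or agent state (occupancy, lineage,
#' cycle clock, health, accumulated exposure, cell id) from each owning
#' worker into the corresponding ghost slots of its neighbours. After the
#' call every ghost site's payload equals the owner's bit for bit.
#'
#' @param ts a `tissue_state` (see [init_tissue()]).
#' @param what any of `"fields"`, `"agents"`.
#' @return the updated `tissue_state`.
#' @export
exchange_ghosts <- function(ts, what = c("fields", "agents")) {
  stopifnot(inherits(ts, "tissue_state"))
  w <- ts$dec$workers; plan <- ts$dec$plan
  if ("fields" %in% what)
    w <- .exchange_fields(w, plan, names(w[[1]]$fields))
  if ("agents" %in% what)
    for (nm in .AGENT_ARRAYS) w <- .exchange_array(w, plan, nm)
  ts$dec$workers <- w
  ts
}

#' Verify decomposition invariants (debug access guard)
#'
#' Checks, for a decomposition, that (i) owned blocks tile the unit lattice
#' exactly (disjoint and exhaustive); (ii) the ghost layer has width exactly
#' one cell: each worker's ghost set equals the set of foreign graph
#' neighbours of its owned sites, no more and no fewer; (iii) every neighbour
#' slot of an owned site resolves inside the owned + ghost halo, so no rule
#' evaluated on owned sites can read beyond one cell; and (iv) every ghost
#' slot has exactly one source in the exchange plan. Used as the runtime
#' access guard in debug mode.
#'
#' @param dec a `decomposition` (or a `tissue_state`, whose decomposition is
#'   checked).
#' @return TRUE invisibly; stops with a message on any violation.
#' @export
check_partition_invariants <- function(dec) {
  if (inherits(dec, "tissue_state")) dec <- dec$dec
  stopifnot(inherits(dec, "decomposition"))
  idx <- dec$idx
  all_owned <- sort(unlist(lapply(dec$workers, `[[`, "owned")))
  if (!identical(all_owned, seq_len(idx$N)))
    stop("owned blocks do not tile the lattice exactly")
  for (w in dec$workers) {
    nb <- idx$nbr[w$owned, , drop = FALSE]
    nbv <- unique(nb[!is.na(nb)])
    expected <- sort(setdiff(nbv, w$owned))
    if (!identical(sort(w$ghosts), expected))
      stop(sprintf("worker %d: ghost layer is not exactly one cell wide", w$id))
    loc <- w$nbr_local
    bad <- !is.na(loc) & (loc < 1L | loc > w$n_local)
    if (any(bad))
      stop(sprintf("worker %d: a rule could read beyond the one-cell halo", w$id))
  }
  dst_slots <- unlist(lapply(dec$plan, function(tr)
    (tr$dst - 1) * (idx$N + 1) + tr$dst_idx))
  if (anyDuplicated(dst_slots))
    stop("exchange plan assigns multiple sources to one ghost slot")
  n_ghost <- sum(vapply(dec$workers, function(w) length(w$ghosts), integer(1)))
  if (length(dst_slots) != n_ghost)
    stop("exchange plan does not cover every ghost slot")
  invisible(TRUE)
}

#' Maximum owner-ghost discrepancy
#'
#' For every ghost slot, compares the ghost copy against the owner's value
#' for all mediator fields and agent arrays; returns the largest absolute
#' difference (0 when ghosts are exact copies).
#'
#' @param ts a `tissue_state`.
#' @return numeric scalar.
#' @export
ghost_discrepancy <- function(ts) {
  stopifnot(inherits(ts, "tissue_state"))
  w <- ts$dec$workers
  worst <- 0
  for (tr in ts$dec$plan) {
    for (m in names(w[[1]]$fields))
      worst <- max(worst, abs(w[[tr$dst]]$fields[[m]][tr$dst_idx] -
                              w[[tr$src]]$fields[[m]][tr$src_idx]))
    for (nm in .AGENT_ARRAYS)
      worst <- max(worst, abs(w[[tr$dst]][[nm]][tr$dst_idx] -
                              w[[tr$src]][[nm]][tr$src_idx]))
  }
  worst
}
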