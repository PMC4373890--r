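# Stool-flow surrogate: the fecal microbiome as a slow-flowing liquid.
#
# The pouch fills over `fill_steps` timesteps (default 16: a 4-hour cycle at
# 15 minutes per step) and then empties; one stool parcel enters per step.
# Each parcel's inflammatory potential grows linearly with residence time,
# IP_t = IP_{t-1} + delta_IP, so stasis (long residence) makes stool more
# inflammatory. Filling proceeds from the terminal (distal) end toward the
# inflow by default, so terminal units accumulate the longest contact with
# the oldest, highest-IP stool -- the generative mechanism for the
# distal-dominant metaplasia gradient. No fluid dynamics: flow is modeled
# indirectly, and only epithelial contact matters.

#' Create a stool state
#'
#' @param fill_steps integer steps per fill/empty cycle (default 16 = 4 h at
#'   15 min/step).
#' @param delta_ip inflammatory-potential increment per parcel per step
#'   (>= 0).
#' @param ip0 inflammatory potential of fresh stool.
#' @param per_parcel logical; if TRUE (default) each parcel accumulates its
#'   own IP, if FALSE a single pouch-wide IP scalar accumulates instead.
#' @param fill_direction `"terminal_first"` (default; gravity/stasis
#'   surrogate) or `"proximal_first"` (mechanism check: reverses the
#'   exposure gradient).
#' @return A `stool_state` object.
#' @export
stool_state <- function(fill_steps = 16L, delta_ip = 0.05, ip0 = 0,
                        per_parcel = TRUE,
                        fill_direction = c("terminal_first", "proximal_first")) {
  fill_steps <- as.integer(fill_steps)
  if (is.na(fill_steps) || fill_steps < 1L)
    stop("fill_steps must be a positive integer", call. = FALSE)
  if (delta_ip < 0) stop("delta_ip must be >= 0", call. = FALSE)
  if (ip0 < 0) stop("ip0 must be >= 0", call. = FALSE)
  structure(list(fill_steps = fill_steps, delta_ip = delta_ip, ip0 = ip0,
                 per_parcel = isTRUE(per_parcel),
                 fill_direction = match.arg(fill_direction),
                 step = 0L, since_empty = 0L, fill_fraction = 0,
                 entry = integer(0),      # entry step of each resident parcel
                 ip_scalar = 0,           # pouch-wide IP (per_parcel = FALSE)
                 emptied_at = integer(0)),
            class = "stool_state")
}

#' Advance the stool cycle by one timestep
#'
#' One new parcel enters; every resident parcel's IP rises by `delta_ip`
#' (implicitly: IP is computed from residence time); the fill fraction is
#' `(steps since last emptying) / fill_steps`. When the fill fraction
#' reaches 1 the pouch empties -- all parcels are cleared and the cycle
#' restarts -- so with the defaults emptying events fall exactly every 16
#' steps.
#'
#' @param state a `stool_state`.
#' @return the updated `stool_state`.
#' @export
step_stool <- function(state) {
  stopifnot(inherits(state, "stool_state"))
  t <- state$step + 1L
  state$step <- t
  state$entry <- c(state$entry, t)
  state$ip_scalar <- state$ip_scalar + state$delta_ip
  s <- state$since_empty + 1L
  if (s == state$fill_steps) {
    state$entry <- integer(0)
    state$ip_scalar <- 0
    state$emptied_at <- c(state$emptied_at, t)
    s <- 0L
  }
  state$since_empty <- s
  state$fill_fraction <- s / state$fill_steps
  state
}

#' Inflammatory potential of resident parcels
#'
#' `IP(t) = IP0 + (t - entry) * delta_ip`, exactly (linear recurrence
#' IP_t = IP_{t-1} + delta_IP applied since entry).
#'
#' @param state a `stool_state`.
#' @param at_step step at which to evaluate (default: current step).
#' @return numeric vector, one IP per resident parcel (empty right after an
#'   emptying event).
#' @export
parcel_ip <- function(state, at_step = state$step) {
  stopifnot(inherits(state, "stool_state"))
  if (!length(state$entry)) return(numeric(0))
  state$ip0 + (at_step - state$entry) * state$delta_ip
}

.mean_ip <- function(state) {
  if (state$per_parcel) {
    ip <- parcel_ip(state)
    if (!length(ip)) 0 else mean(ip)
  } else {
    state$ip_scalar
  }
}

#' Axial unit rows contacted at a given fill fraction
#'
#' With terminal-first filling the stool column occupies the distal
#' `floor(fill_fraction * n_axial)` axial rows; proximal-first reverses the
#' direction. `fill_fraction = 0` contacts nothing, `fill_fraction = 1`
#' contacts every row.
#'
#' @param fill_fraction number in `[0, 1]`.
#' @param n_axial number of axial unit rows.
#' @param fill_direction `"terminal_first"` or `"proximal_first"`.
#' @return integer vector of contacted 0-based axial rows.
#' @export
axial_fill_map <- function(fill_fraction, n_axial,
                           fill_direction = "terminal_first") {
  stopifnot(fill_fraction >= 0, fill_fraction <= 1, n_axial >= 1)
  k <- floor(fill_fraction * n_axial + 1e-9)
  if (k == 0) return(integer(0))
  if (fill_direction == "terminal_first")
    seq.int(n_axial - k, n_axial - 1L)
  else
    seq.int(0L, k - 1L)
}

#' Per-unit Toll-like-receptor drive from stool contact
#'
#' Units whose axial row lies inside the current stool column receive TLR
#' activation input proportional to the mean IP of resident parcels. Over a
#' whole cycle with terminal-first filling the integrated drive is monotone
#' non-increasing from the terminal toward the proximal end: terminal rows
#' are contacted for more of the cycle, and during the late, high-IP part
#' of it.
#'
#' @param state a `stool_state`.
#' @param geom a `pouch_geometry`.
#' @param tlr_gain scaling of mean parcel IP into TLR input per step.
#' @return tibble with one row per unit: `unit`, `axial`, `contacted`,
#'   `drive` (TLR input this step) and `mean_ip`.
#' @export
contact_exposure <- function(state, geom, tlr_gain = 1) {
  stopifnot(inherits(state, "stool_state"), inherits(geom, "pouch_geometry"))
  rows <- axial_fill_map(state$fill_fraction, geom$n_axial,
                         state$fill_direction)
  mip <- .mean_ip(state)
  contacted <- geom$units$axial %in% rows
  tibble::tibble(unit = geom$units$unit,
                 axial = geom$units$axial,
                 contacted = contacted,
                 mean_ip = ifelse(contacted, mip, 0),
                 drive = ifelse(contacted, tlr_gain * mip, 0))
}

# engine-internal: per-unit drive and contact IP as plain vectors
.contact_drive <- function(state, geom, tlr_gain) {
  rows <- axial_fill_map(state$fill_fraction, geom$n_axial,
                         state$fill_direction)
  mip <- .mean_ip(state)
  contacted <- geom$units$axial %in% rows
  list(drive = ifelse(contacted, tlr_gain * mip, 0),
       ip = ifelse(contacted, mip, 0))
}
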