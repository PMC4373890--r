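# Rule parameters and the assembled default parameter set.

#' Default cell rule parameters
#'
#' Constants governing the per-step cell rules. Cycle lengths are in
#' 15-minute steps (stem 96 steps = 24 h, progenitor 48 steps = 12 h,
#' physiological orders). Thresholds are in the relative concentration units
#' of the mediator fields. None of these is printed in the literature the
#' model derives from; they are shipped as documented, configurable defaults
#' calibrated only to give a stable homeostatic steady state with a
#' villus:crypt population ratio near 4:1.
#'
#' @return named list:
#' \describe{
#'   \item{cycle_len_stem, cycle_len_progenitor}{steps between divisions.}
#'   \item{theta_wnt}{proliferation-drive threshold for division.}
#'   \item{theta_bmp}{BMP threshold for enterocyte differentiation.}
#'   \item{stem_rows}{crypt base rows (plus the valley cap) that hold stem
#'     cells.}
#'   \item{shed_rows}{top villus rows (plus the tip cap) where shedding
#'     occurs.}
#'   \item{p_shed}{per-step shedding probability inside the shed zone.}
#'   \item{death_a_ros, death_a_tnfa}{coefficients of the per-step death
#'     probability `1 - exp(-(a_ros*ROS + a_tnfa*TNFA))` (monotone in both,
#'     0 at (0,0)).}
#'   \item{k_exposure}{scaling of `TLR_ACT * IP` into per-agent accumulated
#'     inflammation exposure.}
#'   \item{metaplasia_exposure_threshold}{unit mean exposure above which a
#'     unit turns metaplastic.}
#'   \item{metaplasia_height_slope}{fractional villus height loss per unit of
#'     excess exposure (see [villus_target_height()]).}
#'   \item{metaplasia_min_height_frac}{floor of the metaplastic villus target
#'     height, as a fraction of the original height (>= 1 row).}
#'   \item{metaplasia_reversible}{if FALSE (default) metaplastic units stay
#'     metaplastic after the stimulus is removed.}
#'   \item{resize_every}{steps between dynamic grid resize checks.}
#' }
#' @export
default_rule_params <- function() {
  list(cycle_len_stem = 96L,
       cycle_len_progenitor = 48L,
       theta_wnt = 0.2,
       theta_bmp = 0.5,
       stem_rows = 3L,
       shed_rows = 2L,
       p_shed = 0.012,
       death_a_ros = 0.004,
       death_a_tnfa = 0.004,
       k_exposure = 1,
       metaplasia_exposure_threshold = 3,
       metaplasia_height_slope = 0.15,
       metaplasia_min_height_frac = 0.2,
       metaplasia_reversible = FALSE,
       resize_every = 25L)
}

#' Default stool parameters
#'
#' @return named list of arguments for [stool_state()] plus `enabled` (the
#'   homeostasis scenario runs without stool-driven inflammation) and
#'   `tlr_gain`, the scaling of mean parcel IP into per-step TLR input on
#'   contacted epithelium.
#' @export
default_stool_params <- function() {
  list(enabled = FALSE,
       fill_steps = 16L,
       delta_ip = 0.05,
       ip0 = 0,
       per_parcel = TRUE,
       fill_direction = "terminal_first",
       tlr_gain = 0.5)
}

#' Assembled default parameter set
#'
#' Bundles rule, signaling and stool parameters with the debug switch. Every
#' entry can be overridden via the scenario configuration.
#'
#' @param rules,signaling,stool optional partial overrides (named lists
#'   merged over the defaults).
#' @param debug if TRUE, per-step invariant checks (one-agent-per-site,
#'   halo access guard) are run every step.
#' @return nested parameter list.
#' @export
default_params <- function(rules = list(), signaling = list(),
                           stool = list(), debug = FALSE) {
  p <- list(rules = utils::modifyList(default_rule_params(), rules),
            signaling = utils::modifyList(default_signaling_params(),
                                          signaling),
            stool = utils::modifyList(default_stool_params(), stool),
            debug = isTRUE(debug))
  .check_signaling(p$signaling)
  stopifnot(p$rules$p_shed >= 0, p$rules$p_shed <= 1,
            p$rules$theta_wnt >= 0, p$rules$theta_bmp >= 0,
            p$rules$death_a_ros >= 0, p$rules$death_a_tnfa >= 0)
  p
}

#' Metaplastic villus target height
#'
#' Monotone non-increasing map from a unit's accumulated mean inflammation
#' exposure to its villus target height: below the exposure threshold the
#' target is the original height; above it the target falls linearly with
#' excess exposure down to a floor of
#' `max(1, ceiling(h0 * metaplasia_min_height_frac))` rows. Villus shortening
#' (toward a flatter, colon-like mucosa) is how metaplasia manifests here.
#'
#' @param exposure unit mean accumulated exposure (vector ok).
#' @param h0 original villus height in rows.
#' @param rules rule parameter list (see [default_rule_params()]).
#' @return integer target heights, same length as `exposure`.
#' @export
villus_target_height <- function(exposure, h0, rules = default_rule_params()) {
  thr <- rules$metaplasia_exposure_threshold
  floor_h <- pmax(1L, as.integer(ceiling(h0 * rules$metaplasia_min_height_frac)))
  excess <- pmax(0, exposure - thr)
  tgt <- as.integer(floor(h0 * pmax(0, 1 - rules$metaplasia_height_slope * excess)))
  pmax(floor_h, pmin(as.integer(h0), tgt))
}

# lineage codes
.EMPTY <- 0L
.STEM <- 1L
.PROGENITOR <- 2L
.ENTEROCYTE <- 3L
.METAPLASTIC <- 4L
.LINEAGES <- c("STEM", "PROGENITOR", "ENTEROCYTE", "METAPLASTIC")

#' Lineage names
#'
#' @return character vector of the four epithelial lineages.
#' @export
lineage_ids <- function() .LINEAGES
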