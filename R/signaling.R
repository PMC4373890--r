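# Mediator fields and the signed stimulation/inhibition network.
#
# Every lattice site carries a vector of relative (dimensionless) mediator
# concentrations. Secreted mediators (morphogens, cytokines, ROS) diffuse on
# the folded grids with an explicit 5-point stencil and decay
# multiplicatively; intracellular mediators (kinases, transcription factors,
# receptor activation) do not diffuse and are updated purely by the network.
# The network is a signed, weighted edge list applied synchronously:
#   next = clamp0( cur + basal + input + sum(stim w*src) - sum(inhib w*src)
#                  - lam * cur )
# Acyclic sub-networks therefore have closed-form fixed points (w/lam chains)
# that the tests check against.

.MEDIATORS <- c("WNT", "BMP", "HH", "PTEN", "PI3K", "AKT", "TNFA", "IFNG",
                "RIPK", "NFKB", "JAK", "STAT3", "ROS", "IL6", "IL10",
                "IL13", "IL15", "TLR_ACT")

#' Mediator identifiers
#'
#' The signaling mediators carried per lattice site: the morphogen pathway
#' (Wnt, BMP, Hh, PTEN/PI3K/Akt) and the inflammatory pathway (TNF-alpha,
#' IFN-gamma, RIP kinase, NF-kB, JAK, STAT3, ROS, IL-6/10/13/15, and
#' Toll-like-receptor activation).
#'
#' @return character vector of mediator names.
#' @export
mediator_ids <- function() .MEDIATORS

.med <- function(D, lam, basal = 0, emission = 0, source = "none",
                 source_rows = 0L) {
  list(D = D, lam = lam, basal = basal, emission = emission,
       source = source, source_rows = as.integer(source_rows))
}

#' Default signaling parameters
#'
#' Rate constants (diffusivity `D` in sites^2/step, decay `lam` as fraction
#' per step, constitutive production `basal`, and morphogen emission at
#' source sites) plus the signed network edge list. Secreted mediators
#' diffuse; intracellular ones have `D = 0`. Wnt and Hh are emitted at the
#' crypt base, BMP near the villus tip. Defaults are calibrated only to give
#' monotone crypt-to-tip morphogen gradients and a stable homeostatic
#' steady state; none of the rate constants is measured.
#'
#' IL-13/IL-15 connectors are shipped with zero weight (their directionality
#' is left configurable): edit `edges` to activate them.
#'
#' @return list with elements `mediators` (per-mediator rate list), `edges`
#'   (data frame `source`, `target`, `sign`, `weight`) and `w_stat3_prolif`,
#'   the coupling of STAT3 onto the proliferation drive read by the division
#'   rule.
#' @export
default_signaling_params <- function() {
  mediators <- list(
    WNT  = .med(D = 0.20, lam = 0.08, emission = 1.0,
                source = "crypt_base", source_rows = 2L),
    HH   = .med(D = 0.20, lam = 0.08, emission = 1.0,
                source = "crypt_base", source_rows = 2L),
    BMP  = .med(D = 0.20, lam = 0.05, emission = 1.0,
                source = "villus_tip", source_rows = 2L),
    TNFA = .med(D = 0.10, lam = 0.15),
    IFNG = .med(D = 0.10, lam = 0.10),
    ROS  = .med(D = 0.05, lam = 0.20),
    IL6  = .med(D = 0.10, lam = 0.10),
    IL10 = .med(D = 0.10, lam = 0.10),
    IL13 = .med(D = 0.10, lam = 0.10),
    IL15 = .med(D = 0.10, lam = 0.10),
    TLR_ACT = .med(D = 0, lam = 0.25),
    NFKB = .med(D = 0, lam = 0.20),
    JAK  = .med(D = 0, lam = 0.20),
    STAT3 = .med(D = 0, lam = 0.20),
    RIPK = .med(D = 0, lam = 0.20),
    PTEN = .med(D = 0, lam = 0.02, basal = 0.02),
    PI3K = .med(D = 0, lam = 0.02, basal = 0.04),
    AKT  = .med(D = 0, lam = 0.10)
  )
  edges <- data.frame(
    source = c("TLR_ACT", "TNFA", "NFKB", "NFKB", "NFKB", "IFNG", "RIPK",
               "IL6", "JAK", "IL10", "PTEN", "PI3K", "IL13", "IL15"),
    target = c("NFKB", "NFKB", "TNFA", "IL6", "ROS", "RIPK", "ROS",
               "JAK", "STAT3", "NFKB", "PI3K", "AKT", "NFKB", "TNFA"),
    sign   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, -1, -1, 1, 1, 1),
    weight = c(0.5, 0.3, 0.05, 0.2, 0.2, 0.3, 0.2, 0.3, 0.3, 0.3, 0.02,
               0.1, 0, 0),
    stringsAsFactors = FALSE)
  list(mediators = mediators, edges = edges, w_stat3_prolif = 0.5)
}

.check_signaling <- function(sig) {
  unknown <- setdiff(names(sig$mediators), .MEDIATORS)
  if (length(unknown))
    stop("unknown mediator in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.MEDIATORS, names(sig$mediators))
  if (length(missing))
    stop("mediator missing from config: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(c(sig$edges$source, sig$edges$target)), .MEDIATORS)
  if (length(bad))
    stop("unknown mediator in network edges: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(sig$edges$weight < 0))
    stop("edge weights must be non-negative (sign carries inhibition)",
         call. = FALSE)
  if (any(sig$edges$source == sig$edges$target))
    stop("self-edges are not allowed in the signaling network", call. = FALSE)
  for (m in names(sig$mediators)) {
    p <- sig$mediators[[m]]
    if (p$D < 0 || 4 * p$D > 1)
      stop(sprintf("mediator %s: need 0 <= D and 4*D <= 1 for stencil stability (D = %g)",
                   m, p$D), call. = FALSE)
    if (p$lam < 0 || p$lam > 1)
      stop(sprintf("mediator %s: decay lam must lie in [0, 1]", m),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' One explicit diffusion + decay step
#'
#' Applies the 5-point stencil over the folded neighbour graph with zero-flux
#' outer boundaries (a missing neighbour contributes the centre value), then
#' multiplicative decay `(1 - lam)`. Because neighbour exchange is pairwise
#' antisymmetric, total mass is conserved exactly (to float tolerance) when
#' `lam = 0`, and the mass removed by decay is exactly `lam` times the
#' pre-decay mass. Stability requires `4 * D <= 1`, which also preserves
#' non-negativity.
#'
#' @param values numeric per-site vector (length `idx$N`), non-negative.
#' @param idx a `site_index` (or `pouch_geometry`).
#' @param D diffusivity in sites^2 per step.
#' @param lam decay fraction per step in `[0, 1]`.
#' @return updated per-site vector.
#' @export
diffuse_decay_step <- function(values, idx, D, lam = 0) {
  idx <- .as_index(idx)
  stopifnot(length(values) == idx$N)
  if (D < 0 || 4 * D > 1)
    stop("stencil stability requires 0 <= D and 4*D <= 1", call. = FALSE)
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]", call. = FALSE)
  nb <- idx$nbr
  self <- seq_len(idx$N)
  n1 <- ifelse(is.na(nb[, 1]), self, nb[, 1])
  n2 <- ifelse(is.na(nb[, 2]), self, nb[, 2])
  n3 <- ifelse(is.na(nb[, 3]), self, nb[, 3])
  n4 <- ifelse(is.na(nb[, 4]), self, nb[, 4])
  (values + D * (values[n1] + values[n2] + values[n3] + values[n4] -
                   4 * values)) * (1 - lam)
}

#' One synchronous network update
#'
#' Updates the mediator vector(s) from the previous step's values:
#' `next = clamp0(cur + basal + input + sum(signed weighted sources) - lam*cur)`.
#' Works on any set of equal-length concentration vectors (a single site or
#' a whole tissue).
#'
#' @param conc named list of numeric vectors, one per mediator (all 18).
#' @param sig signaling parameter list (see [default_signaling_params()]).
#' @param inputs optional named list of additive external inputs (e.g.
#'   Toll-like-receptor drive from stool contact).
#' @param lam_override optional named numeric vector replacing the decay of
#'   selected mediators for this call (the engine uses it to avoid applying
#'   decay twice to mediators whose decay was taken during diffusion).
#' @return named list of updated vectors.
#' @export
network_step <- function(conc, sig, inputs = NULL, lam_override = NULL) {
  .check_signaling(sig)
  if (length(bad <- setdiff(names(conc), .MEDIATORS)))
    stop("unknown mediator in concentration vector: ",
         paste(bad, collapse = ", "), call. = FALSE)
  nxt <- conc
  for (m in names(conc)) {
    p <- sig$mediators[[m]]
    lam <- if (!is.null(lam_override) && m %in% names(lam_override))
      lam_override[[m]] else p$lam
    acc <- conc[[m]] + p$basal - lam * conc[[m]]
    if (!is.null(inputs) && !is.null(inputs[[m]])) acc <- acc + inputs[[m]]
    e <- sig$edges[sig$edges$target == m & sig$edges$weight > 0, , drop = FALSE]
    for (i in seq_len(nrow(e)))
      acc <- acc + e$sign[i] * e$weight[i] * conc[[e$source[i]]]
    nxt[[m]] <- pmax(0, acc)
  }
  nxt
}

#' Knock out a mediator
#'
#' Silences a mediator the way a gene knockout does: its morphogen emission,
#' constitutive production and every stimulatory edge producing it are set to
#' zero. Existing concentration is left to decay naturally. Inhibitory edges
#' onto the mediator are kept (they act on whatever remains).
#'
#' @param params either a full scenario parameter list containing
#'   `$signaling`, or a signaling parameter list itself.
#' @param mediator one of [mediator_ids()].
#' @return the modified parameter object.
#' @export
apply_knockout <- function(params, mediator) {
  mediator <- toupper(as.character(mediator))
  if (!mediator %in% .MEDIATORS)
    stop("unknown mediator: ", mediator, call. = FALSE)
  sig_inside <- !is.null(params$signaling)
  sig <- if (sig_inside) params$signaling else params
  sig$mediators[[mediator]]$emission <- 0
  sig$mediators[[mediator]]$basal <- 0
  hit <- sig$edges$target == mediator & sig$edges$sign > 0
  sig$edges$weight[hit] <- 0
  if (sig_inside) { params$signaling <- sig; params } else sig
}

#' Per-row mean concentration along the crypt-villus axis
#'
#' Averages a mediator field over the columns of one unit, row by row along
#' the crypt-base -> villus-tip axis (crypt rows first, then villus rows; cap
#' rows are excluded). At homeostatic steady state with default sources the
#' Wnt and Hh profiles are monotone non-increasing from the crypt base and
#' the BMP profile non-decreasing toward the tip.
#'
#' @param values per-site field vector (length `idx$N`) or a `tissue_state`
#'   (in which case `mediator` selects the field).
#' @param idx a `site_index` (ignored when a `tissue_state` is given).
#' @param unit 0-based unit index.
#' @param mediator mediator name when `values` is a `tissue_state`.
#' @return tibble with `axis_row` (0 = crypt base), `component`, `row`,
#'   `mean_concentration`.
#' @export
gradient_profile <- function(values, idx = NULL, unit = 0L, mediator = NULL) {
  if (inherits(values, "tissue_state")) {
    ts <- values
    stopifnot(!is.null(mediator))
    idx <- ts$idx
    values <- .gather_field(ts, mediator)
  }
  idx <- .as_index(idx)
  unit <- as.integer(unit)
  sel <- which(idx$unit == unit & !idx$is_cap)
  if (!length(sel)) stop("invalid unit index", call. = FALSE)
  comp <- idx$comp[sel]; row <- idx$row[sel]
  dc <- idx$height[sel][comp == .CRYPT][1]
  axis <- ifelse(comp == .CRYPT, row, dc + row)
  agg <- tapply(values[sel], axis, mean)
  ax <- as.integer(names(agg))
  tibble::tibble(axis_row = ax,
                 component = ifelse(ax < dc, "CRYPT", "VILLUS"),
                 row = ifelse(ax < dc, ax, ax - dc),
                 mean_concentration = as.numeric(agg))
}
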