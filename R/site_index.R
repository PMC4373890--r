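# Site index: explicit per-site arrays and the folded-grid adjacency.
#
# Each crypt-villus prism is stored as an unwrapped tube: rows x W grid with
# W = n_faces * face_width columns that wrap circularly around the prism
# (faces are contiguous column ranges). The villus tube is closed at the tip
# and the crypt tube at the valley by one cap row of W/2 sites lying along a
# fold line: cap site k joins the two opposite-face columns k and W-1-k.
# The open ends (villus base, crypt mouth) are joined across the inter-unit
# flat: face f of a villus connects to the crypt mouth of the lattice
# neighbour unit in direction f, column-mirrored, which realizes the offset
# alternation of crypt and villus prisms. The resulting neighbour relation is
# symmetric with degree <= 4 everywhere.

.CRYPT <- 1L
.VILLUS <- 2L
.RANK_VILLUS_BASE <- 4096L

# cap index served by main-row column c
.cap_k <- function(c, W) ifelse(c < W %/% 2L, c, W - 1L - c)

# Internal adjacency of one tube (main rows + one cap row), 0-based relative
# ids, NA where the neighbour lies outside the component (cross-unit link or
# missing). `open` is "bottom" (villus: cap above top row, row 0 open) or
# "top" (crypt: cap below row 0, top row open).
.tube_proto <- function(H, W, open) {
  Wh <- W %/% 2L
  n <- H * W + Wh
  nbr <- matrix(NA_integer_, n, 4L)
  r <- rep(0:(H - 1L), each = W)
  c <- rep(0:(W - 1L), H)
  main <- seq_len(H * W)
  up <- ifelse(r < H - 1L, (r + 1L) * W + c, NA_integer_)
  dn <- ifelse(r > 0L, (r - 1L) * W + c, NA_integer_)
  cap_of_c <- H * W + .cap_k(c, W)
  if (open == "bottom") {          # villus: tip cap above row H-1
    up[r == H - 1L] <- cap_of_c[r == H - 1L]
  } else {                         # crypt: valley cap below row 0
    dn[r == 0L] <- cap_of_c[r == 0L]
  }
  nbr[main, 1L] <- up
  nbr[main, 2L] <- dn
  nbr[main, 3L] <- r * W + (c - 1L) %% W
  nbr[main, 4L] <- r * W + (c + 1L) %% W
  k <- 0:(Wh - 1L)
  cap <- H * W + k + 1L
  anchor <- if (open == "bottom") H - 1L else 0L
  nbr[cap, 1L] <- anchor * W + k
  nbr[cap, 2L] <- anchor * W + (W - 1L - k)
  nbr[cap, 3L] <- ifelse(k > 0L, H * W + k - 1L, NA_integer_)
  nbr[cap, 4L] <- ifelse(k < Wh - 1L, H * W + k + 1L, NA_integer_)
  list(n = n, nbr = nbr,
       row = c(r, rep(H, Wh)),              # cap stored as row = H
       col = c(c, k),
       is_cap = c(rep(FALSE, H * W), rep(TRUE, Wh)))
}

#' Build the per-site index of a pouch geometry
#'
#' Materializes every lattice site of the geometry: coordinates, the folded
#' von Neumann adjacency (degree <= 4, symmetric), the migration rank along
#' the crypt-base -> villus-tip axis, and a stable per-site key used by the
#' counter-based RNG. Intended for desk-scale geometries (it allocates
#' O(sites) arrays).
#'
#' @param geom a `pouch_geometry`.
#' @return A `site_index` object: list with per-site vectors `unit`, `comp`
#'   (1 = crypt, 2 = villus), `row` (cap sites carry `row = height`), `col`
#'   (global column, 0..W-1; cap sites carry the cap position 0..W/2-1),
#'   `is_cap`, `axial`, `rank`, `key`, the `N x 4` neighbour matrix `nbr`
#'   (1-based global site ids, NA where no neighbour exists) and unit offsets.
#' @export
site_index <- function(geom) {
  stopifnot(inherits(geom, "pouch_geometry"))
  tpl <- geom$template
  W <- tpl$n_faces * tpl$face_width
  fw <- tpl$face_width
  Wh <- W %/% 2L
  un <- geom$units
  n_units <- nrow(un)
  dc <- un$crypt_depth
  hv <- un$villus_height
  csize <- dc * W + Wh
  vsize <- hv * W + Wh
  su <- csize + vsize
  off <- cumsum(c(0L, su))[seq_len(n_units)]
  N <- sum(su)

  unit <- integer(N); comp <- integer(N); row <- integer(N)
  col <- integer(N); is_cap <- logical(N)
  nbr <- matrix(NA_integer_, N, 4L)

  protos <- new.env(parent = emptyenv())
  get_proto <- function(H, open) {
    keyp <- paste0(open, H)
    if (is.null(protos[[keyp]])) protos[[keyp]] <- .tube_proto(H, W, open)
    protos[[keyp]]
  }
  # unit lattice neighbours per direction (0-based unit ids, NA off the ends)
  nb_dir <- matrix(NA_integer_, n_units, 4L)
  for (d in 0:3) for (u in seq_len(n_units))
    nb_dir[u, d + 1L] <- .unit_neighbor(geom, u - 1L, d)

  cols <- 0:(W - 1L)
  f_of_c <- cols %/% fw
  c_mirror <- ((f_of_c + 2L) %% 4L) * fw + (fw - 1L - cols %% fw)

  for (u in seq_len(n_units)) {
    pc <- get_proto(dc[u], "top")
    pv <- get_proto(hv[u], "bottom")
    ic <- off[u] + seq_len(pc$n)             # crypt block (1-based global)
    iv <- off[u] + pc$n + seq_len(pv$n)      # villus block
    unit[ic] <- un$unit[u]; unit[iv] <- un$unit[u]
    comp[ic] <- .CRYPT; comp[iv] <- .VILLUS
    row[ic] <- pc$row; row[iv] <- pv$row
    col[ic] <- pc$col; col[iv] <- pv$col
    is_cap[ic] <- pc$is_cap; is_cap[iv] <- pv$is_cap
    nbr[ic, ] <- pc$nbr + off[u] + 1L
    nbr[iv, ] <- pv$nbr + off[u] + pc$n + 1L
    # cross-unit links: crypt mouth (top row) <-> villus base (row 0) of the
    # lattice neighbour in the face direction, column-mirrored
    nbu <- nb_dir[u, f_of_c + 1L]            # 0-based or NA, per column
    has <- !is.na(nbu)
    crypt_top <- off[u] + (dc[u] - 1L) * W + cols + 1L
    villus_r0 <- off[u] + pc$n + cols + 1L
    if (any(has)) {
      nb1 <- nbu[has] + 1L
      vr0_nb <- off[nb1] + csize[nb1] + c_mirror[has] + 1L
      ctop_nb <- off[nb1] + (dc[nb1] - 1L) * W + c_mirror[has] + 1L
      nbr[crypt_top[has], 1L] <- vr0_nb
      nbr[villus_r0[has], 2L] <- ctop_nb
    }
    if (any(!has)) {
      # pouch ends are closed: where no axial neighbour exists the
      # inter-unit flat folds back onto the same unit (face-local column
      # mirror), so no conveyor column dead-ends at the boundary
      c_self <- (cols %/% fw) * fw + (fw - 1L - cols %% fw)
      nbr[crypt_top[!has], 1L] <- villus_r0[c_self[!has] + 1L]
      nbr[villus_r0[!has], 2L] <- crypt_top[c_self[!has] + 1L]
    }
  }

  height <- ifelse(comp == .CRYPT, dc[unit + 1L], hv[unit + 1L])
  rank <- ifelse(comp == .CRYPT,
                 ifelse(is_cap, -1L, row),
                 .RANK_VILLUS_BASE + row)    # villus cap row = hv => rank base+hv
  rowcode <- ifelse(is_cap, 0L, row + 1L)   # caps keep their key across resizes
  key <- ((unit * 2 + (comp == .VILLUS)) * 4096 + rowcode) * 256 + col + 1

  structure(list(geom = geom, N = N, W = W, face_width = fw,
                 unit = unit, comp = comp, row = row, col = col,
                 is_cap = is_cap, height = height,
                 axial = un$axial[unit + 1L],
                 rank = rank, key = key, nbr = nbr,
                 offsets = off, unit_size = su),
            class = "site_index")
}

#' @export
print.site_index <- function(x, ...) {
  cat(sprintf("<site_index> %d sites over %d units (W = %d)\n",
              x$N, nrow(x$geom$units), x$W))
  invisible(x)
}

.as_index <- function(x) {
  if (inherits(x, "site_index")) return(x)
  if (inherits(x, "pouch_geometry")) return(site_index(x))
  stop("expected a pouch_geometry or site_index", call. = FALSE)
}

#' Convert grid coordinates to site ids
#'
#' @param idx a `site_index` (or `pouch_geometry`).
#' @param coords data frame with columns `unit_index`, `component` ("CRYPT" or
#'   "VILLUS"), `face` (0..3), `row` (cap sites use `row = height`) and `col`
#'   (column within the face).
#' @return integer vector of 1-based site ids.
#' @export
coord_to_site <- function(idx, coords) {
  idx <- .as_index(idx)
  compc <- ifelse(toupper(as.character(coords$component)) == "VILLUS",
                  .VILLUS, .CRYPT)
  fw <- idx$face_width
  gcol <- as.integer(coords$face) * fw + as.integer(coords$col)
  # cap sites are addressed by row = height; their stored col is the cap
  # position, reachable from either opposite face column
  gid <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    u <- as.integer(coords$unit_index[i])
    sel <- which(idx$unit == u & idx$comp == compc[i])
    if (!length(sel)) stop("invalid unit_index in coordinate", call. = FALSE)
    h <- idx$height[sel[1]]
    r <- as.integer(coords$row[i])
    if (r == h) {
      hit <- sel[idx$is_cap[sel] & idx$col[sel] == .cap_k(gcol[i], idx$W)]
    } else {
      hit <- sel[!idx$is_cap[sel] & idx$row[sel] == r & idx$col[sel] == gcol[i]]
    }
    if (length(hit) != 1) stop("invalid grid coordinate", call. = FALSE)
    gid[i] <- hit
  }
  gid
}

#' Convert site ids to grid coordinates
#'
#' @param idx a `site_index` (or `pouch_geometry`).
#' @param sites integer vector of 1-based site ids.
#' @return A tibble with columns `site`, `unit_index`, `component`, `face`,
#'   `row`, `col`, `is_cap`.
#' @export
site_to_coord <- function(idx, sites) {
  idx <- .as_index(idx)
  sites <- as.integer(sites)
  if (any(is.na(sites)) || any(sites < 1L) || any(sites > idx$N))
    stop("invalid site id", call. = FALSE)
  fw <- idx$face_width
  tibble::tibble(site = sites,
                 unit_index = idx$unit[sites],
                 component = ifelse(idx$comp[sites] == .VILLUS,
                                    "VILLUS", "CRYPT"),
                 face = idx$col[sites] %/% fw,
                 row = idx$row[sites],
                 col = idx$col[sites] %% fw,
                 is_cap = idx$is_cap[sites])
}

#' Neighbours of a site after folding
#'
#' Returns the von Neumann neighbourhood of a site on the folded crypt-villus
#' surface: within-face row/col neighbours, face-to-face wraps at column
#' edges, the villus-base to crypt-mouth links across the inter-unit flat,
#' and the tip/valley cap links. The relation is symmetric with degree <= 4.
#'
#' @param idx a `site_index` (or `pouch_geometry`).
#' @param coords a coordinate data frame (see [coord_to_site()]) or, if
#'   `sites` is given, NULL.
#' @param sites optional integer site ids (bypasses coordinate conversion).
#' @return A tibble of neighbour coordinates (see [site_to_coord()]), with a
#'   `from_site` column identifying the query site.
#' @export
neighbor_sites <- function(idx, coords = NULL, sites = NULL) {
  idx <- .as_index(idx)
  if (is.null(sites)) sites <- coord_to_site(idx, coords)
  out <- lapply(sites, function(s) {
    nb <- idx$nbr[s, ]
    nb <- nb[!is.na(nb)]
    cbind(from_site = rep(s, length(nb)), site_to_coord(idx, nb))
  })
  tibble::as_tibble(do.call(rbind, out))
}

#' Map sites to 3D pouch coordinates
#'
#' Deterministic embedding used for mesh export: each unit sits on the
#' cylinder surface at its (axial, circumferential) position; villus sites are
#' displaced outward (luminally) by `row` cell diameters and crypt sites
#' inward; prism faces are offset laterally within the tangent plane, and the
#' crypt prism is shifted by half a unit spacing to reflect the offset
#' alternation of crypts and villi. Rendering only; no model rule depends on
#' these coordinates.
#'
#' @param idx a `site_index` (or `pouch_geometry`).
#' @param sites integer site ids (default: all sites).
#' @param cell_diameter_um nominal cell diameter in micrometres.
#' @return numeric matrix with columns x, y, z (millimetres).
#' @export
to_3d <- function(idx, sites = NULL, cell_diameter_um = 10) {
  idx <- .as_index(idx)
  if (is.null(sites)) sites <- seq_len(idx$N)
  geom <- idx$geom
  cell <- cell_diameter_um / 1000               # mm
  R <- geom$diameter_cm * 10 / 2                # mm
  sp <- geom$unit_spacing_mm
  fw <- idx$face_width
  hside <- fw * cell / 2

  u <- idx$unit[sites]
  ax <- u %/% geom$n_circ
  ci <- u %% geom$n_circ
  comp <- idx$comp[sites]
  row <- idx$row[sites]
  col <- idx$col[sites]
  cap <- idx$is_cap[sites]
  h <- idx$height[sites]

  radial <- ifelse(comp == .VILLUS,
                   ifelse(cap, (h + 1), (row + 1)) * cell,
                   ifelse(cap, -h, -(h - 1 - row)) * cell)
  face <- col %/% fw
  cf <- col %% fw
  tpos <- (cf + 0.5) * cell - hside
  # perimeter position of each face in the (tangent t, axial zloc) plane
  # cap sites line up along the fold line at half-cell spacing
  t_loc <- ifelse(cap, (col + 0.5) * cell / 2 - hside,
           ifelse(face == 0L, tpos,
           ifelse(face == 1L, hside,
           ifelse(face == 2L, -tpos, -hside))))
  z_loc <- ifelse(cap, 0,
           ifelse(face == 0L, -hside,
           ifelse(face == 1L, tpos,
           ifelse(face == 2L, hside, -tpos))))
  # crypt prisms sit on the half-spacing offset lattice
  t_loc <- t_loc + ifelse(comp == .CRYPT, sp / 2, 0)
  z_off <- ifelse(comp == .CRYPT, sp / 2, 0)

  theta <- 2 * pi * ci / geom$n_circ + t_loc / R
  r3 <- R + radial
  cbind(x = r3 * cos(theta),
        y = r3 * sin(theta),
        z = ax * sp + z_loc + z_off)
}

# Old-to-new site correspondence after a geometry change: for each site of
# `new_idx`, the matching site id in `old_idx` (NA where the site is new).
# Cap sites match across height changes (their key row code is constant).
.match_sites <- function(new_idx, old_idx) {
  match(new_idx$key, old_idx$key)
}
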