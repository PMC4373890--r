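test_that("anatomic pouch construction gives the expected unit lattice", {
  geom <- build_pouch(3.5, 6, 0.5)
  expect_equal(geom$n_circ, 219)   # floor(pi * 35 / 0.5)
  expect_equal(geom$n_axial, 120)  # floor(60 / 0.5)
  expect_equal(nrow(geom$units), 219 * 120)
  # lazy: site count is arithmetic, no index allocated
  W <- 4 * geom$template$face_width
  expect_equal(n_sites(geom),
               sum((geom$units$villus_height +
                      geom$units$crypt_depth + 1) * W))
})

test_that("degenerate and invalid dimensions are rejected or exact", {
  # spacing exactly equal to the circumference -> a single circumferential unit
  d <- 0.5 / (10 * pi)
  geom <- build_pouch(d, 1, 0.5)
  expect_equal(geom$n_circ, 1)
  expect_error(build_pouch(3.5, 0, 0.5), "length_cm")
  expect_error(build_pouch(-1, 6, 0.5), "diameter_cm")
  expect_error(build_pouch(3.5, 6, 0), "unit_spacing_mm")
  # spacing larger than the circumference: no unit fits
  expect_error(build_pouch(0.01, 6, 5), "circumference")
  expect_error(crypt_villus_unit(villus_height = 0), "villus_height")
  expect_error(crypt_villus_unit(n_faces = 6), "n_faces")
})

test_that("fold adjacency matches a brute-force enumeration of the rules", {
  for (geom in list(lattice_pouch(1, 1, tiny_template()),
                    tiny_geom(2, 3),
                    lattice_pouch(2, 2, tiny_template(2, 2, 2)))) {
    idx <- site_index(geom)
    expect_setequal(index_fold_edges(idx), naive_fold_edges(geom))
  }
})

test_that("neighbour relation is symmetric with degree at most 4", {
  idx <- site_index(tiny_geom(2, 3))
  for (s in seq_len(idx$N)) {
    nb <- idx$nbr[s, ]
    nb <- nb[!is.na(nb)]
    expect_lte(length(nb), 4)
    expect_false(anyDuplicated(nb) > 0)
    for (b in nb) expect_true(s %in% idx$nbr[b, ])
  }
})

test_that("interior sites have exactly four neighbours", {
  geom <- lattice_pouch(2, 2, crypt_villus_unit(villus_height = 10,
                                                crypt_depth = 6,
                                                face_width = 6))
  idx <- site_index(geom)
  s <- coord_to_site(idx, data.frame(unit_index = 0, component = "VILLUS",
                                     face = 0, row = 5, col = 2))
  nb <- neighbor_sites(idx, sites = s)
  expect_equal(nrow(nb), 4)
  # and its neighbours are the within-face von Neumann set
  expect_setequal(nb$row, c(4, 6, 5, 5))
})

test_that("grid coordinates round-trip through site ids", {
  idx <- site_index(tiny_geom(2, 2))
  co <- site_to_coord(idx, seq_len(idx$N))
  back <- coord_to_site(idx, data.frame(unit_index = co$unit_index,
                                        component = co$component,
                                        face = co$face, row = co$row,
                                        col = co$col))
  expect_equal(back, seq_len(idx$N))
})

test_that("3D embedding is injective and respects the radial/angular layout", {
  geom <- tiny_geom(2, 3)
  idx <- site_index(geom)
  xyz <- to_3d(idx)
  expect_equal(nrow(xyz), idx$N)
  expect_equal(anyDuplicated(round(xyz, 9)), 0)

  cell <- 10 / 1000
  radial <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  # villus base and crypt mouth of the same unit sit within one cell
  # diameter of the tissue baseline
  vb <- coord_to_site(idx, data.frame(unit_index = 0, component = "VILLUS",
                                      face = 1, row = 0, col = 0))
  cm <- coord_to_site(idx, data.frame(unit_index = 0, component = "CRYPT",
                                      face = 1, row = 2, col = 0))
  expect_lte(abs(radial[vb] - radial[cm]), cell + 1e-12)
  # villus tip row lies villus_height cell diameters above the baseline
  tip <- coord_to_site(idx, data.frame(unit_index = 0, component = "VILLUS",
                                       face = 1, row = 3, col = 0))
  R <- geom$diameter_cm * 10 / 2
  expect_equal(radial[tip] - R, geom$template$villus_height * cell,
               tolerance = 1e-9)
  # circumferentially adjacent units are separated by 2*pi/n_circ
  a1 <- atan2(xyz[vb, 2], xyz[vb, 1])
  vb2 <- coord_to_site(idx, data.frame(unit_index = 1, component = "VILLUS",
                                       face = 1, row = 0, col = 0))
  a2 <- atan2(xyz[vb2, 2], xyz[vb2, 1])
  expect_equal(unname((a2 - a1) %% (2 * pi)), 2 * pi / geom$n_circ,
               tolerance = 1e-9)
})

test_that("axial positions are monotone multiples of the unit spacing", {
  geom <- build_pouch(3.5, 6, 0.5)
  expect_equal(axial_position_mm(geom, 0), 0)
  k <- 7
  expect_equal(axial_position_mm(geom, k * geom$n_circ), k * 0.5)
  last <- (geom$n_axial - 1) * geom$n_circ
  expect_equal(axial_position_mm(geom, last), 59.5)
  expect_error(axial_position_mm(geom, -1), "invalid")
  expect_error(axial_position_mm(geom, geom$n_axial * geom$n_circ),
               "invalid")
})

test_that("resizing grows by empty rows and preserves payloads", {
  geom <- tiny_geom(1, 2, hv = 4, dc = 3, fw = 2)
  ts <- init_tissue(geom, fast_params(), seed = 1)
  before <- gather_state(ts, fields = FALSE, occupied_only = TRUE)
  n_before <- ts$idx$N
  ts2 <- resize_unit(ts, 0, "VILLUS", 6)
  expect_equal(ts2$idx$N, n_before + 2 * 8)   # 2 new rows x W sites
  after <- gather_state(ts2, fields = FALSE, occupied_only = TRUE)
  # cap sites keep their payload but re-attach at the new height
  key <- function(d) paste(d$unit_index, d$component,
                           ifelse(d$is_cap, "cap", d$row), d$col,
                           d$lineage, d$cell_id)
  expect_setequal(key(after), key(before))
})

test_that("shrinking deletes only empty rows and clamps at occupied ones", {
  geom <- lattice_pouch(1, 2, tiny_template(hv = 12, dc = 3, fw = 2))
  ts <- init_tissue(geom, fast_params(), seed = 1, occupancy = "empty")
  # place one cell on villus row 7 of unit 0
  s <- coord_to_site(ts$idx, data.frame(unit_index = 0, component = "VILLUS",
                                        face = 0, row = 7, col = 0))
  w <- ts$dec$workers[[1]]
  w$lin[s] <- 3L; w$health[s] <- 1; w$cell_id[s] <- 99
  ts$dec$workers[[1]] <- w
  ts2 <- resize_unit(ts, 0, "VILLUS", 4)
  expect_equal(ts2$geom$units$villus_height[1], 8)  # clamped to row 7 + 1
  expect_match(paste(ts2$log, collapse = "\n"), "clamp")
  st <- gather_state(ts2, fields = FALSE, occupied_only = TRUE)
  expect_equal(nrow(st), 1)
  expect_equal(st$row, 7)
  expect_equal(st$cell_id, 99)
  # unit 1 was empty: its shrink is exact
  ts3 <- resize_unit(ts, 1, "VILLUS", 4)
  expect_equal(ts3$geom$units$villus_height[2], 4)
  expect_equal(ts3$idx$N, ts$idx$N - 8 * 8)
})
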