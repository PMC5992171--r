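test_that("constant boundaries map to regular polygons", {
  g <- acquisition_geometry(radial_pixel_pitch = 0.01,
                            probe_offset_radius = 0.3,
                            frame_spacing = 0.2)
  b <- lumen_boundary(rep(70L, 36))
  poly <- boundary_to_polygon(b, g)
  r <- sqrt(rowSums(poly^2))
  expect_equal(r, rep(0.3 + 70 * 0.01, 36))
  # four A-lines at radius 1 from the axis: the canonical diamond
  g0 <- acquisition_geometry(radial_pixel_pitch = 0.01,
                             probe_offset_radius = 0,
                             frame_spacing = 0.2)
  # relax the W >= 8 B-scan convention: geometry math itself is generic
  b4 <- lumen_boundary(rep(100L, 4))
  p4 <- boundary_to_polygon(b4, g0)
  expect_equal(unname(p4),
               rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
               tolerance = 1e-12)
})

test_that("shoelace area matches closed forms", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(cross_section_area(sq), 1)
  # regular W-gon: 0.5 * W * r^2 * sin(2*pi/W); near the control trachea
  # scale this is ~4.33 mm^2
  W <- 360; r <- 1.174
  th <- 2 * pi * (0:(W - 1)) / W
  gon <- cbind(r * cos(th), r * sin(th))
  expect_equal(cross_section_area(gon), 0.5 * W * r^2 * sin(2 * pi / W))
  expect_equal(cross_section_area(gon), pi * r^2, tolerance = 1e-4)
  expect_equal(cross_section_area(gon * 1e-6), 0, tolerance = 1e-9)
  expect_error(cross_section_area(sq[1:2, ]), "3 vertices")
})

test_that("polygon area converges to the circle as A-lines increase", {
  g <- acquisition_geometry(radial_pixel_pitch = 0.005,
                            probe_offset_radius = 0.3, frame_spacing = 0.2)
  r <- 0.3 + 140 * 0.005
  for (W in c(16, 64, 180)) {
    area <- cross_section_area(
      boundary_to_polygon(lumen_boundary(rep(140L, W)), g))
    rel_err <- abs(area - pi * r^2) / (pi * r^2)
    expect_lt(rel_err, 0.5 * (2 * pi / W)^2)
  }
})

test_that("the lumen mask rasterizes the space between probe and boundary", {
  b0 <- lumen_boundary(rep(0L, 10))
  expect_false(any(lumen_mask(b0, c(12, 10))))
  btop <- lumen_boundary(rep(11L, 10))
  m <- lumen_mask(btop, c(12, 10))
  expect_true(all(m[1:11, ]))
  expect_false(any(m[12, ]))
  # column sums equal the boundary depth indices exactly
  set.seed(5)
  d <- as.integer(10 + cumsum(sample(-1:1, 20, replace = TRUE)))
  b <- lumen_boundary(d)
  expect_equal(colSums(lumen_mask(b, c(40, 20))), as.numeric(d),
               ignore_attr = TRUE)
})

test_that("stack quantification integrates areas into volume", {
  g <- acquisition_geometry(radial_pixel_pitch = 0.01,
                            probe_offset_radius = 0.3, frame_spacing = 0.2)
  # constant-area stack: volume = n * A * spacing, SD 0
  b <- lumen_boundary(rep(70L, 36))
  rep150 <- stack_quantify(rep(list(b), 150), g)
  A <- cross_section_area(boundary_to_polygon(b, g))
  expect_equal(rep150$total_volume, 150 * A * 0.2)
  expect_equal(rep150$sd_area, 0)
  # three different radii: volume, mean, SD follow the areas
  g1 <- acquisition_geometry(radial_pixel_pitch = 0.01,
                             probe_offset_radius = 0.3, frame_spacing = 1)
  bs <- lapply(c(40L, 60L, 80L), function(d) lumen_boundary(rep(d, 36)))
  rp <- stack_quantify(bs, g1)
  areas <- vapply(bs, function(b)
    cross_section_area(boundary_to_polygon(b, g1)), numeric(1))
  expect_equal(rp$per_frame_area, areas)
  expect_equal(rp$total_volume, sum(areas) * 1)
  expect_equal(rp$mean_area, mean(areas))
  expect_equal(rp$sd_area, stats::sd(areas))
  # invariant: volume == sum(area) * spacing
  expect_equal(rp$total_volume, sum(rp$per_frame_area) * rp$frame_spacing)
})

test_that("volume is linear in spacing and invariant to frame order", {
  bs <- lapply(c(40L, 60L, 80L, 50L), function(d) lumen_boundary(rep(d, 36)))
  mk <- function(sp) acquisition_geometry(radial_pixel_pitch = 0.01,
                                          probe_offset_radius = 0.3,
                                          frame_spacing = sp)
  v1 <- stack_quantify(bs, mk(0.2))$total_volume
  v2 <- stack_quantify(bs, mk(0.4))$total_volume
  expect_equal(v2, 2 * v1)
  vperm <- stack_quantify(bs[c(3, 1, 4, 2)], mk(0.2))$total_volume
  expect_equal(vperm, v1)
})

test_that("missing frames are excluded and counted", {
  g <- acquisition_geometry(radial_pixel_pitch = 0.01,
                            probe_offset_radius = 0.3, frame_spacing = 0.2)
  b <- lumen_boundary(rep(70L, 36))
  rp <- stack_quantify(list(b, NA, b), g)
  expect_equal(rp$n_missing, 1)
  A <- cross_section_area(boundary_to_polygon(b, g))
  expect_equal(rp$total_volume, 2 * A * 0.2)
  expect_equal(rp$mean_area, A)
})

test_that("regional summaries split the pullback at the given fractions", {
  g <- acquisition_geometry(radial_pixel_pitch = 0.01,
                            probe_offset_radius = 0.3, frame_spacing = 0.2)
  bs <- c(rep(list(lumen_boundary(rep(40L, 36))), 5),
          rep(list(lumen_boundary(rep(80L, 36))), 5))
  rp <- stack_quantify(bs, g, region_splits = 0.5)
  rs <- rp$region_summaries
  expect_equal(nrow(rs), 2)
  expect_equal(rs$frame_lo, c(1, 6))
  expect_equal(rs$frame_hi, c(5, 10))
  expect_equal(rs$sd_area, c(0, 0))
  expect_lt(rs$mean_area[1], rs$mean_area[2])
})
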