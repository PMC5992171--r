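test_that("the transition weight follows its closed form", {
  expect_equal(pixel_cost(1, 1, 1), 0)     # brightest transition is free
  expect_equal(pixel_cost(0, 0, 1), 2)
  expect_equal(pixel_cost(0.25, 0.5, 1), 1.25)
  expect_true(all(pixel_cost(runif(50), runif(50), 1) >= 0))
})

test_that("a bright row accumulates zero cost along every column", {
  G <- matrix(0, 8, 10); G[4, ] <- 1
  cm <- compute_cost_matrix(G)
  expect_equal(cm$cost[4, ], rep(0, 10))
  expect_true(all(cm$cost[-4, ] > 0))
  b <- trace_min_cost_path(cm)
  expect_equal(b$depth_index, rep(3L, 10))   # constant at the bright row
})

test_that("uniform images give equal straight-path costs and straight ties", {
  for (c0 in c(0, 0.3, 1)) {
    G <- matrix(c0, 6, 7)
    cm <- compute_cost_matrix(G)
    # all rows identical by symmetry; ties broken toward straight moves
    expect_true(all(apply(cm$cost, 1, function(r) identical(r, cm$cost[1, ]))))
    expect_true(all(cm$backpointer[, -1] == 0))
    expect_equal(trace_min_cost_path(cm)$depth_index, rep(0L, 7))
  }
})

test_that("the swept minimum cost matches exhaustive path enumeration", {
  set.seed(11)
  G <- matrix(runif(6 * 9), 6, 9)
  p <- dp_params(alpha = 1.5)
  cm <- compute_cost_matrix(G, p)
  expect_equal(min(cm$cost[, 9]), enumerate_min_cost(G, 1.5))
  # and across a batch of random shapes
  for (rep in 1:40) {
    nr <- sample(2:8, 1); nc <- sample(2:10, 1)
    G <- matrix(runif(nr * nc), nr, nc)
    a <- runif(1, 1, 2)
    cm <- compute_cost_matrix(G, dp_params(alpha = a))
    expect_equal(min(cm$cost[, nc]), enumerate_min_cost(G, a))
  }
})

test_that("a bright diagonal is traced exactly", {
  rows <- 2:9
  G <- gradient_from_rows(rows, 12)
  b <- trace_min_cost_path(compute_cost_matrix(G))
  expect_equal(b$depth_index, rows - 1L)
  expect_true(all(abs(diff(b$depth_index)) <= 1))
})

test_that("equal-cost minima in the last column resolve to the smaller row", {
  # two bright rows, symmetric: rows 4 and 8 (1-based) both cost-free
  G <- matrix(0, 10, 6); G[4, ] <- 1; G[8, ] <- 1
  b <- trace_min_cost_path(compute_cost_matrix(G))
  expect_equal(b$depth_index, rep(3L, 6))
})

test_that("every prefix of the traced path is itself minimum-cost", {
  set.seed(3)
  G <- matrix(runif(7 * 8), 7, 8)
  a <- 1.3
  cm <- compute_cost_matrix(G, dp_params(alpha = a))
  rows <- trace_min_cost_path(cm)$depth_index + 1L
  for (i in 2:8) {
    expect_equal(path_cost(G[, 1:i, drop = FALSE], rows[1:i], a,
                           maxI = max(G)),
                 cm$cost[rows[i], i])
  }
})

test_that("circular padding closes the boundary across the seam", {
  W <- 16
  rows <- c(rep(21L, 8), rep(24L, 8))  # +3 step inside AND at the seam
  G <- gradient_from_rows(rows, 40, bright = 1, bg = 0.01)
  padded <- detect_boundary_circular(G, dp_params())
  expect_true(padded$closed)
  d <- padded$depth_index
  expect_true(all(abs(diff(c(d, d[1]))) <= 1))   # wrap-connected
  # without padding the path has no reason to ramp back near the seam
  unpadded <- suppressWarnings(
    detect_boundary_circular(G, dp_params(pad_mode = "none")))
  expect_false(unpadded$closed)
})

test_that("circularly symmetric frames give constant, closed boundaries", {
  ph <- generate_phantom(small_cylinder_spec(n_frames = 1))
  den <- denoise(ph$stack$frames[[1]])
  bin <- remove_small_objects(binarize(den), 200)
  g <- depth_gradient(top_surface_mask(den, bin, feature_params()))
  b <- detect_boundary_circular(g)
  expect_true(b$closed)
  expect_equal(length(unique(b$depth_index)), 1)
})

test_that("a small sinusoidal boundary is recovered within one pixel", {
  W <- 8; n_depth <- 16
  truth <- 8 + round(sin(2 * pi * (0:(W - 1)) / W))   # amplitude 1 px
  G <- gradient_from_rows(truth + 1L, n_depth)
  b <- detect_boundary_circular(G)
  expect_true(all(abs(b$depth_index - truth) <= 1))
})

test_that("rotating the frame columns rotates the boundary identically", {
  W <- 24
  truth <- 12 + round(2 * sin(2 * pi * (0:(W - 1)) / W))
  G <- gradient_from_rows(truth + 1L, 24)
  b0 <- detect_boundary_circular(G)$depth_index
  for (k in c(3, 11)) {
    Gk <- G[, c((k + 1):W, 1:k)]
    bk <- detect_boundary_circular(Gk)$depth_index
    expect_equal(bk, b0[c((k + 1):W, 1:k)])
  }
})

test_that("raising alpha only increases the number of straight moves", {
  # brighter zig-zag path versus a dimmer straight row; an isolated
  # max-intensity pixel in a far corner keeps max(I) above both so the
  # zig-zag transitions are not cost-free
  W <- 9
  zig <- 5 + c(0, 1, 0, 1, 0, 1, 0, 1, 0)
  G <- matrix(0, 12, W)
  G[cbind(zig, 1:W)] <- 0.9
  G[11, ] <- 0.8
  G[12, 1] <- 1
  n_straight <- vapply(c(1, 1.2, sqrt(2), 2, 3), function(a) {
    b <- trace_min_cost_path(compute_cost_matrix(G, dp_params(alpha = a)))
    sum(diff(b$depth_index) == 0)
  }, numeric(1))
  expect_true(all(diff(n_straight) >= 0))
  # with alpha = 1 the brighter zig-zag wins outright
  b1 <- trace_min_cost_path(compute_cost_matrix(G, dp_params(alpha = 1)))
  expect_equal(b1$depth_index, zig - 1L)
})

test_that("degenerate inputs are rejected", {
  expect_error(compute_cost_matrix(matrix(0.5, 5, 1)), "2 columns")
  expect_error(detect_boundary_circular(matrix(0.5, 10, 4)), "8 columns")
  expect_error(dp_params(alpha = 0.5), "alpha")
  expect_error(lumen_boundary(c(0L, 5L)), "connectivity")
})
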