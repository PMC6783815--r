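test_that("convexity and solidity are plain guarded ratios", {
  expect_equal(convexity(6, 6), 1.0)
  expect_equal(convexity(8, 10), 0.8)
  expect_error(convexity(0, 1), "positive")
  expect_equal(solidity(1, 1), 1.0)
  expect_equal(solidity(3, 3.5), 6 / 7)
  expect_error(solidity(-1, 1), "positive")
  expect_error(solidity(1.1, 1), "beyond tolerance")
  expect_equal(solidity(1 + 5e-10, 1), 1 + 5e-10)  # within tolerance
})

test_that("L-tromino prism solidity converges to the analytic 6/7", {
  body <- make_body(phantom_spec("l_prism", size = list(cell = 40,
                                                        height = 40)))
  d <- measure(body$volume)
  expect_equal(body$truth$S, 6 / 7)
  expect_lt(abs(d$S - 6 / 7) / (6 / 7), 0.02)
})

test_that("plus-pentomino prism convexity converges to the analytic value", {
  body <- make_body(phantom_spec("plus_prism", size = list(cell = 40,
                                                           height = 40)))
  C_true <- (18 + 4 * sqrt(2)) / 22  # ~1.0753: hull area exceeds object area
  expect_equal(body$truth$C, C_true)
  d <- measure(body$volume)
  expect_lt(abs(d$C - C_true) / C_true, 0.02)
})

test_that("hemispherical shell solidity matches the analytic ratio", {
  # V_shell / V_half-ball = 1 - (1 - t/r)^3 = 0.271 for r=30, t=3
  body <- make_body(phantom_spec("shell", size = list(r = 30,
                                                      thickness = 3)))
  expect_equal(body$truth$S, 1 - 0.9^3)
  d <- measure(body$volume)
  expect_lt(abs(d$S - (1 - 0.9^3)), 0.02)
})

test_that("a solid sphere is measured as nearly convex", {
  d <- measure(make_body(phantom_spec("sphere", size = list(r = 20)))$volume)
  expect_gte(d$C, 0.97); expect_lte(d$C, 1.03)
  expect_gte(d$S, 0.95); expect_lte(d$S, 1.0)
})

test_that("flat slab phantom is measured as convex; twisting lowers S", {
  flat <- measure(make_twisted_slab(60, 24, 5, twist = 0))
  expect_lt(abs(flat$S - 1), 0.05)
  expect_gt(flat$C, 0.9); expect_lt(flat$C, 1.1)
  twisted <- measure(make_twisted_slab(60, 24, 5, twist = 180))
  expect_lt(twisted$S, flat$S)
})

test_that("solidity converges to 1 with sphere resolution; convexity stays near 1", {
  # |S - 1| shrinks with radius; |C - 1| does NOT converge under this
  # mesher (the staircase area bias is scale-free for fixed voxel-unit
  # smoothing) but stays within 2% at every radius
  ds <- lapply(c(10, 20, 40), function(r)
    measure(make_body(phantom_spec("sphere", size = list(r = r)))$volume))
  s_err <- vapply(ds, function(d) abs(d$S - 1), 0)
  expect_true(all(diff(s_err) < 0))
  expect_true(all(vapply(ds, function(d) abs(d$C - 1), 0) < 0.02))
})

test_that("solidity never exceeds 1 on the phantom suite", {
  specs <- list(
    phantom_spec("sphere", size = list(r = 12)),
    phantom_spec("cuboid", size = list(a = 8, b = 14, c = 20)),
    phantom_spec("slab", size = list(length = 40, width = 16,
                                     thickness = 4)),
    phantom_spec("l_prism", size = list(cell = 10, height = 10)),
    phantom_spec("plus_prism", size = list(cell = 10, height = 10)),
    phantom_spec("shell", size = list(r = 15, thickness = 2)),
    phantom_spec("twisted_slab", size = list(length = 40, width = 16,
                                             thickness = 4), twist = 90)
  )
  for (sp in specs) {
    d <- measure(make_body(sp)$volume)
    expect_lte(d$S, 1 + 1e-9)
    expect_gt(d$S, 0); expect_gt(d$C, 0)
    expect_gt(d$V, 0); expect_lte(d$V, d$Vc * (1 + 1e-9))
  }
})

test_that("doubling spacing leaves C and S unchanged, scales V by 8 and A by 4", {
  a <- make_body(phantom_spec("l_prism", size = list(cell = 10,
                                                     height = 10)))$volume
  b <- binary_volume(a$data, spacing = 2)
  da <- measure(a); db <- measure(b)
  expect_equal(db$C, da$C, tolerance = 1e-9)
  expect_equal(db$S, da$S, tolerance = 1e-9)
  expect_equal(db$V / da$V, 8, tolerance = 1e-9)
  expect_equal(db$Vc / da$Vc, 8, tolerance = 1e-9)
  expect_equal(db$A / da$A, 4, tolerance = 1e-9)
  expect_equal(db$Ac / da$Ac, 4, tolerance = 1e-9)
})
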