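test_that("phantom specs validate their parameters", {
  expect_error(phantom_spec("sphere", size = list(r = -1)), "size")
  expect_error(phantom_spec("slab", size = list(length = 1), twist = -5),
               "twist")
  expect_error(make_twisted_slab(10, 20, 5), "thickness < width < length")
})

test_that("sphere voxel count matches the analytic ball volume within 1%", {
  b <- make_body(phantom_spec("sphere", size = list(r = 20)))
  expect_lt(abs(sum(b$volume$data) - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3),
            0.01)
  expect_equal(b$truth$V, 4 / 3 * pi * 20^3)
})

test_that("twist 0 and undulation 0 reduce to the flat slab exactly", {
  sl <- make_body(phantom_spec("slab", size = list(length = 30, width = 12,
                                                   thickness = 4)))
  tw <- make_twisted_slab(30, 12, 4, twist = 0)
  expect_identical(sl$volume$data, tw$data)
  expect_equal(sum(tw$data), 30 * 12 * 4)
  expect_equal(sl$truth$S, 1)
})

test_that("twisted slabs are connected single components", {
  for (tw in c(90, 180, 270)) {
    b <- make_twisted_slab(40, 16, 4, twist = tw)
    lab <- morphoct:::.label_components3d(b$data, 26L)
    expect_equal(max(lab), 1L)
  }
})

test_that("body generation is bit-reproducible and grids auto-fit", {
  sp <- phantom_spec("twisted_slab",
                     size = list(length = 30, width = 12, thickness = 4),
                     twist = 135, undulation_amplitude = 1.5)
  expect_identical(make_body(sp)$volume$data, make_body(sp)$volume$data)
  expect_error(make_body(phantom_spec("sphere", size = list(r = 10),
                                      grid = c(12L, 12L, 12L))),
               "exceeds the grid")
})

test_that("voxelized measurements converge to the analytic truth", {
  err <- function(shape, size_fn, res) {
    vapply(res, function(r) {
      body <- make_body(phantom_spec(shape, size = size_fn(r)))
      d <- measure(body$volume)
      abs(d$V - body$truth$V) / body$truth$V
    }, 0)
  }
  e_sph <- err("sphere", function(r) list(r = r), c(8, 16, 32))
  expect_true(all(diff(e_sph) < 0))
  e_cub <- err("cuboid", function(r) list(a = r, b = r, c = r), c(8, 16, 32))
  expect_true(all(diff(e_cub) < 0))
})

test_that("scenes have exact intensities without noise and are seeded", {
  sp <- scene_spec(noise_sd = 0, seed = 10)
  sc <- make_scene(sp)
  expect_setequal(unique(as.vector(sc$scene$data)), c(0, 100, 200, 230))
  sc2 <- make_scene(scene_spec(seed = 11))
  sc3 <- make_scene(scene_spec(seed = 11))
  expect_identical(sc2$scene$data, sc3$scene$data)
  expect_false(identical(make_scene(scene_spec(seed = 12))$scene$data,
                         sc2$scene$data))
  # intensity ordering invariant
  expect_error(scene_spec(plant_intensity = 250), "pedestal_intensity")
})

test_that("sample_population jitters sizes reproducibly", {
  base <- phantom_spec("slab", size = list(length = 30, width = 12,
                                           thickness = 4))
  p0 <- sample_population(4, base, jitter = 0, label = "g", seed = 1)
  expect_true(all(vapply(p0, function(x)
    identical(x$volume$data, p0[[1]]$volume$data), TRUE)))

  p1 <- sample_population(6, base, jitter = 0.1, label = "g", seed = 2)
  p1b <- sample_population(6, base, jitter = 0.1, label = "g", seed = 2)
  expect_identical(lapply(p1, function(x) x$spec$size),
                   lapply(p1b, function(x) x$spec$size))
  p2 <- sample_population(6, base, jitter = 0.1, label = "g", seed = 3)
  expect_false(identical(lapply(p1, function(x) x$spec$size),
                         lapply(p2, function(x) x$spec$size)))

  # lognormal jitter with sdlog correction is mean-preserving: two seeds
  # give the same marginal mean length within 3 standard errors
  big1 <- sample_population(60, base, jitter = 0.1, label = "g", seed = 4)
  big2 <- sample_population(60, base, jitter = 0.1, label = "g", seed = 5)
  len <- function(p) vapply(p, function(x) x$spec$size$length, 0)
  se <- sqrt(var(len(big1)) / 60 + var(len(big2)) / 60)
  expect_lt(abs(mean(len(big1)) - mean(len(big2))), 3 * se)
  expect_error(sample_population(3, base, jitter = -1), "invalid jitter")
})
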