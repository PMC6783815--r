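test_that("threshold_volume binarizes at fixed and Otsu thresholds", {
  a <- array(0, c(4, 4, 4)); a[1:2, , ] <- 100
  v <- volume3d(a)
  b <- threshold_volume(v, 50)
  expect_equal(b$data, a >= 50)
  expect_true(all(!threshold_volume(v, max(a) + 1)$data))

  # bimodal: Otsu lands between the modes, mask ~= t = 100 ground truth
  set.seed(5)
  x <- array(c(rnorm(4000, 20, 10), rnorm(4000, 180, 10)), c(20, 20, 20))
  vb <- volume3d(x)
  bb <- threshold_volume(vb, "auto")
  expect_lt(mean(bb$data != (x >= 100)), 0.01)

  expect_error(threshold_volume(volume3d(array(7, c(3, 3, 3))), "auto"),
               "no threshold separates")
})

test_that("pedestal mask covers high-intensity voxels and dilation is monotone", {
  sc <- make_scene(scene_spec(seed = 21, noise_sd = 0))
  v <- sc$scene
  cfg <- extraction_config(high_threshold = 150, plant_threshold = 50)
  m <- build_pedestal_mask(v, cfg)
  expect_equal(unname(m$data), unname(v$data >= 150))  # pedestal + tube
  # covers >= 99% of pedestal voxels
  ped <- v$data == 200
  expect_gte(sum(m$data & ped) / sum(ped), 0.99)

  m1 <- build_pedestal_mask(v, extraction_config(high_threshold = 150,
                                                 plant_threshold = 50,
                                                 mask_dilation_radius = 1))
  expect_true(all(m1$data[m$data]))  # dilated mask is a superset

  none <- build_pedestal_mask(v, extraction_config(high_threshold = 1e6,
                                                   plant_threshold = 50))
  expect_false(any(none$data))
})

test_that("subtract_mask zeroes masked voxels only", {
  set.seed(9)
  v <- volume3d(array(runif(64, 1, 2), c(4, 4, 4)))
  zero <- binary_volume(array(FALSE, c(4, 4, 4)))
  expect_equal(subtract_mask(v, zero)$data, v$data)
  one <- binary_volume(array(TRUE, c(4, 4, 4)))
  expect_true(all(subtract_mask(v, one)$data == 0))
  expect_error(subtract_mask(v, binary_volume(array(TRUE, c(3, 3, 3)))),
               "shape mismatch")
})

test_that("edge mask flags thin rim noise, spares thick bodies", {
  cfg <- extraction_config()
  zero <- binary_volume(array(FALSE, c(6, 6, 6)))
  expect_false(any(build_edge_mask(zero, cfg)$data))

  # solid cube: mask confined to the 1-voxel boundary shell
  cb <- binary_volume(cube_mask(8))
  shell <- cb$data & !morphoct:::.erode3d(cb$data, 6L, 1L)
  m <- build_edge_mask(cb, cfg)
  expect_true(all(!m$data | shell))

  # phantom binarization with a 1-voxel pedestal rim: the mask covers
  # >= 95% of rim voxels and < 1% of plant voxels
  sc <- make_scene(scene_spec(seed = 22, noise_sd = 0))
  v <- sc$scene
  cfg2 <- extraction_config(high_threshold = 150, plant_threshold = 50)
  m1 <- build_pedestal_mask(v, cfg2)
  b <- threshold_volume(subtract_mask(v, m1), 50)
  rim <- b$data & !sc$truth$data  # rim is the only non-plant foreground
  m2 <- build_edge_mask(b, cfg2, near = m1)
  expect_gte(sum(m2$data & rim) / sum(rim), 0.95)
  expect_lt(sum(m2$data & sc$truth$data) / sum(sc$truth$data), 0.01)
})

test_that("component selection matches the spec examples", {
  a <- array(FALSE, c(10, 10, 10))
  a[1:3, 1:3, 1:3] <- TRUE   # 27 voxels
  a[7:8, 7:8, 7:8] <- TRUE   # 8 voxels
  b <- binary_volume(a)
  sel <- select_plant_component(b, extraction_config(), "largest")
  expect_equal(sum(sel$data), 27)
  expect_true(all(sel$data[1:3, 1:3, 1:3]))

  sel2 <- select_plant_component(b, extraction_config(), c(7L, 7L, 7L))
  expect_equal(sum(sel2$data), 8)

  single <- binary_volume(cube_mask(3))
  expect_equal(select_plant_component(single)$data, single$data)

  expect_error(select_plant_component(binary_volume(array(FALSE, c(3, 3, 3)))),
               "empty foreground")
  expect_error(select_plant_component(b, extraction_config(), c(5L, 5L, 5L)),
               "background")

  # diagonal-touching pair: one component under 26, two under 6
  d <- array(FALSE, c(4, 4, 4))
  d[1:2, 1:2, 1:2] <- TRUE; d[3:4, 3:4, 3:4] <- TRUE
  bd <- binary_volume(d)
  expect_equal(sum(select_plant_component(
    bd, extraction_config(connectivity = 26))$data), 16)
  expect_equal(sum(select_plant_component(
    bd, extraction_config(connectivity = 6))$data), 8)
})

test_that("component labeling agrees with a breadth-first oracle", {
  set.seed(1234)
  for (rep in 1:60) {
    a <- array(runif(8^3) < 0.35, c(8, 8, 8))
    conn <- sample(c(6L, 18L, 26L), 1)
    lab <- morphoct:::.label_components3d(a, conn)
    ref <- bfs_components(a, conn)
    # same partition: number of components and same co-membership
    expect_equal(max(lab), max(ref))
    expect_equal(length(unique(paste(lab[a], ref[a]))), max(ref))
  }
})

test_that("extract_plant recovers the plant from phantom scenes", {
  sc <- make_scene(scene_spec(seed = 1))
  p <- extract_plant(sc$scene)
  expect_gte(jaccard(p$data, sc$truth$data), 0.95)
  expect_equal(dim(p$data), dim(sc$scene$data))
  expect_equal(p$spacing, sc$scene$spacing)

  ps <- phantom_spec("twisted_slab",
                     size = list(length = 60, width = 24, thickness = 5),
                     twist = 180, undulation_amplitude = 2,
                     undulation_period = 20)
  sc2 <- make_scene(scene_spec(plant = ps, seed = 2))
  p2 <- extract_plant(sc2$scene)
  expect_gte(jaccard(p2$data, sc2$truth$data), 0.95)

  # output is one connected component and a subset of the binarization
  st <- attr(extract_plant(sc$scene, debug = TRUE), "stages")
  lab <- morphoct:::.label_components3d(p$data, 26L)
  expect_equal(max(lab), 1L)
  expect_true(all(st$binarized$data[p$data]))
})

test_that("extraction quality is non-increasing in noise", {
  j <- vapply(c(0, 5, 20), function(sd) {
    sc <- make_scene(scene_spec(noise_sd = sd, seed = 3))
    jaccard(extract_plant(sc$scene)$data, sc$truth$data)
  }, 0)
  expect_true(all(diff(j) <= 0))
})

test_that("a plant-free scene fails with a clear error", {
  sc <- make_scene(scene_spec(seed = 5))
  d <- sc$scene$data
  d[sc$truth$data] <- 0
  expect_error(extract_plant(volume3d(d, name = "noplant")),
               "no plant component found")
})
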