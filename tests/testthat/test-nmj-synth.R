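test_that("shape parameters validate their ranges", {
  expect_error(nmj_shape_params(target_apposition = 120), "\\[0, 100\\]")
  expect_error(nmj_shape_params(target_relative_planar_area = 0), "\\(0, 100\\]")
  expect_error(nmj_shape_params(n_slices = 0), "\\[1, 50\\]")
  expect_error(nmj_shape_params(pixel_size = -1), "positive")
})

test_that("full apposition with no fringe makes the masks identical", {
  r <- render_nmj_stack(nmj_shape_params(target_apposition = 100,
                                         fringe_fraction = 0, seed = 2))
  expect_identical(r$truth$pre_mask, r$truth$post_mask)
  expect_equal(r$truth$apposition, 100)
})

test_that("area targeting hits the requested endplate area within 2%", {
  for (target in c(150, 417, 600)) {
    r <- render_nmj_stack(nmj_shape_params(target_endplate_csa = target,
                                           canvas = 320, seed = 4))
    expect_equal(r$truth$endplate_csa, target, tolerance = 0.02)
    # pixel-count arithmetic: area / pixel_size^2
    expect_equal(sum(r$truth$post_mask), target / 0.176^2, tolerance = 0.02)
  }
})

test_that("recorded ground truth is self-consistent with the emitted masks", {
  r <- render_nmj_stack(nmj_shape_params(seed = 9))
  with_masks <- 100 * sum(r$truth$pre_mask & r$truth$post_mask) /
    sum(r$truth$post_mask)
  expect_equal(r$truth$apposition, with_masks)
  areas <- compute_areas(r$truth$post_mask, 0.176)
  expect_equal(areas$csa, r$truth$endplate_csa)
  expect_equal(areas$relative_planar_area, r$truth$relative_planar_area,
               tolerance = 1e-9)
})

test_that("rendering is deterministic under a fixed seed", {
  r1 <- render_nmj_stack(nmj_shape_params(seed = 6))
  r2 <- render_nmj_stack(nmj_shape_params(seed = 6))
  expect_identical(r1$stack$post, r2$stack$post)
  expect_identical(r1$stack$pre, r2$stack$pre)
  expect_identical(r1$truth$post_mask, r2$truth$post_mask)
})

test_that("unreachable geometry is reported with achieved vs requested", {
  expect_error(
    render_nmj_stack(nmj_shape_params(target_endplate_csa = 2000,
                                      target_relative_planar_area = 30,
                                      canvas = 128)),
    "canvas|unreachable|Geometry")
})

test_that("cohort draws respect the class criteria and are counted per design", {
  co <- generate_nmj_cohort(n_per_class = 1, n_animals = 2, seed = 8,
                            n_slices = 6)
  expect_equal(nrow(co), 4)  # 1 per class x 2 classes x 2 animals
  small <- co[co$drawn_class == "I_IIa", ]
  expect_true(all(small$target_csa < 500))
  expect_true(all(small$fiber_diameter < 50))
  expect_true(all(small$intended_class == "I_IIa"))
  # a large-endplate draw on a thin fibre is flagged excluded, not reclassed
  expect_equal(as.character(classify_fiber_type(600, 40)), "excluded")
})

test_that("cohort generation is deterministic given the master seed", {
  c1 <- generate_nmj_cohort(n_per_class = 1, n_animals = 1, seed = 12,
                            n_slices = 4)
  c2 <- generate_nmj_cohort(n_per_class = 1, n_animals = 1, seed = 12,
                            n_slices = 4)
  expect_identical(c1$stack[[1]]$post, c2$stack[[1]]$post)
})
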