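test_that("projection of a single-slice stack returns that slice", {
  m <- matrix(0, 32, 32); m[10:20, 10:20] <- 100
  st <- manual_stack(array(m, dim = c(32, 32, 1)))
  pj <- project_stack(st)
  expect_equal(pj$post, m)
})

test_that("automatic slice range keeps only signal-bearing slices", {
  r <- render_nmj_stack(nmj_shape_params(n_slices = 12, seed = 5))
  st <- r$stack
  npx <- prod(dim(st$post)[1:2])
  set.seed(1)
  for (s in c(1, 10, 11, 12)) {
    st$post[, , s] <- round(pmax(0, 20 + rnorm(npx, 0, 7.5)))
    st$pre[, , s] <- round(pmax(0, 20 + rnorm(npx, 0, 7.5)))
  }
  pj <- project_stack(st)
  expect_equal(pj$slices$post, 2:9)
  expect_equal(length(pj$slices$post), 8)
})

test_that("projection errors on empty input or an empty slice range", {
  st <- manual_stack(array(0, dim = c(16, 16, 4)))
  expect_error(project_stack(st), "No signal slices")
  st2 <- manual_stack(array(10, dim = c(16, 16, 4)))
  expect_error(project_stack(st2, slices = 9), "valid slice")
  expect_error(project_stack(st2, slices = integer(0)), "valid slice")
})

test_that("thresholding separates a two-level image exactly and logs itself", {
  img <- matrix(10, 40, 40); img[15:25, 15:25] <- 100
  mk <- threshold_channel(img)
  expect_identical(unclass(mk)[seq_along(img)], as.vector(img == 100))
  expect_equal(attr(mk, "method"), "otsu")
  expect_true(attr(mk, "threshold") > 10 && attr(mk, "threshold") < 100)
  # apposition is invariant to uniform intensity rescaling under otsu
  mk2 <- threshold_channel(img * 7.3)
  expect_equal(sum(mk2), sum(mk))
  expect_error(threshold_channel(matrix(5, 4, 4)), "constant")
  fixed <- threshold_channel(img, "fixed", value = 0)
  expect_true(all(fixed))
  expect_error(threshold_channel(img, "fixed"), "required")
})

test_that("thresholded masks recover the generator's truth masks", {
  r <- render_nmj_stack(nmj_shape_params(seed = 3))
  pj <- project_stack(r$stack)
  mk <- clean_mask(threshold_channel(pj$post), pj$pixel_size,
                   keep_largest = TRUE)
  jaccard <- sum(mk & r$truth$post_mask) / sum(mk | r$truth$post_mask)
  expect_gte(jaccard, 0.9)
})

test_that("apposition is overlap over post-synaptic area", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:20] <- TRUE
  expect_equal(compute_apposition(a, a), 100)
  b <- matrix(FALSE, 20, 20); b[11:20, 1:20] <- TRUE
  expect_equal(compute_apposition(b, a), 0)
  post <- matrix(FALSE, 20, 20); post[1:10, 1:20] <- TRUE  # 200 px
  pre <- matrix(FALSE, 20, 20); pre[1:6, 1:20] <- TRUE     # 120 px overlap
  expect_equal(compute_apposition(pre, post), 60.0)
  expect_error(compute_apposition(pre, matrix(FALSE, 20, 20)), "empty")
})

test_that("areas and relative planar area follow pixel arithmetic", {
  full <- matrix(TRUE, 10, 20)
  res <- compute_areas(full, 1)
  expect_equal(res$relative_planar_area, 100)
  expect_equal(res$csa, 200)
  sq <- matrix(FALSE, 30, 30); sq[1:10, 1:10] <- TRUE
  expect_equal(compute_areas(sq, 0.5)$csa, 25)
  expect_error(compute_areas(matrix(FALSE, 5, 5), 1), "empty")
  # relative planar area is 100 only when the mask fills its bounding box
  l_shape <- matrix(FALSE, 10, 10); l_shape[1:10, 1] <- TRUE; l_shape[10, 1:10] <- TRUE
  expect_lt(compute_areas(l_shape, 1)$relative_planar_area, 100)
})

test_that("fibre-type classification applies the joint size criteria", {
  expect_equal(as.character(classify_fiber_type(400, 40)), "I_IIa")
  expect_equal(as.character(classify_fiber_type(600, 60)), "IIx_IIb")
  expect_equal(as.character(classify_fiber_type(600, 40)), "excluded")
  # exact boundary values fall in neither class
  expect_equal(as.character(classify_fiber_type(500, 50)), "excluded")
  expect_equal(as.character(classify_fiber_type(c(400, 600), c(40, 60))),
               c("I_IIa", "IIx_IIb"))
  expect_error(classify_fiber_type(-1, 40), "positive")
})

test_that("single-NMJ measurement recovers generator ground truth", {
  r <- render_nmj_stack(nmj_shape_params(seed = 11))
  m <- measure_nmj(r$stack)
  expect_equal(m$endplate_csa, r$truth$endplate_csa, tolerance = 0.05)
  expect_equal(m$apposition, r$truth$apposition, tolerance = 0.05)
  expect_equal(m$relative_planar_area, r$truth$relative_planar_area,
               tolerance = 0.07)
  expect_equal(as.character(m$fiber_type_class),
               as.character(r$truth$intended_class))
})

test_that("cohort analysis aggregates per animal and retains excluded NMJs", {
  co <- generate_nmj_cohort(n_per_class = 1, n_animals = 2, seed = 21,
                            n_slices = 6)
  res <- analyze_nmj_cohort(co)
  expect_equal(nrow(res$per_nmj), 4)
  expect_equal(nrow(res$per_animal), 2)
  # single NMJ per class per animal: class means equal the NMJ values
  one <- res$per_nmj[res$per_nmj$fiber_type_class != "excluded", ]
  for (i in seq_len(nrow(one))) {
    cls_row <- res$per_animal_class[
      res$per_animal_class$animal_id == one$animal_id[i] &
        res$per_animal_class$fiber_type_class == one$fiber_type_class[i], ]
    expect_equal(cls_row$apposition, one$apposition[i])
  }
  # overall means include every NMJ
  expect_equal(sum(res$per_animal$n_nmj), 4)
  expect_error(analyze_nmj_cohort(tibble::tibble()), "at least one row")
})

test_that("all-excluded cohorts leave the type table empty, not the overall", {
  r1 <- render_nmj_stack(nmj_shape_params(target_endplate_csa = 600,
                                          fiber_diameter = 40, seed = 2,
                                          canvas = 320))
  co <- tibble::tibble(animal_id = "R1", stack = list(r1$stack))
  res <- analyze_nmj_cohort(co)
  expect_equal(nrow(res$per_animal_class), 0)
  expect_equal(nrow(res$per_animal), 1)
  expect_equal(res$per_animal$n_excluded, 1)
})
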