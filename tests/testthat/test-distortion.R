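test_that("RMS length error vanishes on a zero field", {
  zero <- disk_field(function(x, y) 0 * x, function(x, y) 0 * y)
  cv <- rms_length_error(zero, n_pairs = 2e4, seed = 1)
  expect_true(all(cv$rms_um[!is.na(cv$rms_um)] == 0))
})

test_that("a residual uniform 5% scale reads 5% of L in every bin", {
  sc <- disk_field(function(x, y) 0.05 * (x - 995),
                   function(x, y) 0.05 * (y - 995))
  cv <- rms_length_error(sc, n_pairs = 2e5, seed = 1)
  ok <- !is.na(cv$rms_pct)
  expect_true(all(abs(cv$rms_pct[ok] - 5) < 0.1))
})

test_that("sampled curve matches the dense brute-force oracle on a shear", {
  g <- 0.1
  fx <- function(x, y) g * (y - 995)
  fy <- function(x, y) 0 * y
  sh <- disk_field(fx, fy)
  cv <- rms_length_error(sh, n_pairs = 2e5, seed = 2)
  br <- attr(cv, "breaks")
  oracle <- brute_force_rms(fx, fy, 1e6, centre = 995, r_um = 900,
                            breaks = br, seed = 42)
  ok <- !is.na(cv$rms_um) & !is.na(oracle$rms_um)
  rel <- abs(cv$rms_um[ok] - oracle$rms_um[ok]) / oracle$rms_um[ok]
  expect_lt(max(rel), 0.05)
  # consistency: doubling n_pairs moves bins by less than 3x the MC error
  cv2 <- rms_length_error(sh, n_pairs = 4e5, seed = 3)
  mc_se <- cv$rms_um / sqrt(2 * pmax(cv$n_pairs, 1))
  ok2 <- ok & cv$n_pairs > 100
  expect_true(all(abs(cv2$rms_um[ok2] - cv$rms_um[ok2]) <=
                    3 * mc_se[ok2] + 1e-9))
})

test_that("identical seeds give bit-identical curves", {
  sh <- disk_field(function(x, y) 0.05 * y, function(x, y) 0.02 * x)
  a <- rms_length_error(sh, n_pairs = 3e4, seed = 77)
  b <- rms_length_error(sh, n_pairs = 3e4, seed = 77)
  expect_identical(a, b)
  c_ <- rms_length_error(sh, n_pairs = 3e4, seed = 78)
  expect_false(identical(a$rms_um, c_$rms_um))
})

test_that("removing the similarity makes a pure uniformly-scaled pair error-free", {
  # a landmark set under pure scaling: the fitted similarity absorbs all
  # of it and the residual non-rigid field is numerically zero
  ph <- make_phantom_pair(size = c(96, 96), pixel_size = 16, lef = 6.5,
                          amplitude = 0, noise_sd = 0, seed = 12)
  reg <- register_expansion(ph$pre, ph$post, ph$landmarks, refine = FALSE)
  cv <- rms_length_error(reg$field, n_pairs = 2e4, max_length = 1200,
                         seed = 4)
  expect_lt(max(cv$rms_um, na.rm = TRUE), 1e-4)
})

test_that("endpoint-error variant reports differential displacement", {
  sh <- disk_field(function(x, y) 0.1 * (y - 995), function(x, y) 0 * y)
  cv <- rms_length_error(sh, n_pairs = 5e4, seed = 5, error = "endpoint")
  # endpoint error >= length error for the same field (triangle inequality)
  cl <- rms_length_error(sh, n_pairs = 5e4, seed = 5, error = "length")
  ok <- !is.na(cv$rms_um) & !is.na(cl$rms_um)
  expect_true(all(cv$rms_um[ok] >= cl$rms_um[ok] - 1e-9))
})

test_that("curves compile to per-bin mean and sample SD across samples", {
  single <- compile_curves(list(fake_curve(c(5, 6, 7))))
  expect_equal(single$mean_um, c(5, 6, 7))
  expect_equal(single$sd_um, c(0, 0, 0))

  twin <- compile_curves(list(fake_curve(c(5, 6, 7)), fake_curve(c(5, 6, 7))))
  expect_equal(twin$sd_um, c(0, 0, 0))

  three <- compile_curves(list(fake_curve(c(6, 6, 6)), fake_curve(c(8, 8, 8)),
                               fake_curve(c(10, 10, 10))))
  expect_equal(three$mean_um, c(8, 8, 8))
  expect_equal(three$sd_um, c(2, 2, 2))   # sample SD of {6, 8, 10}

  expect_error(compile_curves(list(fake_curve(1:3), fake_curve(1:4))),
               "binning")
  expect_error(compile_curves(list()), "at least one")
})

test_that("degenerate masks are rejected", {
  sh <- disk_field(function(x, y) 0 * x, function(x, y) 0 * y,
                   n = 20, psz = 1, r_um = 3)
  expect_error(rms_length_error(sh, n_pairs = 100, bin_width = 50),
               "bin width")
})
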