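test_that("preprocess converts, downsamples below the size cap and normalizes", {
  img <- matrix(runif(4000 * 3000, 0.2, 0.8), 4000, 3000)
  out <- preprocess(img, pixel_size = 2)
  expect_equal(dim(out), c(1334, 1000))   # smallest integer factor (3)
  expect_equal(pixel_size(out), 6)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(range(out), c(0, 1))

  small <- matrix(runif(500 * 500), 500, 500)
  expect_equal(dim(preprocess(small, 1)), c(500, 500))

  rgb <- array(runif(60 * 50 * 3), c(60, 50, 3))
  expect_equal(dim(preprocess(rgb, 1)), c(60, 50))

  expect_warning(out0 <- preprocess(matrix(0.5, 20, 20), 1), "constant")
  expect_true(all(out0 == 0))
  expect_error(preprocess(matrix(numeric(0), 0, 0), 1))
})

test_that("similarity fit is exact on noiseless transforms", {
  p <- cbind(c(10, 200, 50, 400, 320), c(30, 60, 350, 220, 410))
  id <- fit_similarity(data.frame(x_pre = p[, 1], y_pre = p[, 2],
                                  x_post = p[, 1], y_post = p[, 2]))
  expect_equal(id$s, 1, tolerance = 1e-12)
  expect_equal(id$theta, 0, tolerance = 1e-12)
  expect_equal(id$t, c(0, 0), tolerance = 1e-10)

  sc <- fit_similarity(data.frame(x_pre = p[, 1], y_pre = p[, 2],
                                  x_post = 6.2 * p[, 1],
                                  y_post = 6.2 * p[, 2]))
  expect_equal(sc$s, 1 / 6.2, tolerance = 1e-12)
  expect_equal(estimate_expansion_factor(sc), 6.2, tolerance = 1e-12)
  expect_equal(max(abs(attr(sc, "residuals"))), 0, tolerance = 1e-9)

  expect_error(fit_similarity(data.frame(x_pre = c(1, 2), y_pre = c(1, 2),
                                         x_post = c(5, 5), y_post = c(5, 5))),
               "degenerate")
})

test_that("similarity fit recovers a known jittered transform within 1%", {
  set.seed(42)
  s_true <- 5.8; th <- 0.3; tr <- c(40, -25)
  p <- cbind(runif(5, 0, 1500), runif(5, 0, 1500))
  # post = forward expansion map of pre (scale s, rotation, translation)
  # plus 1 um Gaussian jitter
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  q <- s_true * p %*% t(R) + matrix(tr, 5, 2, byrow = TRUE) +
    matrix(rnorm(10, 0, 1), 5, 2)
  fit <- fit_similarity(data.frame(x_pre = p[, 1], y_pre = p[, 2],
                                   x_post = q[, 1], y_post = q[, 2]))
  expect_lt(abs(estimate_expansion_factor(fit) - s_true) / s_true, 0.01)
})

test_that("Procrustes matches a brute-force grid search on 3-point instances", {
  set.seed(7)
  for (rep in 1:5) {
    p <- cbind(runif(3, 0, 1000), runif(3, 0, 1000))
    q <- cbind(runif(3, 0, 1000), runif(3, 0, 1000))
    fit <- fit_similarity(data.frame(x_pre = p[, 1], y_pre = p[, 2],
                                     x_post = q[, 1], y_post = q[, 2]))
    ssd_of <- function(s, th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      m <- s * q %*% t(R)
      tt <- colMeans(p) - colMeans(m)
      sum((p - sweep(m, 2, -tt))^2)
    }
    ss <- seq(0.2, 3, length.out = 120)
    ths <- seq(-pi, pi, length.out = 240)
    grid_best <- min(outer(ss, ths, Vectorize(ssd_of)))
    fit_ssd <- sum(attr(fit, "residuals")^2)
    expect_lte(fit_ssd, grid_best + 1e-6)
  }
})

test_that("B-spline interpolation partitions unity and reproduces constants", {
  f <- bspline_field(c(800, 600), 100)
  f$cx[] <- 7.5; f$cy[] <- -3.25
  xs <- runif(200, 0, 800); ys <- runif(200, 0, 600)
  u <- eval_bspline(f, xs, ys)
  expect_equal(u[, 1], rep(7.5, 200), tolerance = 1e-12)
  expect_equal(u[, 2], rep(-3.25, 200), tolerance = 1e-12)
  expect_error(bspline_field(c(800, 600), 2000), "coarser")
})

test_that("landmark stage reproduces representable fields and nests across grids", {
  set.seed(11)
  extent <- c(1600, 1600)
  truth <- bspline_field(extent, 400)
  truth$cx[] <- rnorm(length(truth$cx), 0, 8)
  truth$cy[] <- rnorm(length(truth$cy), 0, 8)
  p <- cbind(runif(20, 100, 1500), runif(20, 100, 1500))
  targ <- eval_bspline(truth, p[, 1], p[, 2])

  fit_res <- function(spacing, lambda = 1e-8) {
    f <- expansionqc:::fit_bspline_landmarks(
      bspline_field(extent, spacing), p[, 1], p[, 2], targ,
      lambda = lambda)
    got <- eval_bspline(f, p[, 1], p[, 2])
    sqrt(mean((got - targ)^2))
  }
  # exact pairs from a field representable on the same grid -> ~0 residual
  expect_lt(fit_res(400), 1e-4)
  # nested-model property: residual non-increasing as the grid refines
  r <- sapply(c(800, 400, 200), fit_res)
  expect_true(all(diff(r) <= 1e-6))
})

test_that("deformation field of a zero B-spline is zero and needs a mask", {
  f <- bspline_field(c(400, 400), 100)
  mask <- matrix(TRUE, 20, 20)
  fld <- deformation_field(similarity_transform(), f, mask, pixel_size = 20)
  expect_equal(max(abs(fld$dx)), 0)
  expect_equal(max(abs(fld$dy)), 0)
  expect_error(deformation_field(similarity_transform(), f,
                                 matrix(FALSE, 20, 20), 20), "empty")
})

test_that("registration recovers a planted smooth field on a textured phantom", {
  ph <- make_phantom_pair(size = c(192, 192), pixel_size = 8, lef = 6,
                          amplitude = 20, wavelengths = c(800, 1200),
                          seed = 5)
  reg <- suppressWarnings(register_expansion(ph$pre, ph$post, ph$landmarks))
  # LEF from landmarks
  expect_lt(abs(coef(reg)["lef"] - 6) / 6, 0.01)
  # mean endpoint error under 25% of the planted amplitude
  tr <- ph$truth$field
  joint <- reg$mask & tr$mask
  err <- sqrt((reg$field$dx - tr$dx)^2 + (reg$field$dy - tr$dy)^2)
  expect_lt(mean(err[joint]), 0.25 * ph$truth$amplitude)
  # aligned post image identical scene: all-zero field when pre == post
  lm0 <- data.frame(x_pre = ph$landmarks$x_pre, y_pre = ph$landmarks$y_pre,
                    x_post = ph$landmarks$x_pre, y_post = ph$landmarks$y_pre)
  reg0 <- register_expansion(ph$pre, ph$pre, lm0, refine = FALSE)
  expect_lt(max(abs(reg0$field$dx), na.rm = TRUE), 1e-6)
})

test_that("point mapping matches closed forms and round-trips", {
  f0 <- bspline_field(c(1000, 1000), 200)
  pts <- cbind(c(100, 900, 450), c(250, 600, 800))
  # identity registration
  idm <- map_point(pts, similarity_transform(), f0)
  expect_equal(idm, pts, tolerance = 1e-9)
  # pure scale s: x_pre = x_post / s
  sc <- similarity_transform(1 / 6, 0, c(0, 0))
  expect_equal(map_point(pts * 6, sc, bspline_field(c(1000, 1000), 200)),
               pts, tolerance = 1e-9)
  # forward-then-inverse round trip on a non-trivial field within 0.1 um
  ph <- make_phantom_pair(size = c(96, 96), pixel_size = 16, lef = 6,
                          amplitude = 15, wavelengths = c(900, 1300),
                          seed = 9)
  reg <- suppressWarnings(register_expansion(ph$pre, ph$post, ph$landmarks,
                                             refine = FALSE))
  pre_pts <- as.matrix(ph$landmarks[, c("x_pre", "y_pre")])
  fwd <- predict(reg, pre_pts, direction = "pre_to_post")
  back <- predict(reg, fwd, direction = "post_to_pre")
  expect_lt(max(abs(back - pre_pts)), 0.1)
})

test_that("tissue mask isolates the dominant foreground component", {
  ph <- make_phantom_pair(size = c(128, 128), pixel_size = 16, seed = 2)
  m <- tissue_mask(ph$pre)
  truth <- ph$truth$mask
  jac <- sum(m & truth) / sum(m | truth)
  expect_gt(jac, 0.8)
})
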