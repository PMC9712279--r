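punch_row <- function(x, y, d = 2000, id = "p1", sid = "s1") {
  data.frame(punch_id = id, sample_id = sid, x_um = x, y_um = y,
             diameter_um = d)
}

test_that("punch placement under identity and pure scale matches geometry", {
  idp <- place_punches(punch_row(500, 700), similarity_transform())
  expect_equal(idp$x_pre_um, 500)
  expect_equal(idp$pre_diameter_um, 2000)

  sc <- similarity_transform(1 / 6, 0, c(0, 0))
  pp <- place_punches(punch_row(6000, 6000), sc)
  expect_equal(pp$x_pre_um, 1000)
  expect_equal(report_signif(pp$pre_diameter_um), 330)
  # commutes with the geometry calculus
  expect_equal(pp$pre_diameter_um, pre_expansion_diameter(2000, 6))
  expect_equal(pp$pre_volume_nL, cylinder_volume_nL(2000 / 6, 30))
  expect_equal(pp$cell_estimate,
               estimate_cells(cylinder_volume_nL(2000 / 6, 30)))
})

test_that("punch centres round-trip through a planted-field registration", {
  ph <- make_phantom_pair(size = c(96, 96), pixel_size = 16, lef = 6,
                          amplitude = 12, seed = 18)
  reg <- suppressWarnings(register_expansion(ph$pre, ph$post, ph$landmarks,
                                             refine = FALSE))
  pre_pts <- as.matrix(ph$landmarks[2:5, c("x_pre", "y_pre")])
  post_pts <- predict(reg, pre_pts, direction = "pre_to_post")
  placed <- place_punches(
    data.frame(punch_id = paste0("p", 1:4), sample_id = paste0("s", 1:4),
               x_um = post_pts[, 1], y_um = post_pts[, 2],
               diameter_um = 2000), reg)
  expect_lt(max(abs(cbind(placed$x_pre_um, placed$y_pre_um) - pre_pts)), 0.5)
})

test_that("z-scores standardize the cohort and respect missingness", {
  m <- matrix(c(10, 20), 1, dimnames = list("prA", c("s1", "s2")))
  am <- toy_am(m)
  p2 <- rbind(punch_row(0, 0, id = "p1", sid = "s1"),
              punch_row(10, 0, id = "p2", sid = "s2"))
  p2$x_pre_um <- p2$x_um; p2$y_pre_um <- p2$y_um
  p2$pre_diameter_um <- 330
  zm <- zscore_map(am, "prA", p2)
  expect_equal(zm$zscore, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # cohort z-scores have mean 0 and sample SD 1
  set.seed(9)
  m2 <- matrix(2^rnorm(12, 18, 1), 1,
               dimnames = list("prB", paste0("s", 1:12)))
  am2 <- toy_am(m2)
  p12 <- do.call(rbind, lapply(1:12, function(i)
    punch_row(i * 100, 0, id = paste0("p", i), sid = paste0("s", i))))
  p12$x_pre_um <- p12$x_um; p12$y_pre_um <- p12$y_um
  p12$pre_diameter_um <- 330
  z <- zscore_map(am2, "prB", p12)$zscore
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)

  # zero cohort SD warns and yields an all-zero map
  m3 <- matrix(c(7, 7, 7), 1, dimnames = list("prC", c("s1", "s2", "s3")))
  p3 <- do.call(rbind, lapply(1:3, function(i)
    punch_row(i, 0, id = paste0("p", i), sid = paste0("s", i))))
  p3$x_pre_um <- p3$x_um; p3$y_pre_um <- p3$y_um; p3$pre_diameter_um <- 330
  expect_warning(z3 <- zscore_map(toy_am(m3), "prC", p3), "zero cohort SD")
  expect_equal(z3$zscore, c(0, 0, 0))
})

test_that("suppressed genotype expression shows strongly negative z-scores", {
  # one group's punches near zero abundance -> strongly negative z there
  vals <- c(rep(1000, 6), rep(1, 6))
  m <- matrix(vals, 1, dimnames = list("prS", paste0("s", 1:12)))
  p <- do.call(rbind, lapply(1:12, function(i)
    punch_row(i, 0, id = paste0("p", i), sid = paste0("s", i))))
  p$x_pre_um <- p$x_um; p$y_pre_um <- p$y_um; p$pre_diameter_um <- 330
  z <- zscore_map(toy_am(m), "prS", p)$zscore
  expect_true(all(z[7:12] < 0))
  expect_true(all(z[1:6] > 0))
})

test_that("PNG rendering writes a file", {
  m <- matrix(c(10, 20, 30), 1, dimnames = list("prA", c("s1", "s2", "s3")))
  p <- do.call(rbind, lapply(1:3, function(i)
    punch_row(i * 200, 100, id = paste0("p", i), sid = paste0("s", i))))
  p$x_pre_um <- p$x_um; p$y_pre_um <- p$y_um; p$pre_diameter_um <- 330
  p$replicate <- c("a", "b", "c")
  f <- tempfile(fileext = ".png")
  zscore_map(toy_am(m), "prA", p, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
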