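test_that("phantom pairs are deterministic in the seed", {
  a <- make_phantom_pair(size = c(64, 64), pixel_size = 16, seed = 21)
  b <- make_phantom_pair(size = c(64, 64), pixel_size = 16, seed = 21)
  expect_identical(unclass(a$pre), unclass(b$pre))
  expect_identical(unclass(a$post), unclass(b$post))
  expect_identical(a$landmarks, b$landmarks)
  d <- make_phantom_pair(size = c(64, 64), pixel_size = 16, seed = 22)
  expect_false(identical(unclass(a$pre), unclass(d$pre)))
})

test_that("zero-amplitude phantoms are pure similarities recovered to 0.5%", {
  for (s in c(3, 4)) {
    lef <- runif(1, 5.5, 8)
    ph <- make_phantom_pair(size = c(96, 96), pixel_size = 16, lef = lef,
                            amplitude = 0, noise_sd = 0.005, seed = s)
    tf <- fit_similarity(ph$landmarks)
    expect_lt(abs(estimate_expansion_factor(tf) - lef) / lef, 0.005)
    expect_lt(max(abs(attr(tf, "residuals"))), 1e-6)
  }
})

test_that("planted landmark pairs are exact under the planted map", {
  ph <- make_phantom_pair(size = c(96, 96), pixel_size = 16, amplitude = 18,
                          seed = 6)
  tf <- ph$truth$similarity_post_to_pre
  aligned <- apply_similarity(tf, cbind(ph$landmarks$x_post,
                                        ph$landmarks$y_post))
  u <- ph$truth$u_fun(ph$landmarks$x_pre, ph$landmarks$y_pre)
  expect_equal(aligned,
               cbind(ph$landmarks$x_pre, ph$landmarks$y_pre) + u,
               tolerance = 1e-8)
  # planted perturbation has (numerically) no similarity component left
  pts <- expansionqc:::random_points_in_ellipse
  expect_lt(sqrt(sum(colMeans(
    ph$truth$u_fun(ph$landmarks$x_pre, ph$landmarks$y_pre))^2)), 3)
})

test_that("too-short perturbation wavelengths are rejected", {
  expect_error(make_phantom_pair(size = c(64, 64), pixel_size = 16,
                                 wavelengths = c(50), seed = 1),
               "alias")
})

test_that("the planted field's RMS curve is reproducible from the exported grid", {
  ph <- make_phantom_pair(size = c(128, 128), pixel_size = 16,
                          amplitude = 20, wavelengths = c(900, 1300),
                          seed = 14)
  # analytic sampling of the truth function vs the exported grid field:
  # same statistic, two evaluation paths
  grid_curve <- rms_length_error(ph$truth$field, n_pairs = 5e4, seed = 3)
  fx <- function(x, y) ph$truth$u_fun(x, y)[, 1]
  fy <- function(x, y) ph$truth$u_fun(x, y)[, 2]
  ext <- dim(ph$truth$mask) * 16
  oracle <- brute_force_rms(fx, fy, 5e5,
                            centre = ext[1] / 2, r_um = 0.36 * ext[1],
                            breaks = attr(grid_curve, "breaks"), seed = 99)
  ok <- !is.na(grid_curve$rms_um) & !is.na(oracle$rms_um) &
    grid_curve$n_pairs > 500
  rel <- abs(grid_curve$rms_um[ok] - oracle$rms_um[ok]) / oracle$rms_um[ok]
  expect_lt(stats::median(rel), 0.15)
})

test_that("study matrices realize the factorial punch design", {
  sm <- make_study_matrix(n_proteins = 300, seed = 4)
  meta <- sm$samples
  study <- meta[!meta$is_pooled_qc, ]
  expect_equal(nrow(study), 144)          # 12 mice x 12 punches
  expect_equal(length(unique(study$mouse)), 12)
  expect_equal(sum(meta$is_pooled_qc), 12)  # one pooled QC per batch
  counts <- table(study$region) / 12
  expect_equal(as.numeric(counts[c("V1", "CA1", "CA3", "DG", "MGC")]),
               c(3, 3, 3, 1, 2))
  # planted DEP sets disjoint from null proteins and from the markers
  tr <- attr(sm, "truth")$planted
  reg_sets <- split(tr$protein[tr$region != "all"],
                    tr$region[tr$region != "all"])
  expect_false(any(duplicated(unlist(reg_sets))))
  expect_true(all(c("APP", "PSEN1") %in% tr$protein[tr$region == "all"]))
  # determinism
  sm2 <- make_study_matrix(n_proteins = 300, seed = 4)
  expect_identical(sm$intensities, sm2$intensities)
})

test_that("planted genotype markers are recovered by DEP calling", {
  sm <- make_study_matrix(n_proteins = 400, marker_fc = 3, seed = 10)
  meta <- sm$samples
  ad <- meta$sample_id[meta$genotype == "AD"]
  wt <- meta$sample_id[meta$genotype == "WT"]
  dt <- call_deps(sm, ad, wt)
  expect_true(all(c("APP", "PSEN1") %in% dt$protein[dt$significant]))
  expect_true(all(dt$direction[dt$protein %in% c("APP", "PSEN1")] == "up"))
})

test_that("null study construction yields near-nominal false positives", {
  # zero planted effects and batch effects: AD vs WT is a true null
  sm <- make_study_matrix(n_proteins = 500, n_planted_per_region = 0,
                          marker_fc = 1, batch_sd = 0, region_sd = 0,
                          mouse_sd = 0, seed = 77)
  meta <- sm$samples
  dt <- call_deps(sm, meta$sample_id[meta$genotype == "AD"],
                  meta$sample_id[meta$genotype == "WT"])
  expect_lte(sum(dt$significant), 2)
})

test_that("intensity-dependent dropout hits low-abundance proteins hardest", {
  sm <- make_study_matrix(n_proteins = 600, dropout_midpoint = 18,
                          seed = 15)
  mu <- rowMeans(log2(sm$intensities), na.rm = TRUE)
  miss <- rowMeans(is.na(sm$intensities))
  ok <- is.finite(mu)
  mu <- mu[ok]; miss <- miss[ok]
  lo <- miss[mu < stats::quantile(mu, 0.2)]
  hi <- miss[mu > stats::quantile(mu, 0.8)]
  expect_gt(mean(lo), mean(hi))
})
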