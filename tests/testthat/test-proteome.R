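test_that("QC filter excludes samples below the protein-count threshold", {
  m <- matrix(c(10, 20, 30, 40, 50,
                NA, NA, NA, 44, 55,
                11, 21, 31, 41, 51,
                12, 22, 32, 42, 52), nrow = 5)
  am <- toy_am(m)
  res <- qc_filter(am, min_proteins = 3)
  expect_equal(res$report$excluded$sample_id, "s2")
  expect_equal(colnames(res$matrix$intensities), c("s1", "s3", "s4"))
  # min_proteins = 0 excludes nothing
  expect_equal(nrow(qc_filter(am, min_proteins = 0)$report$excluded), 0)
  # all excluded halts the pipeline
  expect_error(qc_filter(am, min_proteins = 6), "halt")
})

test_that("pooled-QC CV is SD/mean per protein, summarized by the median", {
  m <- cbind(a = c(10, 100), b = c(10, 100), c = c(10, 100),
             x = c(12, 105))
  am <- toy_am(m, pooled = c("a", "b", "c"))
  res <- qc_filter(am, min_proteins = 0, cv_max = 0.15)
  expect_equal(unname(res$report$pooled_cv), c(0, 0))
  expect_true(res$report$cv_pass)
  # a generated study matrix with qc_cv = 0.12 stays under the 0.15 bound
  sm <- make_study_matrix(n_proteins = 400, qc_cv = 0.12, seed = 8)
  rep2 <- qc_filter(sm, min_proteins = 0)$report
  expect_lt(rep2$median_cv, 0.15)
})

test_that("imputation writes 0.8 x global minimum into missing cells only", {
  m <- matrix(c(10, NA, 40, 25, NA, 100), 3)
  am <- toy_am(m)
  im <- impute_missing(am)
  expect_equal(im$intensities[is.na(m)], c(8, 8))
  expect_equal(im$intensities[!is.na(m)], m[!is.na(m)])
  # no missing -> identical
  full <- toy_am(matrix(1:6 * 1.0, 3))
  expect_equal(impute_missing(full)$intensities, full$intensities)
  expect_error(impute_missing(toy_am(matrix(NA_real_, 2, 2))), "missing")
})

test_that("fold change omits missing values and flags one-sided absence", {
  m <- rbind(p1 = c(20, 20, 10, 10),
             p2 = c(10, NA, 30, NA),
             p3 = c(NA, NA, 5, 6),
             p4 = c(7, 8, NA, NA))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  am <- toy_am(m)
  fc <- fold_change(am, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fc$fc[1], 2)
  expect_equal(fc$mean_a[2], 10)     # (10, missing) -> 10
  expect_equal(fc$mean_b[2], 30)
  expect_equal(fc$flag, c("ok", "ok", "absent_in_a", "absent_in_b"))
  expect_equal(fc$fc[3], 0)
  expect_equal(fc$fc[4], Inf)
  # identical groups give FC 1; reciprocity
  fc1 <- fold_change(am, c("a1", "a2"), c("a1", "a2"))
  expect_true(all(fc1$fc[fc1$flag == "ok"] == 1))
  fcr <- fold_change(am, c("b1", "b2"), c("a1", "a2"))
  ok <- fc$flag == "ok"
  expect_equal(fc$fc[ok] * fcr$fc[ok], rep(1, sum(ok)))
})

test_that("DEP calling is null on identical groups and recovers planted signal", {
  set.seed(5)
  m <- matrix(2^rnorm(50 * 8, 20, 0.3), 50, 8)
  colnames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  m[, 5:8] <- m[, 1:4]                   # identical groups
  am <- toy_am(m)
  dt <- call_deps(am, paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(sum(dt$significant), 0)

  am2 <- make_two_group_matrix(500, 6, planted = 1:25, fc = 4, cv = 0.2,
                               seed = 31)
  dt2 <- call_deps(am2, paste0("A", 1:6), paste0("B", 1:6))
  truth <- attr(am2, "truth")$planted
  expect_gte(mean(truth %in% dt2$protein[dt2$significant]), 0.9)
  expect_true(all(dt2$padj >= dt2$p, na.rm = TRUE))
  # significance flag definition
  chk <- dt2$tested & dt2$padj < 0.05 & (dt2$fc > 2 | dt2$fc < 0.5)
  expect_equal(dt2$significant, unname(ifelse(is.na(chk), FALSE, chk)))
})

test_that("proteins without two observations per group are untested, not errors", {
  m <- rbind(p1 = c(10, 12, 11, 13),
             p2 = c(10, NA, 11, 13))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  dt <- call_deps(toy_am(m), c("a1", "a2"), c("b1", "b2"))
  expect_true(dt$tested[1])
  expect_false(dt$tested[2])
  expect_true(is.na(dt$p[2]))
})

test_that("Welch test matches the brute-force formula and is symmetric", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.8)
  w <- welch_test(a, b)
  # frozen from the direct Welch-Satterthwaite formula on these vectors
  expect_equal(w$statistic, -2.150784, tolerance = 1e-6)
  expect_equal(w$df, 18.82354, tolerance = 1e-5)
  ws <- welch_test(b, a)
  expect_equal(ws$statistic, -w$statistic)
  expect_equal(ws$p.value, w$p.value)
  # zero-variance conventions
  expect_equal(welch_test(c(5, 5), c(5, 5))$p.value, 1)
  expect_equal(welch_test(c(5, 5), c(6, 6))$p.value, 0)
  # identical groups -> p = 1
  expect_equal(welch_test(a, a)$p.value, 1, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # monotone and never below raw
  set.seed(2)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlation clustermap is symmetric and groups duplicates", {
  set.seed(3)
  m <- matrix(2^rnorm(40 * 4, 18, 1), 40, 4,
              dimnames = list(paste0("pr", 1:40), paste0("s", 1:4)))
  m[, 4] <- m[, 1] * 1.0001              # near-duplicate of sample 1
  am <- toy_am(m)
  res <- correlation_clustermap(am, rownames(m))
  C <- res$correlation
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_gt(C["s1", "s4"], max(C["s1", "s2"], C["s1", "s3"]))
  mrg <- res$hclust$merge
  expect_true(any(apply(mrg, 1, function(r) setequal(r, c(-1, -4)))))
  # hand-computed 3-sample Pearson on log2 intensities
  m3 <- matrix(2^cbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1)), 3)
  colnames(m3) <- c("x", "y", "z")
  r3 <- correlation_clustermap(toy_am(m3), paste0("pr", 1:3))$correlation
  expect_equal(unname(r3["x", "y"]), 1)
  expect_equal(unname(r3["x", "z"]), -1)
})

test_that("4PL saturation fit recovers known parameters and degenerates safely", {
  set.seed(1)
  truth <- c(lower = 900, upper = 5100, midpoint = 2.5, slope = 1.8)
  xs <- seq(0.3, 20, length.out = 24)
  mu <- truth["lower"] + (truth["upper"] - truth["lower"]) /
    (1 + (truth["midpoint"] / xs)^truth["slope"])
  fit <- fit_saturation(xs, mu * (1 + rnorm(24, 0, 0.02)))
  expect_true(all(abs(coef(fit) - truth) / truth < 0.1))
  # monotone fitted curve for positive slope
  pr <- predict(fit, seq(0.3, 20, length.out = 100))
  expect_true(all(diff(pr) > 0))
  band <- predict(fit, xs, interval = "confidence")
  expect_true(all(band$lwr <= band$fit & band$fit <= band$upr))
  # flat data
  expect_warning(flat <- fit_saturation(1:6, rep(100, 6)), "flat")
  expect_equal(unname(coef(flat)["upper"]), unname(coef(flat)["lower"]))
  expect_error(fit_saturation(1:3, 1:3), "5 points")
})
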