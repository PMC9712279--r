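# Ground-truthed synthetic inputs: image phantoms related by a known
# similarity composed with a smooth, band-limited perturbation field, and
# proteomic matrices emulating a factorial punch study with planted fold
# changes, intensity-dependent dropout and pooled-QC replicates.  All
# generators are pure functions of (parameters, seed) and emit their
# planted truth alongside the data.

#' Synthetic pre/post expansion image pair with known distortion
#'
#' The pre-expansion image is a seeded blob/texture phantom with an
#' elliptical tissue mask.  The post-expansion image is the same scene
#' carried through a global similarity (scale = the planted linear
#' expansion factor) composed with a smooth band-limited perturbation:
#' a sum of sinusoidal displacement components with random directions and
#' phases, rescaled so the peak displacement magnitude equals
#' `amplitude`.  Landmark pairs are exact under the planted map, and the
#' true residual field is exported in the same form the registration
#' produces, so every downstream stage can be scored against truth.
#'
#' @param size pre-image dimensions, pixels (rows, cols).
#' @param pixel_size pre-image pixel size, um.
#' @param lef planted linear expansion factor (typical range 5.5--8).
#' @param theta planted rotation, radians.
#' @param translation planted translation of the pre -> post map, um.
#' @param amplitude peak perturbation displacement, um (pre-expansion
#'   scale); 0 gives a pure similarity.
#' @param wavelengths sinusoid wavelengths, um (each must be >= 4 pre
#'   pixels; longer wavelengths are smoother fields).
#' @param n_landmarks number of exact landmark pairs (>= 4; spread over
#'   the tissue by farthest-point sampling).
#' @param noise_sd Gaussian intensity noise added to both images.
#' @param n_blobs number of Gaussian texture blobs.
#' @param post_pixel_size post-image pixel size, um; defaults to
#'   `pixel_size * lef` (the expanded sample imaged at lower
#'   magnification), giving matched pixel counts.
#' @param seed RNG seed (same seed, same outputs, bit for bit).
#' @return object of class `phantom_pair`: `pre`, `post`
#'   ([gray_image()]s), `landmarks` (um), and `truth` (planted
#'   similarity in both directions, the dense residual
#'   [deformation_field()] on the pre grid, the closed-form field
#'   function `u_fun(x, y)`, and the tissue mask).
#' @export
make_phantom_pair <- function(size = c(256, 256), pixel_size = 8,
                              lef = 6, theta = 0.05,
                              translation = c(40, -25),
                              amplitude = 20,
                              wavelengths = c(900, 1300),
                              n_landmarks = 20, noise_sd = 0.01,
                              n_blobs = 140, post_pixel_size = NULL,
                              seed = 1) {
  check_number(lef, "lef", lower = 1)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(wavelengths, "wavelengths", lower = 0, strict_lower = TRUE)
  if (any(wavelengths < 4 * pixel_size))
    stop_invalid("perturbation wavelength below 4 pixels would alias; ",
                 "shortest allowed is ", 4 * pixel_size, " um")
  if (is.null(post_pixel_size)) post_pixel_size <- pixel_size * lef
  with_seed(seed, {
    ny <- size[1]; nx <- size[2]
    extent <- c(nx, ny) * pixel_size
    centre <- extent / 2
    ax <- 0.44 * extent[1]; ay <- 0.38 * extent[2]

    # closed-form perturbation: sum of plane-wave displacements
    n_w <- length(wavelengths)
    dirs <- matrix(rnorm(2 * n_w), n_w)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    disp <- matrix(rnorm(2 * n_w), n_w)
    disp <- disp / sqrt(rowSums(disp^2))
    phases <- runif(n_w, 0, 2 * pi)
    amps <- rep(1, n_w)
    u_raw <- function(x, y) {
      ux <- numeric(length(x)); uy <- numeric(length(x))
      for (i in seq_len(n_w)) {
        ph <- sin(2 * pi * (dirs[i, 1] * x + dirs[i, 2] * y) /
                    wavelengths[i] + phases[i]) * amps[i]
        ux <- ux + disp[i, 1] * ph
        uy <- uy + disp[i, 2] * ph
      }
      cbind(ux, uy)
    }
    # project the similarity modes (uniform scale, rotation, translation)
    # out of the perturbation over the tissue ellipse, so the planted
    # similarity is exactly the best-fit similarity of the composite map
    # and the residual field is pure non-rigid distortion; then rescale
    # to the requested peak amplitude
    el_grid <- random_points_in_ellipse(4096, centre, c(ax, ay))
    sim_modes <- local({
      g <- u_raw(el_grid[, 1], el_grid[, 2])
      xt <- el_grid[, 1] - mean(el_grid[, 1])
      yt <- el_grid[, 2] - mean(el_grid[, 2])
      den <- sum(xt^2 + yt^2)
      list(mx = mean(el_grid[, 1]), my = mean(el_grid[, 2]),
           tx = mean(g[, 1]), ty = mean(g[, 2]),
           a = sum(xt * g[, 1] + yt * g[, 2]) / den,
           b = sum(xt * g[, 2] - yt * g[, 1]) / den)
    })
    u_proj <- function(x, y) {
      g <- u_raw(x, y)
      xt <- x - sim_modes$mx; yt <- y - sim_modes$my
      cbind(g[, 1] - (sim_modes$a * xt - sim_modes$b * yt + sim_modes$tx),
            g[, 2] - (sim_modes$b * xt + sim_modes$a * yt + sim_modes$ty))
    }
    scale_u <- if (amplitude > 0) {
      g <- u_proj(el_grid[, 1], el_grid[, 2])
      amplitude / max(sqrt(rowSums(g^2)))
    } else 0
    u_fun <- function(x, y) scale_u * u_proj(x, y)

    # analytic phantom intensity
    bl_xy <- random_points_in_ellipse(n_blobs, centre, 0.92 * c(ax, ay))
    bl_sigma <- runif(n_blobs, 2 * pixel_size, 8 * pixel_size)
    bl_amp <- runif(n_blobs, 0.15, 0.65) * sign(runif(n_blobs) - 0.25)
    scene <- function(x, y) {
      el <- ((x - centre[1]) / ax)^2 + ((y - centre[2]) / ay)^2
      tis <- plogis((1 - el) / 0.015)
      v <- rep(0.35, length(x))
      for (b in seq_len(n_blobs)) {
        d2 <- (x - bl_xy[b, 1])^2 + (y - bl_xy[b, 2])^2
        v <- v + bl_amp[b] * exp(-d2 / (2 * bl_sigma[b]^2))
      }
      0.06 + tis * pmin(pmax(v, 0), 1)
    }

    xs <- rep((seq_len(nx) - 1) * pixel_size, each = ny)
    ys <- rep((seq_len(ny) - 1) * pixel_size, times = nx)
    pre_mat <- matrix(scene(xs, ys), ny, nx)
    mask <- matrix(((xs - centre[1]) / ax)^2 + ((ys - centre[2]) / ay)^2 <= 1,
                   ny, nx)

    # planted similarity pre -> post, shifted so the post scene is in frame
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    corners <- rbind(c(0, 0), c(extent[1], 0), c(0, extent[2]), extent)
    cp <- lef * corners %*% t(R)
    margin <- 4 * post_pixel_size + lef * amplitude
    t_eff <- translation - apply(cp, 2, min) + margin
    fwd <- function(xy) lef * xy %*% t(R) + rep(t_eff, each = nrow(xy))
    post_extent <- apply(cp, 2, max) - apply(cp, 2, min) + 2 * margin
    npx <- ceiling(post_extent[1] / post_pixel_size)
    npy <- ceiling(post_extent[2] / post_pixel_size)

    # post image: pull every post pixel back through the planted map
    pxs <- rep((seq_len(npx) - 1) * post_pixel_size, each = npy)
    pys <- rep((seq_len(npy) - 1) * post_pixel_size, times = npx)
    Rt <- t(R)
    inv_rigid <- cbind(pxs - t_eff[1], pys - t_eff[2]) %*% R / lef
    x_cur <- inv_rigid
    for (it in 1:25) {   # invert x + u(x) = inv_rigid
      u <- u_fun(x_cur[, 1], x_cur[, 2])
      x_new <- inv_rigid - u
      if (max(abs(x_new - x_cur)) < 1e-6) { x_cur <- x_new; break }
      x_cur <- x_new
    }
    post_mat <- matrix(scene(x_cur[, 1], x_cur[, 2]), npy, npx)

    if (noise_sd > 0) {
      pre_mat <- pre_mat + rnorm(length(pre_mat), 0, noise_sd)
      post_mat <- post_mat + rnorm(length(post_mat), 0, noise_sd)
    }
    pre_img <- gray_image(normalize01(pre_mat), pixel_size)
    post_img <- gray_image(normalize01(post_mat), post_pixel_size)

    # exact landmarks, spread by farthest-point sampling in the mask
    cand <- random_points_in_ellipse(60 * n_landmarks, centre,
                                     0.85 * c(ax, ay))
    lp <- farthest_points(cand, n_landmarks)
    lq <- fwd(lp + u_fun(lp[, 1], lp[, 2]))
    landmarks <- data.frame(x_pre = lp[, 1], y_pre = lp[, 2],
                            x_post = lq[, 1], y_post = lq[, 2])

    tf_fwd <- list(s = lef, theta = theta, t = t_eff)
    tf_inv <- similarity_transform(
      1 / lef, -theta,
      as.vector(-cbind(t_eff[1], t_eff[2]) %*% R / lef))
    fld <- truth_field_on_grid(u_fun, mask, pixel_size)
    structure(list(pre = pre_img, post = post_img, landmarks = landmarks,
                   truth = list(similarity_pre_to_post = tf_fwd,
                                similarity_post_to_pre = tf_inv,
                                field = fld, u_fun = u_fun, mask = mask,
                                amplitude = amplitude,
                                wavelengths = wavelengths, lef = lef,
                                seed = seed)),
              class = "phantom_pair")
  })
}

normalize01 <- function(m) {
  r <- range(m)
  if (r[2] <= r[1]) return(array(0, dim(m)))
  pmin(pmax((m - r[1]) / (r[2] - r[1]), 0), 1)
}

random_points_in_ellipse <- function(n, centre, semi) {
  r <- sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  cbind(centre[1] + semi[1] * r * cos(a),
        centre[2] + semi[2] * r * sin(a))
}

# Greedy farthest-point (max-min) subsampling of candidate points.
farthest_points <- function(cand, n) {
  n <- min(n, nrow(cand))
  sel <- integer(n)
  sel[1] <- 1L
  d <- sqrt(rowSums((cand - matrix(cand[1, ], nrow(cand), 2,
                                   byrow = TRUE))^2))
  for (k in 2:n) {
    sel[k] <- which.max(d)
    dk <- sqrt(rowSums((cand - matrix(cand[sel[k], ], nrow(cand), 2,
                                      byrow = TRUE))^2))
    d <- pmin(d, dk)
  }
  cand[sel, , drop = FALSE]
}

# Evaluate a closed-form displacement function on the pre grid -> the
# deformation-field container used by the distortion statistics.
truth_field_on_grid <- function(u_fun, mask, pixel_size) {
  ny <- nrow(mask)
  pix <- which(mask)
  xs <- ((pix - 1L) %/% ny) * pixel_size
  ys <- ((pix - 1L) %% ny) * pixel_size
  u <- u_fun(xs, ys)
  dx <- matrix(NA_real_, ny, ncol(mask)); dy <- dx
  dx[pix] <- u[, 1]; dy[pix] <- u[, 2]
  structure(list(dx = dx, dy = dy, mask = mask, pixel_size = pixel_size),
            class = "deformation_field")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(
    "<phantom_pair> planted LEF %.3g, rotation %.3g rad, perturbation %.3g um (wavelengths %s um)\n",
    x$truth$lef, x$truth$similarity_pre_to_post$theta, x$truth$amplitude,
    paste(x$truth$wavelengths, collapse = "/")))
  cat("  pre: "); print(x$pre)
  cat("  post:"); print(x$post)
  invisible(x)
}

#' Synthetic two-group abundance matrix with planted fold changes
#'
#' Log-normal baseline intensities with a planted multiplicative effect
#' in group A for a chosen protein subset; the simple two-group design
#' used to calibrate differential-expression calling.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group samples per group (groups `A` and `B`).
#' @param planted integer indices (or protein names) receiving the fold
#'   change in group A; empty for a null experiment.
#' @param fc planted fold change (> 0).
#' @param cv within-group coefficient of variation of intensities.
#' @param baseline_mean,baseline_sd mean and SD of per-protein baseline
#'   log2 intensity.
#' @param dropout_rate fraction of entries removed completely at random
#'   (default 0: complete matrix).
#' @param seed RNG seed.
#' @return an [abundance_matrix()] with metadata column `group` and
#'   attribute `truth` (planted protein ids and fold change).
#' @export
make_two_group_matrix <- function(n_proteins = 1000, n_per_group = 6,
                                  planted = integer(0), fc = 4, cv = 0.2,
                                  baseline_mean = 20, baseline_sd = 1.5,
                                  dropout_rate = 0, seed = 1) {
  check_number(fc, "fc", lower = 0, strict_lower = TRUE)
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    if (is.character(planted)) planted <- match(planted, prot)
    mu <- rnorm(n_proteins, baseline_mean, baseline_sd)
    sd_log2 <- sqrt(log1p(cv^2)) / log(2)
    n <- 2 * n_per_group
    log2x <- matrix(rnorm(n_proteins * n, mean = mu, sd = sd_log2),
                    n_proteins, n)
    if (length(planted))
      log2x[planted, seq_len(n_per_group)] <-
        log2x[planted, seq_len(n_per_group)] + log2(fc)
    x <- 2^log2x
    if (dropout_rate > 0)
      x[runif(length(x)) < dropout_rate] <- NA
    rownames(x) <- prot
    colnames(x) <- c(paste0("A", seq_len(n_per_group)),
                     paste0("B", seq_len(n_per_group)))
    am <- abundance_matrix(x, data.frame(
      sample_id = colnames(x),
      group = rep(c("A", "B"), each = n_per_group)))
    attr(am, "truth") <- list(planted = prot[planted], fc = fc)
    am
  })
}

#' Synthetic punch study matrix emulating the factorial brain design
#'
#' Generates the full punch-level design: 2 genotypes (AD/WT) x 2 ages
#' (young/old) x `n_mice_per_group` mice, with punches per slice V1 x3,
#' CA1 x3, CA3 x3, DG x1, MGC x2 (144 samples at the defaults), one
#' batch per mouse and one pooled-QC sample per batch.  Per-protein
#' log-normal baselines receive region, mouse and batch effects; planted
#' differentially expressed proteins multiply the mean by `planted_fc`
#' in AD samples of chosen regions, and genotype marker proteins (named
#' `APP` and `PSEN1`, mimicking the transgenic construct) are shifted in
#' all AD samples.  Missingness follows an intensity-dependent logistic
#' dropout; pooled-QC samples are drawn around the grand mean with a
#' target coefficient of variation `qc_cv`.
#'
#' @param n_proteins number of proteins (default 2000; set 6215 to
#'   emulate the full matrix).
#' @param n_mice_per_group mice per genotype x age cell (default 3).
#' @param punches_per_region named integer vector of punches per slice.
#' @param n_planted_per_region planted DEPs per region (AD effect).
#' @param planted_fc fold change of planted DEPs (> 0).
#' @param marker_fc fold change of the genotype markers in AD (> 0).
#' @param cv within-group coefficient of variation.
#' @param region_sd,mouse_sd,batch_sd SDs (log2) of region, mouse and
#'   batch effects.
#' @param dropout_midpoint,dropout_slope logistic dropout in log2
#'   intensity: `P(missing) = plogis(slope * (midpoint - log2 x))`.
#' @param qc_cv target CV of pooled-QC samples (default 0.12).
#' @param baseline_mean,baseline_sd baseline log2 intensity distribution.
#' @param seed RNG seed.
#' @return an [abundance_matrix()] with metadata columns `genotype`,
#'   `age`, `region`, `replicate`, `mouse`, `batch`, `is_pooled_qc`, and
#'   attribute `truth` listing every planted effect.
#' @export
make_study_matrix <- function(n_proteins = 2000, n_mice_per_group = 3,
                              punches_per_region = c(V1 = 3, CA1 = 3,
                                                     CA3 = 3, DG = 1,
                                                     MGC = 2),
                              n_planted_per_region = 8, planted_fc = 4,
                              marker_fc = 3, cv = 0.2, region_sd = 0.5,
                              mouse_sd = 0.2, batch_sd = 0.15,
                              dropout_midpoint = 16, dropout_slope = 1.2,
                              qc_cv = 0.12, baseline_mean = 20,
                              baseline_sd = 1.5, seed = 1) {
  check_number(planted_fc, "planted_fc", lower = 0, strict_lower = TRUE)
  check_number(marker_fc, "marker_fc", lower = 0, strict_lower = TRUE)
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    markers <- c("APP", "PSEN1")
    prot[seq_along(markers)] <- markers
    regions <- names(punches_per_region)

    mice <- expand.grid(idx = seq_len(n_mice_per_group),
                        age = c("young", "old"),
                        genotype = c("WT", "AD"),
                        stringsAsFactors = FALSE)
    mice$mouse <- sprintf("%s_%s_%d", mice$genotype, mice$age, mice$idx)
    mice$batch <- sprintf("B%02d", seq_len(nrow(mice)))

    samp <- do.call(rbind, lapply(seq_len(nrow(mice)), function(m) {
      do.call(rbind, lapply(regions, function(r) {
        reps <- letters[seq_len(punches_per_region[[r]])]
        data.frame(mouse = mice$mouse[m], genotype = mice$genotype[m],
                   age = mice$age[m], batch = mice$batch[m], region = r,
                   replicate = reps,
                   sample_id = sprintf("%s_%s_%s", mice$mouse[m], r, reps),
                   is_pooled_qc = FALSE, stringsAsFactors = FALSE)
      }))
    }))

    mu <- rnorm(n_proteins, baseline_mean, baseline_sd)
    reg_eff <- matrix(rnorm(n_proteins * length(regions), 0, region_sd),
                      n_proteins, dimnames = list(prot, regions))
    mouse_eff <- matrix(rnorm(n_proteins * nrow(mice), 0, mouse_sd),
                        n_proteins, dimnames = list(prot, mice$mouse))
    batch_eff <- matrix(rnorm(n_proteins * nrow(mice), 0, batch_sd),
                        n_proteins, dimnames = list(prot, mice$batch))

    # planted AD effects: per-region DEP sets, disjoint from the markers
    pool <- setdiff(prot, markers)
    planted <- do.call(rbind, lapply(regions, function(r) {
      if (n_planted_per_region < 1) return(NULL)
      pick <- sample(pool, n_planted_per_region)
      pool <<- setdiff(pool, pick)
      data.frame(protein = pick, region = r, genotype = "AD",
                 log2fc = log2(planted_fc))
    }))
    if (is.null(planted))
      planted <- data.frame(protein = character(0), region = character(0),
                            genotype = character(0), log2fc = numeric(0))
    planted <- rbind(planted,
                     data.frame(protein = rep(markers, each = 1),
                                region = "all", genotype = "AD",
                                log2fc = log2(marker_fc)))

    sd_log2 <- sqrt(log1p(cv^2)) / log(2)
    mean_log2 <- sapply(seq_len(nrow(samp)), function(k) {
      m <- mu + reg_eff[, samp$region[k]] + mouse_eff[, samp$mouse[k]] +
        batch_eff[, samp$batch[k]]
      if (samp$genotype[k] == "AD") {
        hit <- planted$protein[planted$region %in% c(samp$region[k], "all")]
        m[match(hit, prot)] <- m[match(hit, prot)] +
          planted$log2fc[planted$region %in% c(samp$region[k], "all")]
      }
      m
    })
    log2x <- mean_log2 + rnorm(length(mean_log2), 0, sd_log2)
    x <- 2^log2x
    rownames(x) <- prot; colnames(x) <- samp$sample_id

    # pooled QC: grand mean per protein with target CV, one per batch
    grand <- rowMeans(x)
    sd_ln_qc <- sqrt(log1p(qc_cv^2))
    qc <- sapply(mice$batch, function(b)
      grand * exp(rnorm(n_proteins, -sd_ln_qc^2 / 2, sd_ln_qc)))
    colnames(qc) <- paste0("QC_", mice$batch)
    qc_samp <- data.frame(mouse = NA, genotype = "pooled", age = "pooled",
                          batch = mice$batch, region = "pooled",
                          replicate = "qc",
                          sample_id = colnames(qc), is_pooled_qc = TRUE,
                          stringsAsFactors = FALSE)

    full <- cbind(x, qc)
    meta <- rbind(samp, qc_samp)

    # intensity-dependent dropout
    p_miss <- plogis(dropout_slope * (dropout_midpoint - log2(full)))
    full[runif(length(full)) < p_miss] <- NA

    am <- abundance_matrix(full, meta)
    attr(am, "truth") <- list(planted = planted, params = list(
      planted_fc = planted_fc, marker_fc = marker_fc, cv = cv,
      qc_cv = qc_cv, dropout_midpoint = dropout_midpoint,
      dropout_slope = dropout_slope, seed = seed))
    am
  })
}
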