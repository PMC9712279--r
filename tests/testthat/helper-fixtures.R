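# Shared fixtures: analytic deformation fields on simple masks, and an
# independent brute-force RMS oracle used to cross-check the package's
# sampled statistic.

# Deformation field from closed-form displacement functions on a disk
# mask of radius `r_um` centred in a square grid.
disk_field <- function(fx, fy, n = 200, psz = 10, r_um = 900) {
  c0 <- (n - 1) * psz / 2
  xs <- rep((seq_len(n) - 1) * psz, each = n)
  ys <- rep((seq_len(n) - 1) * psz, times = n)
  mask <- matrix((xs - c0)^2 + (ys - c0)^2 <= r_um^2, n, n)
  dx <- matrix(NA_real_, n, n)
  dy <- matrix(NA_real_, n, n)
  dx[mask] <- fx(xs[mask], ys[mask])
  dy[mask] <- fy(xs[mask], ys[mask])
  structure(list(dx = dx, dy = dy, mask = mask, pixel_size = psz),
            class = "deformation_field")
}

# Independent Monte-Carlo oracle for the RMS length-error curve: direct
# uniform sampling in the analytic disk, analytic displacements, plain
# loop-free binning.  Deliberately avoids every code path of
# rms_length_error().
brute_force_rms <- function(fx, fy, n_pairs, centre, r_um, breaks,
                            seed) {
  set.seed(seed)
  rpt <- function(n) {
    r <- r_um * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
    cbind(centre + r * cos(a), centre + r * sin(a))
  }
  p1 <- rpt(n_pairs); p2 <- rpt(n_pairs)
  L <- sqrt(rowSums((p1 - p2)^2))
  q1 <- p1 + cbind(fx(p1[, 1], p1[, 2]), fy(p1[, 1], p1[, 2]))
  q2 <- p2 + cbind(fx(p2[, 1], p2[, 2]), fy(p2[, 1], p2[, 2]))
  e <- abs(sqrt(rowSums((q1 - q2)^2)) - L)
  keep <- L > 0 & L <= max(breaks)
  b <- findInterval(L[keep], breaks, rightmost.closed = TRUE,
                    left.open = TRUE)
  rms <- sqrt(tapply(e[keep]^2, factor(b, levels = seq_len(length(breaks) - 1)),
                     mean))
  lr <- sqrt(tapply(L[keep]^2, factor(b, levels = seq_len(length(breaks) - 1)),
                    mean))
  list(rms_um = as.numeric(rms), rms_len = as.numeric(lr))
}

# Construct an rms_curve object directly from per-bin values (for
# compile_curves unit tests).
fake_curve <- function(values, bin_width = 50) {
  breaks <- seq(0, bin_width * length(values), by = bin_width)
  out <- data.frame(
    bin_center_um = (breaks[-1] + breaks[-length(breaks)]) / 2,
    rms_um = values,
    rms_pct = 100 * values / (breaks[-1] - bin_width / 2),
    n_pairs = rep(1000L, length(values)))
  structure(out, breaks = breaks, max_length = max(breaks),
            error = "length", class = c("rms_curve", "data.frame"))
}

# Small abundance matrix from a plain matrix with auto metadata.
toy_am <- function(m, pooled = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("pr", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  meta <- data.frame(sample_id = colnames(m),
                     is_pooled_qc = colnames(m) %in% (pooled %||% character(0)))
  abundance_matrix(m, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
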