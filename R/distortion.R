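# RMS length-measurement-error statistic: how much distances measured on
# the registered post-expansion image (after removing the global
# similarity) deviate from the same distances on the pre-expansion image,
# as a function of the measurement length.

#' RMS length measurement error of a deformation field
#'
#' Samples random point pairs uniformly within the tissue mask, compares
#' the true pre-expansion separation `L = |x1 - x2|` with the separation
#' measured after the residual deformation,
#' `L' = |(x1 + u(x1)) - (x2 + u(x2))|`, and reports the per-bin root mean
#' square of the length error `e = |L' - L|` in um and as a percentage of
#' the measurement distance.  The percentage divides the per-bin RMS
#' error by the per-bin RMS measurement length, so a pure residual scale
#' mismatch of `a` percent reads exactly `a` percent in every bin.
#'
#' @param field a [deformation_field()] (or an `expansion_registration`,
#'   whose field is used).
#' @param n_pairs number of point pairs with length below `max_length` to
#'   accumulate (default 1e5).
#' @param max_length largest measurement length considered, um
#'   (default 1500).
#' @param bin_width length-bin width, um (default 50).
#' @param seed RNG seed; identical seeds give identical curves.
#' @param error one of `"length"` (default, `|L' - L|`) or `"endpoint"`
#'   (RMS of the differential endpoint displacement
#'   `|u(x1) - u(x2)|`).
#' @return object of class `rms_curve`: data.frame with
#'   `bin_center_um`, `rms_um`, `rms_pct`, `n_pairs`; attributes `breaks`
#'   and `max_length`.
#' @export
rms_length_error <- function(field, n_pairs = 1e5, max_length = 1500,
                             bin_width = 50, seed = 1,
                             error = c("length", "endpoint")) {
  error <- match.arg(error)
  if (inherits(field, "expansion_registration")) field <- field$field
  if (!inherits(field, "deformation_field"))
    stop_invalid("'field' must be a deformation_field")
  if (!any(field$mask)) stop_invalid("tissue mask is empty")
  check_number(n_pairs, "n_pairs", lower = 1)
  check_number(max_length, "max_length", lower = 0, strict_lower = TRUE)
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  psz <- field$pixel_size
  ny <- nrow(field$mask)
  pix <- which(field$mask)
  ext <- (apply(which(field$mask, arr.ind = TRUE), 2, function(v)
    diff(range(v))) + 1) * psz
  if (max(ext) < bin_width)
    stop_invalid("tissue mask smaller than one bin width")
  breaks <- seq(0, max_length, by = bin_width)
  if (breaks[length(breaks)] < max_length)
    breaks <- c(breaks, max_length)
  nb <- length(breaks) - 1L

  sample_pts <- function(n) {
    k <- pix[sample.int(length(pix), n, replace = TRUE)]
    cbind(((k - 1L) %/% ny) * psz + runif(n, -0.5, 0.5) * psz,
          ((k - 1L) %% ny) * psz + runif(n, -0.5, 0.5) * psz)
  }
  L <- e <- numeric(0)
  with_seed(seed, {
    got <- 0L
    tries <- 0L
    while (got < n_pairs && tries < 200L) {
      tries <- tries + 1L
      n <- max(2048L, ceiling((n_pairs - got) * 1.6))
      p1 <- sample_pts(n); p2 <- sample_pts(n)
      u1x <- interp_bilinear_na(field$dx, p1[, 1], p1[, 2], psz)
      u1y <- interp_bilinear_na(field$dy, p1[, 1], p1[, 2], psz)
      u2x <- interp_bilinear_na(field$dx, p2[, 1], p2[, 2], psz)
      u2y <- interp_bilinear_na(field$dy, p2[, 1], p2[, 2], psz)
      len <- sqrt(rowSums((p1 - p2)^2))
      keep <- len > 0 & len <= max_length &
        !is.na(u1x) & !is.na(u1y) & !is.na(u2x) & !is.na(u2y)
      err <- if (error == "length") {
        abs(sqrt((p1[, 1] + u1x - p2[, 1] - u2x)^2 +
                 (p1[, 2] + u1y - p2[, 2] - u2y)^2) - len)
      } else {
        sqrt((u1x - u2x)^2 + (u1y - u2y)^2)
      }
      L <- c(L, len[keep]); e <- c(e, err[keep])
      got <- length(L)
    }
  })
  if (length(L) > n_pairs) { L <- L[seq_len(n_pairs)]; e <- e[seq_len(n_pairs)] }
  bin <- findInterval(L, breaks, rightmost.closed = TRUE, left.open = TRUE)
  rms_um <- rms_len <- rep(NA_real_, nb)
  npb <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    npb[b] <- sum(sel)
    if (npb[b] > 0L) {
      rms_um[b] <- sqrt(mean(e[sel]^2))
      rms_len[b] <- sqrt(mean(L[sel]^2))
    }
  }
  out <- data.frame(
    bin_center_um = (breaks[-1] + breaks[-length(breaks)]) / 2,
    rms_um = rms_um,
    rms_pct = 100 * rms_um / rms_len,
    n_pairs = npb
  )
  structure(out, breaks = breaks, max_length = max_length,
            error = error, class = c("rms_curve", "data.frame"))
}

#' @export
print.rms_curve <- function(x, ...) {
  cat(sprintf("RMS length-measurement-error curve (%d bins up to %g um, %d pairs)\n",
              nrow(x), attr(x, "max_length"), sum(x$n_pairs)))
  ok <- !is.na(x$rms_pct)
  if (any(ok))
    cat(sprintf("  mean over bins: %.3g um (%.3g%% of measurement distance); plateau (last bin): %.3g%%\n",
                mean(x$rms_um[ok]), mean(x$rms_pct[ok]),
                x$rms_pct[max(which(ok))]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Compile RMS curves across samples into a mean +/- SD curve
#'
#' @param curves list of [rms_length_error()] results with identical
#'   binning.
#' @return object of class `compiled_rms_curve`: data.frame with
#'   `bin_center_um`, per-bin `mean_um`, `sd_um`, `mean_pct`, `sd_pct`
#'   and `n_samples`.  Bins not populated in every sample are dropped.
#' @export
compile_curves <- function(curves) {
  if (!length(curves)) stop_invalid("at least one curve required")
  if (inherits(curves, "rms_curve")) curves <- list(curves)
  brk <- attr(curves[[1]], "breaks")
  for (cv in curves) {
    if (!inherits(cv, "rms_curve")) stop_invalid("all inputs must be rms_curve")
    if (!isTRUE(all.equal(attr(cv, "breaks"), brk)))
      stop_invalid("curves have mismatched binning")
  }
  um <- sapply(curves, `[[`, "rms_um")
  pct <- sapply(curves, `[[`, "rms_pct")
  um <- matrix(um, ncol = length(curves))
  pct <- matrix(pct, ncol = length(curves))
  keep <- rowSums(is.na(um)) == 0L
  sd0 <- function(v) if (length(v) > 1L) sd(v) else 0
  out <- data.frame(
    bin_center_um = curves[[1]]$bin_center_um[keep],
    mean_um = rowMeans(um[keep, , drop = FALSE]),
    sd_um = apply(um[keep, , drop = FALSE], 1, sd0),
    mean_pct = rowMeans(pct[keep, , drop = FALSE]),
    sd_pct = apply(pct[keep, , drop = FALSE], 1, sd0),
    n_samples = length(curves)
  )
  structure(out, breaks = brk, class = c("compiled_rms_curve", "data.frame"))
}

#' @export
print.compiled_rms_curve <- function(x, ...) {
  cat(sprintf("Compiled RMS curve over %d samples (%d shared bins)\n",
              x$n_samples[1], nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Plot an RMS length-measurement-error curve
#'
#' Compiled curves are drawn as a mean line with a +/- SD shaded band.
#'
#' @param x an `rms_curve` or `compiled_rms_curve`.
#' @param units `"um"` or `"pct"` (percent of measurement distance).
#' @param ... passed to [graphics::plot()].
#' @export
plot.compiled_rms_curve <- function(x, units = c("um", "pct"), ...) {
  units <- match.arg(units)
  m <- if (units == "um") x$mean_um else x$mean_pct
  s <- if (units == "um") x$sd_um else x$sd_pct
  ylab <- if (units == "um") "RMS length error (um)"
          else "RMS length error (% of measurement distance)"
  plot(x$bin_center_um, m, type = "n", xlab = "measurement length (um)",
       ylab = ylab, ylim = range(0, m + s), ...)
  polygon(c(x$bin_center_um, rev(x$bin_center_um)),
          c(m + s, rev(pmax(m - s, 0))),
          col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  lines(x$bin_center_um, m, col = "blue", lwd = 2)
  invisible(x)
}

#' @rdname plot.compiled_rms_curve
#' @export
plot.rms_curve <- function(x, units = c("um", "pct"), ...) {
  units <- match.arg(units)
  y <- if (units == "um") x$rms_um else x$rms_pct
  ylab <- if (units == "um") "RMS length error (um)"
          else "RMS length error (% of measurement distance)"
  plot(x$bin_center_um, y, type = "l", col = "blue", lwd = 2,
       xlab = "measurement length (um)", ylab = ylab, ...)
  invisible(x)
}

#' Write an RMS curve to a TSV file
#' @param curve an `rms_curve` or `compiled_rms_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rms_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
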