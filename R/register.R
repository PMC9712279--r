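# End-to-end registration of a post-expansion image onto its
# pre-expansion partner: similarity (Procrustes) alignment from landmark
# pairs, then cubic B-spline free-form deformation refinement.  The result
# is a classed fit carrying the transform, the control lattice, and the
# dense deformation vector field on the pre grid.

#' Register a post-expansion image onto the pre-expansion image
#'
#' The pre-expansion image is the static image; the post-expansion image
#' is the moving one.  The fit proceeds in the standard two steps for
#' expansion-isotropy analysis: a least-squares similarity transform from
#' paired landmarks (its scale gives the linear expansion factor), then a
#' landmark-initialized, intensity-refined cubic B-spline free-form
#' deformation.  The residual non-rigid displacement, expressed in
#' pre-expansion um on the pre pixel grid, is the deformation vector
#' field used for all downstream distortion statistics.
#'
#' @param pre pre-expansion [gray_image()] (already preprocessed).
#' @param post post-expansion [gray_image()].
#' @param landmarks data.frame with columns `x_pre`, `y_pre`, `x_post`,
#'   `y_post` in um.
#' @param mask optional logical tissue mask on the pre grid; computed with
#'   [tissue_mask()] when omitted.
#' @inheritParams fit_bspline
#' @return object of class `expansion_registration` with elements
#'   `similarity`, `bspline`, `field` (the [deformation_field()]),
#'   `landmarks`, `pre`, `post_aligned`, `mask`.
#' @seealso [deformation_field()], [map_point()], [rms_length_error()]
#' @export
register_expansion <- function(pre, post, landmarks, mask = NULL,
                               grid_spacing = NULL, lambda = 0.1,
                               refine = TRUE, levels = 3, max_iter = 40,
                               lambda_refine = 1e-6) {
  if (!inherits(pre, "gray_image") || !inherits(post, "gray_image"))
    stop_invalid("'pre' and 'post' must be gray_image objects (see preprocess())")
  tf <- fit_similarity(landmarks)
  aligned <- resample_to_pre(post, tf, pre)
  if (is.null(mask)) mask <- tissue_mask(pre)
  bsp <- fit_bspline(pre, aligned, landmarks, tf,
                     grid_spacing = grid_spacing, lambda = lambda,
                     refine = refine, mask = mask, levels = levels,
                     max_iter = max_iter, lambda_refine = lambda_refine)
  fld <- deformation_field(tf, bsp, mask, pixel_size = pixel_size(pre))
  structure(list(similarity = tf, bspline = bsp, field = fld,
                 landmarks = landmarks, pre = pre, post_aligned = aligned,
                 mask = mask),
            class = "expansion_registration")
}

#' @export
print.expansion_registration <- function(x, ...) {
  cat("Expansion registration (similarity + B-spline FFD)\n")
  cat(sprintf("  linear expansion factor (LEF): %.4g\n",
              estimate_expansion_factor(x$similarity)))
  cat(sprintf("  rotation %.4g rad, translation (%.4g, %.4g) um\n",
              x$similarity$theta, x$similarity$t[1], x$similarity$t[2]))
  cat(sprintf("  landmarks: %d pairs, similarity RMSE %.3g um\n",
              nrow(x$landmarks), attr(x$similarity, "rmse")))
  u <- sqrt(x$field$dx^2 + x$field$dy^2)
  cat(sprintf("  deformation field: mean |u| %.3g um, max |u| %.3g um on %d mask pixels\n",
              mean(u, na.rm = TRUE), max(u, na.rm = TRUE), sum(x$mask)))
  if (!isTRUE(attr(x$bspline, "converged")))
    cat("  note: intensity refinement did not converge\n")
  invisible(x)
}

#' @export
coef.expansion_registration <- function(object, ...) {
  c(scale = object$similarity$s,
    theta = object$similarity$theta,
    tx = object$similarity$t[1], ty = object$similarity$t[2],
    lef = estimate_expansion_factor(object$similarity))
}

#' @export
residuals.expansion_registration <- function(object, ...) {
  attr(object$similarity, "residuals")
}

#' Map points between post- and pre-expansion coordinates
#'
#' `predict()` on a registration maps point coordinates.  The
#' `"post_to_pre"` direction applies the similarity and then removes the
#' non-rigid residual by fixed-point iteration (the deformation field is
#' defined on the pre grid); `"pre_to_post"` is the closed-form forward
#' map.
#'
#' @param object an `expansion_registration`.
#' @param newdata n x 2 matrix or data.frame of (x, y) um.
#' @param direction `"post_to_pre"` (default) or `"pre_to_post"`.
#' @param tol fixed-point tolerance, um.
#' @param max_iter fixed-point iteration cap.
#' @param ... unused.
#' @return n x 2 matrix of mapped coordinates, um.
#' @export
predict.expansion_registration <- function(object, newdata,
                                           direction = c("post_to_pre",
                                                         "pre_to_post"),
                                           tol = 0.1, max_iter = 50, ...) {
  direction <- match.arg(direction)
  xy <- rbind2cols(as.matrix(newdata))
  if (direction == "pre_to_post") {
    u <- eval_bspline(object$bspline, xy[, 1], xy[, 2])
    return(apply_similarity(invert_similarity(object$similarity), xy + u))
  }
  map_point(xy, object$similarity, object$bspline,
            tol = tol, max_iter = max_iter)
}

#' Map post-expansion points into pre-expansion coordinates
#'
#' Applies the similarity transform, then solves for the pre-expansion
#' location `x` satisfying `x + u(x) = T(x_post)` by fixed-point
#' iteration (`u` is the non-rigid residual on the pre grid).
#'
#' @param x_post n x 2 matrix (or length-2 vector) of post coordinates, um.
#' @param transform [similarity_transform()] (post -> pre).
#' @param bspline [bspline_field()] on the pre grid.
#' @param tol convergence tolerance, um (default 0.1).
#' @param max_iter iteration cap (default 50).
#' @return n x 2 matrix of pre-expansion coordinates, um.
#' @export
map_point <- function(x_post, transform, bspline, tol = 0.1, max_iter = 50) {
  xy <- rbind2cols(x_post)
  target <- apply_similarity(transform, xy)
  x <- target
  for (it in seq_len(max_iter)) {
    u <- eval_bspline(bspline, x[, 1], x[, 2])
    x_new <- target - u
    dimnames(x_new) <- NULL
    delta <- sqrt(rowSums((x_new - x)^2))
    x <- x_new
    if (max(delta) < tol) return(x)
  }
  bad <- which(delta >= tol)
  stop_invalid(sprintf(
    "point inversion did not converge for point %d at post (%.6g, %.6g) um",
    bad[1], xy[bad[1], 1], xy[bad[1], 2]))
}

#' Dense deformation vector field on the pre-expansion grid
#'
#' Evaluates the residual non-rigid displacement `u(x)` (um, after
#' removing the global similarity) at every pre-image pixel inside the
#' tissue mask.
#'
#' @param transform [similarity_transform()] (post -> pre); kept for
#'   bookkeeping of the direction convention.
#' @param bspline [bspline_field()].
#' @param mask logical tissue mask (pre grid).
#' @param pixel_size pre-image pixel size, um.
#' @return object of class `deformation_field`: matrices `dx`, `dy`
#'   (um, `NA` off the mask), the `mask`, and `pixel_size`.
#' @export
deformation_field <- function(transform, bspline, mask, pixel_size) {
  if (!any(mask)) stop_invalid("tissue mask is empty")
  ny <- nrow(mask); nx <- ncol(mask)
  pix <- which(mask)
  xs <- ((pix - 1L) %/% ny) * pixel_size
  ys <- ((pix - 1L) %% ny) * pixel_size
  u <- eval_bspline(bspline, xs, ys)
  dx <- matrix(NA_real_, ny, nx); dy <- matrix(NA_real_, ny, nx)
  dx[pix] <- u[, 1]; dy[pix] <- u[, 2]
  structure(list(dx = dx, dy = dy, mask = mask, pixel_size = pixel_size),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  u <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf(
    "<deformation_field> %d x %d grid (%.4g um/px), %d mask px, mean |u| %.3g um, max %.3g um\n",
    nrow(x$dx), ncol(x$dx), x$pixel_size, sum(x$mask),
    mean(u, na.rm = TRUE), max(u, na.rm = TRUE)))
  invisible(x)
}

#' Plot a registration: overlay or deformation vector field
#'
#' `type = "overlay"` shows the pre image in green and the registered
#' post image in magenta (grey where they agree); `type = "field"` draws
#' the deformation vector field as arrows over the pre image.
#'
#' @param x an `expansion_registration`.
#' @param type `"overlay"` or `"field"`.
#' @param arrow_step arrow grid stride in pixels for `type = "field"`.
#' @param arrow_scale magnification applied to displacement arrows.
#' @param ... unused.
#' @export
plot.expansion_registration <- function(x, type = c("overlay", "field"),
                                        arrow_step = 16, arrow_scale = 3,
                                        ...) {
  type <- match.arg(type)
  if (type == "overlay") {
    rgb_arr <- overlay_array(x)
    op <- par(mar = c(0, 0, 2, 0)); on.exit(par(op))
    plot(0, 0, type = "n", xlim = c(0, 1), ylim = c(0, 1), axes = FALSE,
         xlab = "", ylab = "", asp = nrow(x$pre) / ncol(x$pre))
    rasterImage(rgb_arr, 0, 0, 1, 1)
    title("pre (green) / registered post (magenta)")
  } else {
    fld <- x$field
    psz <- fld$pixel_size
    image(x = (seq_len(ncol(x$pre)) - 1) * psz,
          y = (seq_len(nrow(x$pre)) - 1) * psz,
          z = t(unclass(x$pre))[, rev(seq_len(nrow(x$pre)))],
          col = gray(seq(0, 1, length.out = 64)), xlab = "x (um)",
          ylab = "y (um)", useRaster = TRUE)
    ny <- nrow(fld$dx)
    pick <- which(fld$mask &
                    (row(fld$dx) %% arrow_step == 0) &
                    (col(fld$dx) %% arrow_step == 0))
    xs <- ((pick - 1L) %/% ny) * psz
    ys <- ((pick - 1L) %% ny) * psz
    ymax <- (ny - 1) * psz
    arrows(xs, ymax - ys, xs + arrow_scale * fld$dx[pick],
           ymax - (ys + arrow_scale * fld$dy[pick]),
           length = 0.04, col = "red")
    title("deformation vector field")
  }
  invisible(x)
}

# Two-channel pseudo-colour overlay (pre green, registered post magenta).
overlay_array <- function(reg) {
  pre <- unclass(reg$pre); attr(pre, "pixel_size") <- NULL
  post <- unclass(reg$post_aligned); attr(post, "pixel_size") <- NULL
  post <- pmin(pmax(post, 0), 1)
  arr <- array(0, c(nrow(pre), ncol(pre), 3))
  arr[, , 1] <- post
  arr[, , 2] <- pre
  arr[, , 3] <- post
  arr
}

#' Write the registration overlay image to a PNG file
#' @param reg an `expansion_registration`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(reg, path) {
  png::writePNG(overlay_array(reg), path)
  invisible(path)
}
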