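# Cubic B-spline free-form deformation (FFD).  A displacement field on the
# pre-expansion grid is parameterized by displacements of a regular control
# lattice with spacing `spacing` um; the displacement at a point is the
# tensor-product cubic B-spline blend of the 4 x 4 surrounding control
# displacements (weights sum to 1, so a constant lattice gives a constant
# field).  The lattice carries one extra ring of controls on every side so
# the 4 x 4 support is defined over the whole image extent.

# Uniform cubic B-spline basis at fractional position t in [0, 1):
# n x 4 matrix of weights for the controls at cells -1, 0, 1, 2.
bspline_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - 3 * t + 3 * t2 - t3) / 6,
        (3 * t3 - 6 * t2 + 4) / 6,
        (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
        t3 / 6)
}

#' Construct an (initially zero) B-spline displacement field
#'
#' @param extent length-2 physical extent (x, y) covered by the field, um.
#' @param spacing control-point spacing, um (> 0, and no larger than the
#'   extent).
#' @return object of class `bspline_field`: control-point displacement
#'   matrices `cx`, `cy` (um, rows = lattice y, cols = lattice x),
#'   `spacing`, cell counts `ncell` and the covered `extent`.
#' @export
bspline_field <- function(extent, spacing) {
  check_number(extent, "extent", lower = 0, strict_lower = TRUE)
  check_number(spacing, "spacing", lower = 0, strict_lower = TRUE)
  if (length(extent) != 2L) stop_invalid("'extent' must have length 2")
  if (spacing > max(extent))
    stop_invalid("control-point spacing coarser than the image extent")
  ncell <- pmax(1L, ceiling(extent / spacing))
  dims <- ncell + 3L                      # one extra ring each side
  structure(list(
    cx = matrix(0, dims[2], dims[1]),
    cy = matrix(0, dims[2], dims[1]),
    spacing = spacing, ncell = ncell, extent = as.numeric(extent)
  ), class = "bspline_field")
}

#' @export
print.bspline_field <- function(x, ...) {
  cat(sprintf(
    "<bspline_field> %d x %d control points, spacing %.4g um, max |u| = %.3g um\n",
    nrow(x$cx), ncol(x$cx), x$spacing,
    max(abs(c(x$cx, x$cy)))))
  invisible(x)
}

# Tensor-product support of points (x, y): returns the 16 lattice indices
# and weights per point as n x 16 matrices.
bspline_support <- function(field, x, y) {
  sp <- field$spacing
  sx <- x / sp; sy <- y / sp
  cx <- pmin(pmax(floor(sx), 0), field$ncell[1] - 1L)
  cy <- pmin(pmax(floor(sy), 0), field$ncell[2] - 1L)
  wx <- bspline_weights(sx - cx)
  wy <- bspline_weights(sy - cy)
  nlat_y <- nrow(field$cx)
  idx <- matrix(0L, length(x), 16L)
  w <- matrix(0, length(x), 16L)
  k <- 0L
  for (m in 0:3) {           # lattice column (x direction)
    col <- cx + m + 1L       # 1-based lattice column
    for (l in 0:3) {         # lattice row (y direction)
      k <- k + 1L
      idx[, k] <- (col - 1L) * nlat_y + (cy + l + 1L)
      w[, k] <- wx[, m + 1L] * wy[, l + 1L]
    }
  }
  list(idx = idx, w = w)
}

#' Evaluate a B-spline displacement field at points
#'
#' @param field a [bspline_field()].
#' @param x,y point coordinates, um (vectors of equal length).
#' @return n x 2 matrix of displacements (ux, uy), um.
#' @export
eval_bspline <- function(field, x, y) {
  s <- bspline_support(field, x, y)
  ux <- rowSums(s$w * matrix(field$cx[s$idx], nrow(s$w)))
  uy <- rowSums(s$w * matrix(field$cy[s$idx], nrow(s$w)))
  cbind(ux, uy)
}

# Second-difference bending penalty matrix over the control lattice
# (applied independently to each displacement component):
# P = Dxx'Dxx + 2 Dxy'Dxy + Dyy'Dyy for plain lattice differences.
bending_penalty <- function(nlat_y, nlat_x) {
  n <- nlat_y * nlat_x
  id <- function(i, j) (j - 1L) * nlat_y + i
  rows <- list(); cnt <- 0L
  add <- function(ii, jj, coefs, offs_i, offs_j) {
    D <- matrix(0, length(ii) * length(jj), n)
    r <- 0L
    for (j in jj) for (i in ii) {
      r <- r + 1L
      for (k in seq_along(coefs))
        D[r, id(i + offs_i[k], j + offs_j[k])] <-
          D[r, id(i + offs_i[k], j + offs_j[k])] + coefs[k]
    }
    D
  }
  Dyy <- add(1:(nlat_y - 2L), 1:nlat_x, c(1, -2, 1), c(0, 1, 2), c(0, 0, 0))
  Dxx <- add(1:nlat_y, 1:(nlat_x - 2L), c(1, -2, 1), c(0, 0, 0), c(0, 1, 2))
  Dxy <- add(1:(nlat_y - 1L), 1:(nlat_x - 1L), c(1, -1, -1, 1),
             c(0, 1, 0, 1), c(0, 0, 1, 1))
  crossprod(Dxx) + 2 * crossprod(Dxy) + crossprod(Dyy)
}

# Landmark stage: least-squares control displacements reproducing the
# landmark residuals, with quadratic bending-energy regularization.
# targets: n x 2 matrix of required displacements at (x, y) in um.
fit_bspline_landmarks <- function(field, x, y, targets, lambda = 0.1) {
  s <- bspline_support(field, x, y)
  n_ctrl <- length(field$cx)
  W <- matrix(0, length(x), n_ctrl)
  for (k in seq_len(16L))
    W[cbind(seq_along(x), s$idx[, k])] <- W[cbind(seq_along(x), s$idx[, k])] + s$w[, k]
  P <- bending_penalty(nrow(field$cx), ncol(field$cx))
  A <- crossprod(W) + lambda * P + diag(1e-9, n_ctrl)
  sol <- solve(A, crossprod(W, targets))
  field$cx[] <- sol[, 1]
  field$cy[] <- sol[, 2]
  field
}

# Intensity refinement: coarse-to-fine damped Gauss-Newton
# (Levenberg-Marquardt) minimization of the masked mean squared intensity
# difference between the (fixed) pre image and the rigidly aligned post
# image warped through the current field, plus a small bending penalty
# keeping the lattice smooth.
refine_bspline_intensity <- function(field, pre, post_aligned, mask,
                                     levels = 3, max_iter = 40,
                                     lambda_refine = 1e-6, tol = 1e-6) {
  psz0 <- pixel_size(pre)
  I0 <- unclass(pre); attr(I0, "pixel_size") <- NULL
  J0 <- unclass(post_aligned); attr(J0, "pixel_size") <- NULL
  P <- bending_penalty(nrow(field$cx), ncol(field$cx))
  converged <- TRUE
  for (lev in seq(levels - 1, 0)) {
    f <- 2^lev
    if (f > 1) {
      I <- block_mean(I0, f); J <- block_mean(J0, f)
      M <- block_mean(mask * 1, f) > 0.5
    } else {
      I <- I0; J <- J0; M <- mask
    }
    psz <- psz0 * f
    res <- refine_level(field, I, J, M, psz, P,
                        max_iter = max_iter, lambda_refine = lambda_refine,
                        tol = tol)
    field <- res$field
    if (lev == 0) converged <- res$converged
  }
  attr(field, "converged") <- converged
  field
}

refine_level <- function(field, I, J, M, psz, P, max_iter, lambda_refine,
                         tol) {
  pix <- which(M)
  if (!length(pix)) return(list(field = field, converged = TRUE))
  ny <- nrow(I)
  xs <- ((pix - 1L) %/% ny) * psz
  ys <- ((pix - 1L) %% ny) * psz
  Iv <- I[pix]
  n <- length(pix)
  # image gradients of the moving image (per um, central differences)
  Jx <- J; Jx[] <- 0
  Jx[, 2:(ncol(J) - 1)] <- (J[, 3:ncol(J)] - J[, 1:(ncol(J) - 2)]) / (2 * psz)
  Jy <- J; Jy[] <- 0
  Jy[2:(ny - 1), ] <- (J[3:ny, ] - J[1:(ny - 2), ]) / (2 * psz)
  sup <- bspline_support(field, xs, ys)
  n_ctrl <- length(field$cx)
  # fixed sparse basis design matrix (n pixels x n_ctrl)
  B <- Matrix::sparseMatrix(i = rep(seq_len(n), 16L),
                            j = as.vector(sup$idx),
                            x = as.vector(sup$w),
                            dims = c(n, n_ctrl))
  energy <- function(cx, cy) {
    u <- cbind(rowSums(sup$w * matrix(cx[sup$idx], n)),
               rowSums(sup$w * matrix(cy[sup$idx], n)))
    d <- interp_bilinear(J, xs + u[, 1], ys + u[, 2], psz) - Iv
    pen <- sum((P %*% as.vector(cx)) * as.vector(cx)) +
           sum((P %*% as.vector(cy)) * as.vector(cy))
    list(E = mean(d * d) + lambda_refine * pen / n_ctrl, diff = d, u = u)
  }
  cx <- field$cx; cy <- field$cy
  e <- energy(cx, cy)
  mu <- NULL
  converged <- FALSE
  Pn <- lambda_refine / n_ctrl * P
  for (it in seq_len(max_iter)) {
    wx <- xs + e$u[, 1]; wy <- ys + e$u[, 2]
    gx_pix <- interp_bilinear(Jx, wx, wy, psz)
    gy_pix <- interp_bilinear(Jy, wx, wy, psz)
    Bx <- Matrix::Diagonal(x = gx_pix) %*% B   # row-scaled Jacobian blocks
    By <- Matrix::Diagonal(x = gy_pix) %*% B
    Axx <- as.matrix(Matrix::crossprod(Bx)) / n + Pn
    Ayy <- as.matrix(Matrix::crossprod(By)) / n + Pn
    Axy <- as.matrix(Matrix::crossprod(Bx, By)) / n
    gvec <- c(as.vector(Matrix::crossprod(Bx, e$diff)) / n +
                as.vector(Pn %*% as.vector(cx)),
              as.vector(Matrix::crossprod(By, e$diff)) / n +
                as.vector(Pn %*% as.vector(cy)))
    A <- rbind(cbind(Axx, Axy), cbind(t(Axy), Ayy))
    dg <- diag(A)
    if (is.null(mu)) mu <- 1e-3 * mean(dg)
    accepted <- FALSE
    for (lm_try in 1:12) {
      step <- tryCatch(solve(A + diag(mu + 1e-12, nrow(A)), gvec),
                       error = function(err) NULL)
      if (!is.null(step)) {
        cx2 <- cx - matrix(step[seq_len(n_ctrl)], nrow(cx))
        cy2 <- cy - matrix(step[n_ctrl + seq_len(n_ctrl)], nrow(cy))
        e2 <- energy(cx2, cy2)
        if (e2$E < e$E) { accepted <- TRUE; break }
      }
      mu <- mu * 4
    }
    if (!accepted) { converged <- TRUE; break }
    rel <- (e$E - e2$E) / max(e$E, 1e-12)
    cx <- cx2; cy <- cy2; e <- e2
    mu <- mu / 3
    if (rel < tol) { converged <- TRUE; break }
  }
  field$cx <- cx; field$cy <- cy
  list(field = field, converged = converged)
}

#' Fit a B-spline free-form deformation between aligned images
#'
#' Two-stage non-rigid refinement after rigid (similarity) alignment:
#' \enumerate{
#'   \item \emph{Landmark stage}: least-squares control-point
#'     displacements reproducing the landmark residuals left by the
#'     similarity transform, with a quadratic bending-energy penalty.
#'   \item \emph{Intensity refinement} (optional): coarse-to-fine
#'     minimization of the masked mean squared intensity difference by
#'     gradient descent on the control displacements, initialized from
#'     the landmark stage.
#' }
#'
#' @param pre pre-expansion [gray_image()] (static).
#' @param post_aligned post-expansion image already resampled through the
#'   similarity transform onto the pre grid ([resample_to_pre()]).
#' @param landmarks data.frame with `x_pre`, `y_pre`, `x_post`, `y_post`
#'   (um); >= 4 pairs required.
#' @param transform the fitted [similarity_transform()] (post -> pre),
#'   used to express landmark residuals in the pre frame.
#' @param grid_spacing control-point spacing, um; default 1/12 of the
#'   shorter pre-image side.
#' @param lambda bending-energy weight of the landmark stage.
#' @param refine run the intensity refinement stage (default `TRUE`).
#' @param mask logical tissue mask on the pre grid; default
#'   [tissue_mask()] of `pre`.
#' @param levels pyramid levels for the refinement.
#' @param max_iter gradient-descent iterations per level.
#' @param lambda_refine bending weight of the refinement stage (intensity
#'   units; the data term is a mean square of [0, 1] intensities).
#' @return a [bspline_field()] with attribute `converged`.
#' @export
fit_bspline <- function(pre, post_aligned, landmarks, transform,
                        grid_spacing = NULL, lambda = 0.1, refine = TRUE,
                        mask = NULL, levels = 3, max_iter = 40,
                        lambda_refine = 1e-6) {
  if (nrow(landmarks) < 4L)
    stop_invalid("non-rigid refinement requires >= 4 landmark pairs")
  extent <- c(ncol(pre), nrow(pre)) * pixel_size(pre)
  if (is.null(grid_spacing)) grid_spacing <- min(extent) / 12
  field <- bspline_field(extent, grid_spacing)
  # residual displacement at each pre landmark: where the rigidly aligned
  # post image places the feature, relative to the pre landmark
  aligned <- apply_similarity(transform, cbind(landmarks$x_post, landmarks$y_post))
  targets <- aligned - cbind(landmarks$x_pre, landmarks$y_pre)
  field <- fit_bspline_landmarks(field, landmarks$x_pre, landmarks$y_pre,
                                 targets, lambda = lambda)
  if (refine) {
    if (is.null(mask)) mask <- tissue_mask(pre)
    field <- refine_bspline_intensity(field, pre, post_aligned, mask,
                                      levels = levels, max_iter = max_iter,
                                      lambda_refine = lambda_refine)
    if (!isTRUE(attr(field, "converged")))
      warning("intensity refinement stopped before convergence")
  } else {
    attr(field, "converged") <- TRUE
  }
  field
}

#' Resample the post-expansion image into the pre-expansion frame
#'
#' Pulls the moving (post) image back through the inverse similarity so it
#' lives on the static (pre) pixel grid.
#'
#' @param post post-expansion [gray_image()].
#' @param transform [similarity_transform()] mapping post -> pre.
#' @param pre pre-expansion [gray_image()] providing the target grid.
#' @return [gray_image()] on the pre grid.
#' @export
resample_to_pre <- function(post, transform, pre) {
  psz <- pixel_size(pre)
  ny <- nrow(pre); nx <- ncol(pre)
  xs <- rep((seq_len(nx) - 1) * psz, each = ny)
  ys <- rep((seq_len(ny) - 1) * psz, times = nx)
  inv <- invert_similarity(transform)
  yz <- apply_similarity(inv, cbind(xs, ys))
  vals <- interp_bilinear(unclass(post), yz[, 1], yz[, 2], pixel_size(post))
  gray_image(matrix(vals, ny, nx), psz)
}
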