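# Landmark-guided similarity (Procrustes) registration.  The transform
# maps post-expansion coordinates onto the pre-expansion frame:
#   T(y) = s R(theta) y + t,  y in post um, T(y) in pre um.
# Because the fit maps post -> pre, the fitted scale is 1/LEF and the
# linear expansion factor is reported as post-size / pre-size = 1/s.

#' Construct a similarity transform
#'
#' @param s scale factor (> 0).
#' @param theta rotation, radians (counter-clockwise).
#' @param t length-2 translation (tx, ty), um.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(s = 1, theta = 0, t = c(0, 0)) {
  check_number(s, "s", lower = 0, strict_lower = TRUE)
  check_number(theta, "theta")
  check_number(t, "t")
  if (length(t) != 2L) stop_invalid("'t' must have length 2")
  structure(list(s = s, theta = theta, t = as.numeric(t)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> scale %.5g, rotation %.5g rad, translation (%.4g, %.4g) um\n",
    x$s, x$theta, x$t[1], x$t[2]))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param tf a [similarity_transform()].
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) coordinates, um.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_similarity <- function(tf, xy) {
  xy <- rbind2cols(xy)
  cs <- cos(tf$theta); sn <- sin(tf$theta)
  cbind(tf$s * (cs * xy[, 1] - sn * xy[, 2]) + tf$t[1],
        tf$s * (sn * xy[, 1] + cs * xy[, 2]) + tf$t[2])
}

#' Invert a similarity transform
#' @param tf a [similarity_transform()].
#' @return the inverse `similarity_transform`.
#' @export
invert_similarity <- function(tf) {
  cs <- cos(-tf$theta); sn <- sin(-tf$theta)
  ti <- -c(cs * tf$t[1] - sn * tf$t[2], sn * tf$t[1] + cs * tf$t[2]) / tf$s
  similarity_transform(1 / tf$s, -tf$theta, ti)
}

rbind2cols <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  as.matrix(xy)
}

#' Fit a similarity transform to paired landmarks
#'
#' Closed-form least-squares (Procrustes) fit of scale, rotation and
#' translation mapping post-expansion landmarks onto their pre-expansion
#' partners.  With the two point sets centred, the optimal rotation and
#' scale come from the cross-covariance expressed as a complex number;
#' this is the exact minimizer of the summed squared residuals.
#'
#' @param landmarks data.frame with columns `x_pre`, `y_pre`, `x_post`,
#'   `y_post` in um (>= 2 rows).
#' @return a [similarity_transform()] with attributes `residuals`
#'   (n x 2 matrix, pre-frame um) and `rmse` (um).
#' @export
fit_similarity <- function(landmarks) {
  lm <- as.data.frame(landmarks)
  need <- c("x_pre", "y_pre", "x_post", "y_post")
  if (!all(need %in% names(lm)))
    stop_invalid("landmarks need columns ", paste(need, collapse = ", "))
  if (nrow(lm) < 2L) stop_invalid("at least 2 landmark pairs required")
  p <- complex(real = lm$x_pre, imaginary = lm$y_pre)
  q <- complex(real = lm$x_post, imaginary = lm$y_post)
  qc <- q - mean(q)
  pc <- p - mean(p)
  denom <- sum(Mod(qc)^2)
  if (denom < 1e-12)
    stop_invalid("degenerate landmark configuration: post points coincide")
  a <- sum(pc * Conj(qc)) / denom
  s <- Mod(a)
  if (s < 1e-12)
    stop_invalid("degenerate landmark configuration: no resolvable scale")
  theta <- Arg(a)
  t0 <- mean(p) - a * mean(q)
  tf <- similarity_transform(s, theta, c(Re(t0), Im(t0)))
  fit <- apply_similarity(tf, cbind(lm$x_post, lm$y_post))
  res <- cbind(lm$x_pre, lm$y_pre) - fit
  attr(tf, "residuals") <- res
  attr(tf, "rmse") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Linear expansion factor implied by a fitted similarity transform
#'
#' The registration maps the post-expansion (moving) image onto the
#' pre-expansion (static) image, so its fitted scale is pre-size /
#' post-size; the linear expansion factor (LEF) is always reported in the
#' post/pre direction, i.e. `1 / s`.
#'
#' @param tf a [similarity_transform()] fitted post -> pre.
#' @return LEF, dimensionless.
#' @export
estimate_expansion_factor <- function(tf) {
  if (!inherits(tf, "similarity_transform"))
    stop_invalid("'tf' must be a similarity_transform")
  1 / tf$s
}
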