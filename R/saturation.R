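# Identification-saturation curves: protein (or peptide) identifications
# as a function of punched tissue volume follow a sigmoid that plateaus
# once the sample stops being identification-limited.  Fitted with the
# four-parameter logistic (4PL) model
#   y = lower + (upper - lower) / (1 + (midpoint / x)^slope)
# by Levenberg-Marquardt least squares.

#' Fit a four-parameter logistic saturation curve
#'
#' @param volumes predictor values (e.g. tissue volume in nL), > 0.
#' @param counts response values (e.g. protein identifications).
#' @param conf_level confidence level of the reported band (default 0.95).
#' @return object of class `saturation_fit`: the \pkg{minpack.lm} fit
#'   plus the data; methods `coef`, `predict` (with `interval =
#'   "confidence"`), `print`, `plot`.
#' @examples
#' v <- c(0.6, 2.4, 5.4, 9.6, 15.0)
#' n <- c(928, 3044, 4203, 5058, 5105)
#' fit <- fit_saturation(v, n)
#' coef(fit)
#' @export
fit_saturation <- function(volumes, counts, conf_level = 0.95) {
  if (length(volumes) != length(counts))
    stop_invalid("'volumes' and 'counts' must have equal length")
  if (length(volumes) < 5L)
    stop_invalid("at least 5 points spanning the dynamic range are required")
  check_number(volumes, "volumes", lower = 0, strict_lower = TRUE)
  check_number(counts, "counts")
  dat <- data.frame(x = volumes, y = counts)
  rng <- diff(range(counts))
  if (rng < max(1e-8, 1e-6 * max(abs(counts)))) {
    warning("flat response: slope pinned near zero, upper ~ lower")
    fit <- NULL
    pars <- c(lower = mean(counts), upper = mean(counts),
              midpoint = median(volumes), slope = 0)
    return(structure(list(fit = fit, pars = pars, data = dat,
                          conf_level = conf_level, degenerate = TRUE),
                     class = "saturation_fit"))
  }
  # initialization from data quantiles
  lo0 <- min(counts); up0 <- max(counts)
  half <- lo0 + 0.5 * (up0 - lo0)
  ord <- order(volumes)
  mid0 <- stats::approx(counts[ord], volumes[ord], xout = half,
                        ties = "ordered")$y
  if (!is.finite(mid0) || mid0 <= 0) mid0 <- median(volumes)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lower + (upper - lower) / (1 + (midpoint / x)^slope),
      data = dat,
      start = list(lower = lo0, upper = up0, midpoint = mid0, slope = 1.5),
      lower = c(-Inf, -Inf, 1e-9, -50), upper = c(Inf, Inf, Inf, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_invalid(
      "4PL fit did not converge: ", conditionMessage(e),
      " (n = ", length(volumes), ", response range ", signif(rng, 3), ")"))
  structure(list(fit = fit, pars = coef(fit), data = dat,
                 conf_level = conf_level, degenerate = FALSE),
            class = "saturation_fit")
}

#' @export
coef.saturation_fit <- function(object, ...) object$pars

#' @export
print.saturation_fit <- function(x, ...) {
  p <- x$pars
  cat("Four-parameter logistic saturation fit\n")
  cat(sprintf("  lower %.4g, upper %.4g, midpoint %.4g, slope %.4g\n",
              p["lower"], p["upper"], p["midpoint"], p["slope"]))
  if (!x$degenerate) {
    rss <- sum(residuals(x$fit)^2)
    cat(sprintf("  n = %d, residual SD %.4g\n", nrow(x$data),
                sqrt(rss / max(1, nrow(x$data) - 4))))
  }
  invisible(x)
}

fourpl <- function(x, p) {
  p["lower"] + (p["upper"] - p["lower"]) / (1 + (p["midpoint"] / x)^p["slope"])
}

#' Predict from a saturation fit, optionally with a confidence band
#'
#' The band is the delta-method confidence interval of the fitted mean
#' curve from the parameter covariance.
#'
#' @param object a [fit_saturation()] result.
#' @param newdata optional data.frame with column `x` (or numeric vector).
#' @param interval `"none"` or `"confidence"`.
#' @param ... unused.
#' @return numeric vector, or data.frame with `fit`, `lwr`, `upr`.
#' @export
predict.saturation_fit <- function(object, newdata = NULL,
                                   interval = c("none", "confidence"), ...) {
  interval <- match.arg(interval)
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  yhat <- fourpl(x, object$pars)
  if (interval == "none") return(unname(yhat))
  if (object$degenerate)
    return(data.frame(fit = yhat, lwr = yhat, upr = yhat))
  V <- vcov(object$fit)
  p <- object$pars
  eps <- pmax(abs(p), 1e-4) * 1e-5
  G <- sapply(seq_along(p), function(k) {
    pk <- p; pk[k] <- pk[k] + eps[k]
    (fourpl(x, pk) - yhat) / eps[k]
  })
  G <- matrix(G, nrow = length(x))
  se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  zq <- qnorm(1 - (1 - object$conf_level) / 2)
  data.frame(fit = unname(yhat), lwr = unname(yhat - zq * se),
             upr = unname(yhat + zq * se))
}

#' @export
plot.saturation_fit <- function(x, n_grid = 200, ...) {
  d <- x$data
  xs <- seq(min(d$x), max(d$x), length.out = n_grid)
  pr <- predict(x, xs, interval = "confidence")
  plot(d$x, d$y, pch = 16, xlab = "tissue volume (nL)",
       ylab = "identifications", ylim = range(d$y, pr$lwr, pr$upr), ...)
  polygon(c(xs, rev(xs)), c(pr$upr, rev(pr$lwr)),
          col = grDevices::adjustcolor("grey50", 0.3), border = NA)
  lines(xs, pr$fit, lwd = 2)
  lines(xs, pr$lwr, lty = 2); lines(xs, pr$upr, lty = 2)
  invisible(x)
}
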