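#' Continuous segmented least-squares fit with fixed knots
#'
#' Fits a continuous piecewise-linear function of `x` to `y` by ordinary
#' (optionally weighted) least squares on the truncated power basis
#' `y ~ x + pmax(x - k_1, 0) + ... + pmax(x - k_m, 0)`, which enforces
#' continuity at every knot by construction. With `log_y = TRUE` the fit is
#' to `log(y)` and predictions are returned on the response scale, which is
#' the piecewise log-linear model used for incidence-versus-age smoothing.
#'
#' Knots outside the observed `x` range are dropped (with a warning), so a
#' sparsely populated segment degrades gracefully to fewer segments rather
#' than an unidentified fit.
#'
#' @param x,y numeric vectors (y > 0 required when `log_y = TRUE`).
#' @param knots increasing interior breakpoints on the `x` scale.
#' @param weights optional non-negative least-squares weights.
#' @param log_y fit on the log response scale?
#' @return object of class `segmented_fit` with components `coefficients`
#'   (intercept and per-basis slopes), `knots` (the knots retained),
#'   `segment_slopes` (per-segment slopes, cumulated from the basis), `rss`,
#'   and the data.
#' @seealso [predict.segmented_fit()], [fit_piecewise_loglinear()]
#' @export
segmented_fit <- function(x, y, knots, weights = NULL, log_y = FALSE) {
  stop_if_not(length(x) == length(y), "x and y lengths differ")
  stop_if_not(!is.unsorted(knots, strictly = TRUE),
              "knots must be strictly increasing")
  if (log_y) {
    stop_if_not(all(y > 0), "log-scale fit requires strictly positive y")
    yy <- log(y)
  } else yy <- y
  keep <- knots > min(x) & knots < max(x)
  if (!all(keep)) {
    warning("dropping knot(s) outside the data range: ",
            paste(knots[!keep], collapse = ", "))
    knots <- knots[keep]
  }
  basis <- cbind(x, vapply(knots, function(k) pmax(x - k, 0),
                           numeric(length(x))))
  colnames(basis) <- c("x", if (length(knots))
    paste0("k", seq_along(knots)))
  npar <- ncol(basis) + 1L
  stop_if_not(length(x) >= npar,
              "fewer points than segmented-regression parameters")
  fit <- if (is.null(weights)) lm(yy ~ basis) else
    lm(yy ~ basis, weights = weights)
  cf <- coef(fit)
  names(cf) <- c("(Intercept)", colnames(basis))
  structure(list(coefficients = cf,
                 knots = knots,
                 segment_slopes = cumsum(cf[-1]),
                 rss = sum(resid(fit)^2),
                 fitted = unname(fitted(fit)),
                 residuals = unname(resid(fit)),
                 x = x, y = y, log_y = log_y,
                 weights = weights,
                 n = length(x)),
            class = "segmented_fit")
}

seg_linear_predictor <- function(object, x) {
  cf <- object$coefficients
  lp <- cf[1] + cf[2] * x
  for (j in seq_along(object$knots))
    lp <- lp + cf[2 + j] * pmax(x - object$knots[j], 0)
  unname(lp)
}

#' Predict from a segmented fit
#'
#' @param object a [segmented_fit()].
#' @param newdata numeric vector of `x` values (defaults to the fitted `x`).
#' @param ... unused.
#' @return predictions on the response scale (exponentiated when the fit
#'   was on the log scale).
#' @export
predict.segmented_fit <- function(object, newdata = object$x, ...) {
  lp <- seg_linear_predictor(object, newdata)
  if (object$log_y) exp(lp) else lp
}

#' @export
coef.segmented_fit <- function(object, ...) object$coefficients

#' @export
residuals.segmented_fit <- function(object, ...) object$residuals

#' @export
fitted.segmented_fit <- function(object, ...) object$fitted

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Continuous segmented least-squares fit",
      if (x$log_y) "(log response scale)", "\n")
  cat("  n =", x$n, " knots:",
      if (length(x$knots)) paste(x$knots, collapse = ", ") else "none", "\n")
  cat("  segment slopes:",
      paste(signif(x$segment_slopes, 5), collapse = ", "), "\n")
  cat("  RSS:", signif(x$rss, 6), "\n")
  invisible(x)
}

#' @export
summary.segmented_fit <- function(object, ...) {
  bounds <- c(-Inf, object$knots, Inf)
  seg <- data.frame(from = bounds[-length(bounds)], to = bounds[-1],
                    slope = unname(object$segment_slopes))
  structure(list(segments = seg, rss = object$rss, n = object$n,
                 log_y = object$log_y), class = "summary.segmented_fit")
}

#' @export
print.summary.segmented_fit <- function(x, ...) {
  cat("Segmented fit on", x$n, "points",
      if (x$log_y) "(log scale)", "- RSS", signif(x$rss, 6), "\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}
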