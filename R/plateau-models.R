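#' Quadratic-plateau model parameters
#'
#' Constructs the parameter set of the three-parameter quadratic-plateau
#' saturation curve: an intercept `b0`, an initial slope `b1` and a
#' break-point `cx` (the incipient limiting level, ILL). The quadratic
#' coefficient is not free: `b2 = -b1 / (2 * cx)`, the unique choice giving a
#' concave-down curve whose first derivative vanishes at the break-point, so
#' the rising branch joins the plateau smoothly.
#'
#' @param b0 Intercept, in response units (e.g. day^-1).
#' @param b1 Initial slope, response units per mg C L^-1. Must be positive
#'   for a biologically meaningful rising curve.
#' @param cx Break-point (ILL), mg C L^-1. Must be positive.
#' @return An object of class `quadplateau_params`: a list with `b0`, `b1`,
#'   `cx` and the derived `b2`.
#' @seealso [quadplateau_predict()], [fit_quadratic_plateau()], [derive_tfl()]
#' @export
#' @examples
#' p <- quadplateau_params(b0 = 0, b1 = 0.8, cx = 1)
#' p$b2  # -0.4
quadplateau_params <- function(b0, b1, cx) {
  stopifnot(is.numeric(b0), is.numeric(b1), is.numeric(cx),
            length(b0) == 1L, length(b1) == 1L, length(cx) == 1L)
  if (!is.finite(cx) || cx <= 0) {
    stop("`cx` (break-point) must be a positive finite number, got ", cx)
  }
  structure(
    list(b0 = as.numeric(b0), b1 = as.numeric(b1), cx = as.numeric(cx),
         b2 = -as.numeric(b1) / (2 * as.numeric(cx))),
    class = "quadplateau_params"
  )
}

#' Hockey-stick (piecewise linear plateau) model parameters
#'
#' The simpler threshold alternative: `y = b0 + b1 * min(x, cx)`. Continuous
#' at `cx` with an abrupt slope change (derivative discontinuity), unlike the
#' smooth join of the quadratic-plateau model.
#'
#' @inheritParams quadplateau_params
#' @return An object of class `hockeystick_params`.
#' @export
hockeystick_params <- function(b0, b1, cx) {
  stopifnot(is.numeric(b0), is.numeric(b1), is.numeric(cx),
            length(b0) == 1L, length(b1) == 1L, length(cx) == 1L)
  if (!is.finite(cx) || cx <= 0) {
    stop("`cx` (threshold) must be a positive finite number, got ", cx)
  }
  structure(
    list(b0 = as.numeric(b0), b1 = as.numeric(b1), cx = as.numeric(cx)),
    class = "hockeystick_params"
  )
}

#' Evaluate the quadratic-plateau curve
#'
#' Returns `b0 + b1*x + b2*x^2` on the rising branch (`x <= cx`) and the
#' constant plateau value `b0 + b1*cx/2` beyond the break-point.
#'
#' @param params A [quadplateau_params()] object.
#' @param x Food concentrations (mg C L^-1), non-negative; vectorized.
#' @return Predicted responses, same length as `x`.
#' @export
#' @examples
#' p <- quadplateau_params(0, 0.8, 1)
#' quadplateau_predict(p, c(0.5, 2))  # 0.3, 0.4
quadplateau_predict <- function(params, x) {
  stopifnot(inherits(params, "quadplateau_params"), is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("`x` must be non-negative")
  xm <- pmin(x, params$cx)
  params$b0 + params$b1 * xm + params$b2 * xm^2
}

#' Evaluate the hockey-stick curve
#'
#' @param params A [hockeystick_params()] object.
#' @param x Food concentrations (mg C L^-1), non-negative; vectorized.
#' @return Predicted responses, same length as `x`.
#' @export
hockeystick_predict <- function(params, x) {
  stopifnot(inherits(params, "hockeystick_params"), is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("`x` must be non-negative")
  params$b0 + params$b1 * pmin(x, params$cx)
}

# mean function used inside nls formulas; xm = pmin(x, cx) collapses both
# branches into one differentiable-enough expression
quadplateau_mean <- function(x, b0, b1, cx) {
  xm <- pmin(x, cx)
  b0 + b1 * xm - (b1 / (2 * cx)) * xm^2
}

hockeystick_mean <- function(x, b0, b1, cx) {
  b0 + b1 * pmin(x, cx)
}

#' Deterministic self-start values for plateau fits
#'
#' Computes starting values for the three plateau parameters from the data
#' alone: the initial plateau guess is the mean response over the two highest
#' concentration levels; the initial slope and intercept come from an
#' ordinary least-squares line through the points below the median
#' concentration; the initial break-point is where that line reaches the
#' plateau guess, clamped into (min positive x, max x].
#'
#' @param x Concentrations (mg C L^-1).
#' @param y Responses.
#' @return A list with `b0`, `b1`, `cx` and a logical `degenerate` flag
#'   (raised when the low-concentration slope is not positive, e.g. flat
#'   data; a fallback start is then substituted).
#' @export
selfstart_quadplateau <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  lev <- sort(unique(x))
  if (length(lev) < 4L) {
    stop("insufficient design: need at least 4 distinct concentration levels, got ",
         length(lev))
  }
  top2 <- lev[(length(lev) - 1L):length(lev)]
  plateau0 <- mean(y[x %in% top2])
  low <- x < stats::median(lev)
  if (sum(low) < 2L) low <- x <= stats::median(lev)
  line <- stats::lm.fit(cbind(1, x[low]), y[low])
  b0_0 <- unname(line$coefficients[1L])
  slope0 <- unname(line$coefficients[2L])
  yscale <- max(abs(y - mean(y)), abs(mean(y)), 1e-12)
  degenerate <- !is.finite(slope0) || slope0 <= 0 ||
    slope0 * (max(x) - min(x)) <= 1e-8 * yscale
  if (degenerate) {
    # flat or decreasing low-food data: fall back to a coarse positive slope
    b0_0 <- min(y)
    slope0 <- max((max(y) - min(y)) / (max(x) - min(x[x > 0])), 1e-8)
    cx0 <- stats::median(lev)
  } else {
    cx0 <- (plateau0 - b0_0) / slope0
  }
  minpos <- min(x[x > 0])
  cx0 <- min(max(cx0, minpos * 1.0001), max(x))
  list(b0 = b0_0, b1 = slope0, cx = cx0, degenerate = degenerate)
}

new_plateau_fit <- function(params, rss, n_obs, converged, model_tag,
                            optimizer_tag, boundary, max_x) {
  plateau <- if (inherits(params, "quadplateau_params")) {
    params$b0 + params$b1 * params$cx / 2
  } else {
    params$b0 + params$b1 * params$cx
  }
  structure(
    list(params = params,
         ill = params$cx,
         plateau_elevation = plateau,
         tfl = derive_tfl(params),
         rss = rss,
         n_obs = n_obs,
         converged = converged,
         model_tag = model_tag,
         optimizer_tag = optimizer_tag,
         boundary = boundary,
         max_x = max_x),
    class = "plateau_fit"
  )
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat(sprintf("<%s fit>  n = %d, optimizer = %s%s\n", x$model_tag, x$n_obs,
              x$optimizer_tag, if (x$boundary) " [cx at boundary]" else ""))
  cat(sprintf("  b0 = %.5g, b1 = %.5g, cx (ILL) = %.5g\n",
              x$params$b0, x$params$b1, x$params$cx))
  cat(sprintf("  plateau = %.5g, TFL = %s, RSS = %.5g\n",
              x$plateau_elevation,
              if (is.na(x$tfl)) "not estimable" else sprintf("%.5g", x$tfl),
              x$rss))
  invisible(x)
}

#' @export
predict.plateau_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  if (object$model_tag == "quadratic_plateau") {
    quadplateau_predict(object$params, x)
  } else {
    hockeystick_predict(object$params, x)
  }
}

check_fit_design <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4L) {
    stop("insufficient design: need at least 4 distinct concentration levels")
  }
  if (length(x) < 6L) {
    stop("insufficient design: need at least 6 observations, got ", length(x))
  }
  if (any(x < 0)) stop("concentrations must be non-negative")
  list(x = x, y = y)
}

try_nls <- function(formula, data, start, lower, upper) {
  tryCatch({
    fit <- stats::nls(formula, data = data, start = start,
                      algorithm = "port", lower = lower, upper = upper,
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = FALSE))
    list(coef = stats::coef(fit), rss = sum(stats::resid(fit)^2),
         ok = TRUE)
  }, error = function(e) list(ok = FALSE, error = conditionMessage(e)),
     warning = function(w) list(ok = FALSE, error = conditionMessage(w)))
}

try_nlsLM <- function(formula, data, start, lower, upper) {
  tryCatch({
    fit <- suppressWarnings(
      minpack.lm::nlsLM(formula, data = data, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    )
    list(coef = stats::coef(fit), rss = sum(stats::resid(fit)^2), ok = TRUE)
  }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
}

fit_plateau_engine <- function(x, y, model_tag) {
  d <- check_fit_design(x, y)
  x <- d$x; y <- d$y
  max_x <- max(x)
  minpos <- min(x[x > 0])
  start <- selfstart_quadplateau(x, y)
  start_list <- list(b0 = start$b0, b1 = start$b1, cx = start$cx)
  lower <- c(b0 = -Inf, b1 = -Inf, cx = minpos * 1e-3)
  upper <- c(b0 = Inf, b1 = Inf, cx = max_x)
  form <- if (model_tag == "quadratic_plateau") {
    y ~ quadplateau_mean(x, b0, b1, cx)
  } else {
    y ~ hockeystick_mean(x, b0, b1, cx)
  }
  dat <- data.frame(x = x, y = y)

  primary <- try_nls(form, dat, start_list, lower, upper)
  if (primary$ok) {
    co <- primary$coef
    params <- if (model_tag == "quadratic_plateau") {
      quadplateau_params(co[["b0"]], co[["b1"]], co[["cx"]])
    } else {
      hockeystick_params(co[["b0"]], co[["b1"]], co[["cx"]])
    }
    return(new_plateau_fit(params, primary$rss, length(x), TRUE, model_tag,
                           "primary", co[["cx"]] >= max_x * (1 - 1e-8), max_x))
  }

  # fallback: damped least squares (Levenberg-Marquardt) from a log-spaced
  # grid of break-point starts; lowest RSS wins, ties broken by smallest cx
  cx_starts <- exp(seq(log(minpos), log(max_x), length.out = 20L))
  best <- NULL
  diagnostics <- list(primary_error = primary$error)
  for (cx0 in cx_starts) {
    st <- start_list
    st$cx <- cx0
    res <- try_nlsLM(form, dat, st, lower, upper)
    if (res$ok) {
      if (is.null(best) ||
          res$rss < best$rss - 1e-12 ||
          (abs(res$rss - best$rss) <= 1e-12 &&
           res$coef[["cx"]] < best$coef[["cx"]])) {
        best <- res
      }
    }
  }
  if (is.null(best)) {
    cond <- structure(
      class = c("illfit_nonconvergence", "error", "condition"),
      list(message = paste0("plateau fit failed to converge (", model_tag,
                            "); primary optimizer error: ",
                            diagnostics$primary_error),
           call = sys.call(-1), diagnostics = diagnostics)
    )
    stop(cond)
  }
  co <- best$coef
  params <- if (model_tag == "quadratic_plateau") {
    quadplateau_params(co[["b0"]], co[["b1"]], co[["cx"]])
  } else {
    hockeystick_params(co[["b0"]], co[["b1"]], co[["cx"]])
  }
  new_plateau_fit(params, best$rss, length(x), TRUE, model_tag, "fallback",
                  co[["cx"]] >= max_x * (1 - 1e-8), max_x)
}

#' Fit the quadratic-plateau model
#'
#' Minimizes the residual sum of squares of the quadratic-plateau curve over
#' `(b0, b1, cx)`, starting from [selfstart_quadplateau()]. The primary
#' optimizer is [stats::nls()] (port algorithm, break-point constrained to
#' (0, max x]); if it does not converge, a Levenberg-Marquardt fallback
#' ([minpack.lm::nlsLM()]) is retried from a 20-point log-spaced grid of
#' break-point starting values and the lowest-RSS solution is kept (ties go
#' to the smallest break-point). The returned fit records which path
#' succeeded and whether the break-point estimate sits on the upper boundary.
#'
#' @param x Concentrations (mg C L^-1); at least 4 distinct levels and 6
#'   points.
#' @param y Responses (e.g. somatic growth rate, day^-1). Negative values
#'   (below the threshold food level) are fitted as-is, no truncation.
#' @return A `plateau_fit` object: fitted `params`, `ill` (the break-point),
#'   `plateau_elevation` (predicted response at the ILL), `tfl` (x-intercept,
#'   `NA` when not estimable), `rss`, `n_obs`, `converged`, `model_tag`,
#'   `optimizer_tag`, `boundary`.
#' @export
#' @examples
#' x <- rep(c(0.05, 0.1, 0.25, 0.5, 1, 2.5), each = 2)
#' y <- quadplateau_predict(quadplateau_params(0, 0.8, 1), x)
#' fit_quadratic_plateau(x, y)
fit_quadratic_plateau <- function(x, y) {
  fit_plateau_engine(x, y, "quadratic_plateau")
}

#' Fit the hockey-stick (piecewise linear plateau) model
#'
#' Same optimization strategy as [fit_quadratic_plateau()] with the
#' piecewise-linear mean function `y = b0 + b1 * min(x, cx)`. The plateau
#' elevation is `b0 + b1*cx`; the TFL is `-b0/b1` when it falls in
#' `[0, cx)`.
#'
#' @inheritParams fit_quadratic_plateau
#' @return A `plateau_fit` object with `model_tag = "hockey_stick"`.
#' @export
fit_hockey_stick <- function(x, y) {
  fit_plateau_engine(x, y, "hockey_stick")
}

#' Threshold food level (x-intercept) of a fitted plateau curve
#'
#' The TFL is the food concentration at which the predicted response equals
#' zero. For the quadratic-plateau model this solves
#' `b0 + b1*x + b2*x^2 = 0` and returns the root on the rising branch (the
#' smaller root, within `[0, cx]`); for the hockey-stick model it is
#' `-b0/b1`. When the curve is positive at the origin (`b0 > 0`) or no root
#' lies on the rising branch, the TFL is not estimable and `NA` is returned
#' (a value, not an error).
#'
#' @param params A `quadplateau_params` or `hockeystick_params` object.
#' @return The TFL in mg C L^-1, or `NA_real_` when not estimable.
#' @export
#' @examples
#' derive_tfl(quadplateau_params(-0.1, 0.8, 1))  # 1 - sqrt(3)/2
derive_tfl <- function(params) {
  b0 <- params$b0; b1 <- params$b1; cx <- params$cx
  if (b0 > 0) return(NA_real_)
  if (b0 == 0) return(0)
  if (inherits(params, "hockeystick_params")) {
    tfl <- -b0 / b1
    if (is.finite(tfl) && tfl >= 0 && tfl < cx) return(tfl)
    return(NA_real_)
  }
  # smaller root of b0 + b1 x - b1/(2 cx) x^2: cx * (1 - sqrt(1 + 2 b0/(b1 cx)))
  disc <- 1 + 2 * b0 / (b1 * cx)
  if (!is.finite(disc) || disc < 0) return(NA_real_)
  tfl <- cx * (1 - sqrt(disc))
  if (tfl >= 0 && tfl <= cx) tfl else NA_real_
}

#' Brute-force profiled-grid fit (independent oracle)
#'
#' For a fixed break-point the plateau models are linear in `(b0, b1)`: the
#' quadratic-plateau regressor is `z = x - x^2/(2 cx)` on the rising branch
#' and the constant `cx/2` on the plateau; the hockey-stick regressor is
#' `min(x, cx)`. This routine solves ordinary least squares in closed form at
#' every grid value of `cx` and returns the global minimum over the grid —
#' an optimizer-free cross-check of [fit_quadratic_plateau()] /
#' [fit_hockey_stick()].
#'
#' @inheritParams fit_quadratic_plateau
#' @param cx_grid Candidate break-points, dense over (0, max x].
#' @param model `"quadratic_plateau"` (default) or `"hockey_stick"`.
#' @return A `plateau_fit` object with `optimizer_tag = "grid_oracle"`.
#' @export
profile_grid_oracle <- function(x, y, cx_grid,
                                model = c("quadratic_plateau", "hockey_stick")) {
  model <- match.arg(model)
  d <- check_fit_design(x, y)
  x <- d$x; y <- d$y
  stopifnot(is.numeric(cx_grid), length(cx_grid) >= 1L, all(cx_grid > 0))
  n <- length(x)
  Z <- if (model == "quadratic_plateau") {
    outer(x, cx_grid, function(xi, cc) {
      xm <- pmin(xi, cc)
      xm - xm^2 / (2 * cc)
    })
  } else {
    outer(x, cx_grid, pmin)
  }
  Sy <- sum(y); Syy <- sum(y * y)
  S1 <- colSums(Z); S2 <- colSums(Z * Z); Szy <- colSums(Z * y)
  den <- n * S2 - S1^2
  b1 <- (n * Szy - S1 * Sy) / den
  b0 <- (Sy - b1 * S1) / n
  rss <- Syy - 2 * (b0 * Sy + b1 * Szy) + n * b0^2 + 2 * b0 * b1 * S1 + b1^2 * S2
  rss[!is.finite(rss)] <- Inf
  i <- which.min(rss)  # which.min takes the first (smallest cx) on ties
  params <- if (model == "quadratic_plateau") {
    quadplateau_params(b0[i], b1[i], cx_grid[i])
  } else {
    hockeystick_params(b0[i], b1[i], cx_grid[i])
  }
  new_plateau_fit(params, max(rss[i], 0), n, TRUE, model, "grid_oracle",
                  cx_grid[i] >= max(x) * (1 - 1e-8), max(x))
}
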