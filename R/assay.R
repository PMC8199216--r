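#' Fluorescence polarization from channel intensities
#'
#' Computes polarization in millipolarization units from the parallel
#' (S) and perpendicular (P) plane intensities,
#' `mP = 1000 * (I_S - G * I_P) / (I_S + G * I_P)`, where `G` is the
#' device-specific grating factor. Intensities should already be blank
#' corrected (see [blank_correct()]). Vectorized over wells.
#'
#' @param i_s,i_p non-negative intensities (arbitrary units).
#' @param g G factor, positive scalar.
#' @return mP values in \[-1000, 1000\].
#' @export
polarization_mP <- function(i_s, i_p, g = 1) {
  if (g <= 0) stop_data("polarization_mP: G factor must be positive")
  if (any(i_s < 0) || any(i_p < 0))
    stop_data("polarization_mP: intensities must be non-negative")
  denom <- i_s + g * i_p
  if (any(denom == 0))
    stop_data("polarization_mP: I_S + G*I_P is zero; polarization undefined")
  1000 * (i_s - g * i_p) / denom
}

#' Blank correction of raw intensities
#'
#' Channel-wise subtraction of blank-well intensities from raw
#' intensities. Results that would be negative are clamped to zero with
#' a warning (a blank brighter than a sample well indicates a plate
#' problem but should not crash the analysis).
#'
#' @param raw,blank numeric vectors or matrices of matching shape.
#' @return corrected intensities, same shape as `raw`.
#' @export
blank_correct <- function(raw, blank) {
  if (!identical(dim(raw) %||% length(raw), dim(blank) %||% length(blank)))
    stop_data("blank_correct: raw and blank shapes differ")
  out <- raw - blank
  if (any(out < 0)) {
    warning(sprintf("blank_correct: %d value(s) below blank clamped to 0",
                    sum(out < 0)))
    out[out < 0] <- 0
  }
  out
}

#' Percent inhibition from polarization controls
#'
#' `I = 100 * (1 - (P_I - P_neg) / (P_pos - P_neg))`, where `P_I` is the
#' inhibitor well, `P_neg` the negative control (tracer only, fully
#' displaced limit) and `P_pos` the positive control (uninhibited
#' complex). Values may fall outside \[0, 100\] for wells beyond the
#' controls and are reported as-is. Vectorized over `p_i`.
#'
#' @param p_i inhibitor-well mP value(s).
#' @param p_neg,p_pos control mP values (must differ).
#' @return percent inhibition.
#' @export
percent_inhibition <- function(p_i, p_neg, p_pos) {
  if (p_pos == p_neg)
    stop_data("percent_inhibition: positive and negative controls are equal")
  100 * (1 - (p_i - p_neg) / (p_pos - p_neg))
}

#' Four-parameter logistic (variable-slope) dose-response model
#'
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(ic50) - log10(x))))`
#'
#' @param x concentrations (same unit as the fitted IC50).
#' @param ic50,hill,top,bottom model parameters.
#' @return predicted response.
#' @export
fourpl <- function(x, ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(ic50) - log10(x))))
}

#' Fit a variable-slope sigmoidal dose-response curve
#'
#' Least-squares fit of the four-parameter logistic (4PL) model to
#' percent-inhibition (or raw-response) data, the standard "sigmoidal,
#' variable slope" IC50 fit. The fit is run by Levenberg-Marquardt
#' nonlinear least squares with the IC50 parameterized on the log10
#' scale (which keeps it positive and makes the problem well scaled).
#'
#' Initialization is deterministic: `top`/`bottom` from the max/min
#' response, `ic50` from the concentration whose response is nearest the
#' half-way point, `hill = 1`. Replicates are fitted as individual
#' points by default; set `average_replicates = TRUE` to fit per-
#' concentration means instead.
#'
#' @param concentrations positive concentrations (molar or any fixed
#'   unit; the IC50 is reported in the same unit).
#' @param responses responses (percent inhibition by convention), same
#'   length.
#' @param average_replicates average replicate responses per
#'   concentration before fitting?
#' @return object of class `fit_4pl` with components `coefficients`
#'   (ic50, hill, top, bottom), `se` (asymptotic standard errors, IC50
#'   by the delta method), `converged`, `residuals`, `fitted`, `data`,
#'   `rss`, `sigma` and `init`. Non-convergence yields a flagged
#'   (`converged = FALSE`) result with a warning, never a silent one.
#' @examples
#' conc <- 10^seq(-9, -4.5, length.out = 12)
#' resp <- fourpl(conc, ic50 = 182.6e-9, hill = 1, top = 100, bottom = 0)
#' fit <- fit_4pl(conc, resp)
#' coef(fit)["ic50"] * 1e9   # nM
#' @export
fit_4pl <- function(concentrations, responses, average_replicates = FALSE) {
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  if (length(x) != length(y))
    stop_data("fit_4pl: %d concentrations but %d responses", length(x), length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0))
    stop_data("fit_4pl: concentrations must be positive and responses finite")
  if (average_replicates) {
    y <- tapply(y, x, mean)
    x <- as.numeric(names(y))
    y <- as.numeric(y)
    o <- order(x); x <- x[o]; y <- y[o]
  }
  if (length(unique(x)) < 4L)
    stop_data("fit_4pl: need >= 4 distinct concentrations, got %d",
              length(unique(x)))
  if (diff(range(y)) < 1e-8)
    stop_data("fit_4pl: responses are flat; dose-response fit is degenerate")

  top0 <- max(y); bot0 <- min(y)
  half <- (top0 + bot0) / 2
  ic0 <- x[which.min(abs(y - half))]
  init <- c(logic50 = log10(ic0), hill = 1, top = top0, bottom = bot0)

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (logic50 - log10(x)))),
      data = dat, start = as.list(init),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    warning(sprintf("fit_4pl: did not converge (%s); returning flagged result",
                    conditionMessage(fit)))
    co <- c(ic50 = 10^init[["logic50"]], hill = init[["hill"]],
            top = init[["top"]], bottom = init[["bottom"]])
    return(structure(list(coefficients = co,
                          se = c(ic50 = NA_real_, hill = NA_real_,
                                 top = NA_real_, bottom = NA_real_),
                          converged = FALSE, residuals = rep(NA_real_, length(y)),
                          fitted = rep(NA_real_, length(y)), data = dat,
                          rss = NA_real_, sigma = NA_real_, init = init),
                     class = "fit_4pl"))
  }

  p <- stats::coef(fit)
  co <- c(ic50 = 10^p[["logic50"]], hill = p[["hill"]],
          top = p[["top"]], bottom = p[["bottom"]])
  se_raw <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, 4L), names(p)))
  se <- c(ic50 = unname(se_raw["logic50"]) * log(10) * co[["ic50"]],  # delta method
          hill = unname(se_raw["hill"]),
          top = unname(se_raw["top"]),
          bottom = unname(se_raw["bottom"]))
  res <- stats::residuals(fit)
  structure(list(coefficients = co, se = se, converged = TRUE,
                 residuals = as.numeric(res),
                 fitted = as.numeric(stats::fitted(fit)), data = dat,
                 rss = sum(res^2),
                 sigma = sqrt(sum(res^2) / max(1L, length(y) - 4L)),
                 init = init),
            class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  co <- x$coefficients
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  IC50:   %.6g  (Hill slope %.3f)\n", co[["ic50"]], co[["hill"]]))
  cat(sprintf("  top:    %.3f   bottom: %.3f\n", co[["top"]], co[["bottom"]]))
  cat(sprintf("  %s, RSS %.4g over %d points\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
summary.fit_4pl <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, std.error = object$se)
  structure(list(coefficients = tab, converged = object$converged,
                 sigma = object$sigma, n = nrow(object$data),
                 init = object$init),
            class = "summary.fit_4pl")
}

#' @export
print.summary.fit_4pl <- function(x, ...) {
  cat("4PL fit summary", if (!x$converged) "(NOT CONVERGED)", "\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("residual sigma %.4g on %d points\n", x$sigma, x$n))
  invisible(x)
}

#' @export
coef.fit_4pl <- function(object, ...) object$coefficients

#' @export
residuals.fit_4pl <- function(object, ...) object$residuals

#' @export
fitted.fit_4pl <- function(object, ...) object$fitted

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  co <- object$coefficients
  fourpl(x, co[["ic50"]], co[["hill"]], co[["top"]], co[["bottom"]])
}

#' @export
plot.fit_4pl <- function(x, xlab = "concentration", ylab = "inhibition (%)",
                         ...) {
  d <- x$data
  graphics::plot(d$x, d$y, log = "x", xlab = xlab, ylab = ylab, ...)
  xs <- 10^seq(log10(min(d$x)), log10(max(d$x)), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(v = x$coefficients[["ic50"]], lty = 2)
  invisible(x)
}
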