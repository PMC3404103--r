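#' Boltzmann conductance-voltage function
#'
#' Ascending (activation) form `1 / (1 + exp((V_half - V) / k))` for
#' `k > 0`: the fraction rises with depolarization and equals 0.5 at
#' `V_half`. The descending (steady-state inactivation) branch is obtained
#' with `direction = "descending"`, i.e. `1 / (1 + exp((V - V_half) / k))`.
#'
#' @param V test potential(s), mV.
#' @param V_half midpoint voltage, mV.
#' @param k slope factor, mV; must be nonzero.
#' @param direction `"ascending"` (activation, default) or `"descending"`
#'   (inactivation).
#' @return fraction in (0, 1).
#' @export
boltzmann <- function(V, V_half, k, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (any(k == 0)) stop("slope factor k must be nonzero")
  if (direction == "ascending") 1 / (1 + exp((V_half - V) / k))
  else 1 / (1 + exp((V - V_half) / k))
}

# deterministic initialization: V_half from the half-maximum crossing of the
# linearly interpolated normalized data, k from the 25-75% span
.boltz_init <- function(V, y, direction) {
  ord <- order(V)
  V <- V[ord]; y <- y[ord]
  ys <- if (direction == "ascending") y else 1 - y
  cross <- function(level) {
    i <- which(ys[-1] >= level & ys[-length(ys)] < level)
    if (!length(i)) {
      # monotone-enough fallback: nearest point
      return(V[which.min(abs(ys - level))])
    }
    i <- i[1]
    V[i] + (level - ys[i]) * (V[i + 1] - V[i]) / (ys[i + 1] - ys[i])
  }
  v50 <- cross(0.5)
  span <- cross(0.75) - cross(0.25)
  # logit(0.75) - logit(0.25) = 2.197, so span ~ 2.197 k
  k0 <- max(abs(span) / 2.197, 1e-3)
  c(V_half = v50, k = k0)
}

#' Fit a Boltzmann function to normalized tail-current amplitudes
#'
#' Nonlinear least squares (Levenberg-Marquardt) with deterministic
#' initialization: the midpoint from the half-maximum crossing of the
#' linearly interpolated data, the slope factor from the 25-75% span.
#' Degenerate or clearly non-sigmoid data (e.g. two-phase conductance
#' curves) are flagged by a lack-of-fit check rather than silently fitted.
#'
#' @param V test potentials, mV (distinct, >= 4).
#' @param amplitude normalized amplitudes (same length).
#' @param direction `"ascending"` (activation) or `"descending"`
#'   (steady-state inactivation).
#' @param k_fixed optional fixed slope factor (mV): only `V_half` is
#'   estimated (the fixed-slope fit used when few points are available).
#' @param max_lack_of_fit maximum tolerated residual standard deviation
#'   before the fit is declared a lack of fit (default 0.15 on the
#'   normalized scale).
#' @return a `boltzmann_fit` with `V_half`, `k` (mV), `rss`, standard
#'   errors, `direction`; methods: `print`, `coef`, `predict`.
#' @export
fit_boltzmann <- function(V, amplitude, direction = c("ascending", "descending"),
                          k_fixed = NULL, max_lack_of_fit = 0.15) {
  direction <- match.arg(direction)
  V <- as.numeric(V); y <- as.numeric(amplitude)
  if (length(V) != length(y)) stop("V and amplitude lengths differ")
  if (anyDuplicated(V)) stop("test potentials must be distinct")
  if (is.null(k_fixed) && length(V) < 4) {
    stop("need at least 4 potentials spanning the transition")
  }
  if (max(y) - min(y) < 1e-3) {
    stop("amplitudes are constant: no voltage dependence to fit")
  }
  init <- .boltz_init(V, y, direction)
  df <- data.frame(V = V, y = y)
  sgn <- if (direction == "ascending") 1 else -1
  fit <- if (is.null(k_fixed)) {
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(sgn * (V_half - V) / k)), data = df,
                      start = list(V_half = init[["V_half"]], k = init[["k"]]),
                      lower = c(-Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(sgn * (V_half - V) / k_fixed)),
                      data = df, start = list(V_half = init[["V_half"]]),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- coef(fit)
  k_hat <- if (is.null(k_fixed)) cf[["k"]] else k_fixed
  res <- residuals(fit)
  rsd <- sqrt(sum(res^2) / max(1, length(res) - length(cf)))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  out <- structure(list(V_half = cf[["V_half"]], k = k_hat,
                        k_fixed = !is.null(k_fixed),
                        rss = sum(res^2), residual_sd = rsd,
                        se = se, direction = direction,
                        lack_of_fit = rsd > max_lack_of_fit,
                        data = df, fit = fit),
                   class = "boltzmann_fit")
  if (out$lack_of_fit) {
    warning(sprintf(
      "lack of fit (residual sd %.3f > %.3f): data may be two-phase or non-sigmoid",
      rsd, max_lack_of_fit))
  }
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: V_half = %.2f mV, k = %.2f mV%s (rss %.3g)%s\n",
              x$direction, x$V_half, x$k, if (x$k_fixed) " [fixed]" else "",
              x$rss, if (x$lack_of_fit) " LACK OF FIT" else ""))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(V_half = object$V_half, k = object$k)
}

#' @export
predict.boltzmann_fit <- function(object, V = object$data$V, ...) {
  boltzmann(V, object$V_half, object$k, object$direction)
}

#' Fit a single-exponential decay to a deactivating current
#'
#' Least-squares fit of `A * exp(-t / tau) + C` over the decaying segment
#' (Levenberg-Marquardt). Initialization: `C` from the tail mean, `tau`
#' from a log-linear regression of the offset-corrected trace, `A` from the
#' first sample. Time is measured from the start of the fitted window.
#'
#' @param time time points, ms.
#' @param current current samples (same length, any units).
#' @param window optional `c(t0, t1)` restricting the fitted segment.
#' @return an `exp_fit` with `tau` (ms), `amplitude`, `offset`, `rss`;
#'   methods `print`, `coef`, `predict`.
#' @export
fit_exponential <- function(time, current, window = NULL) {
  t <- as.numeric(time); y <- as.numeric(current)
  if (length(t) != length(y)) stop("time and current lengths differ")
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 5) stop("need at least 5 samples in the fitted window")
  t0 <- t[1]
  ts <- t - t0
  C0 <- mean(y[ts >= 0.9 * max(ts)])
  dy <- y - C0
  if (abs(dy[1]) < 1e-12 || sign(mean(dy[1:3])) * (abs(dy[1]) - abs(dy[length(dy)])) <= 0) {
    # trace does not decay toward the tail level
    if (max(abs(dy)) < 1e-8 * max(1, abs(C0))) {
      stop("trace is constant: no decay to fit")
    }
  }
  pos <- which(dy * sign(dy[1]) > 1e-12 * max(abs(dy)))
  if (length(pos) < 3) stop("trace does not decay: cannot fit an exponential")
  lf <- lm(log(abs(dy[pos])) ~ ts[pos])
  tau0 <- unname(-1 / coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(ts) / 3
  df <- data.frame(ts = ts, y = y)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-ts / tau) + C, data = df,
                           start = list(A = dy[1], tau = tau0, C = C0),
                           lower = c(-Inf, 1e-9, -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  if (abs(cf[["A"]]) < 1e-10 * max(abs(y), 1)) {
    stop("fitted amplitude is zero: trace does not decay")
  }
  structure(list(tau = cf[["tau"]], amplitude = cf[["A"]],
                 offset = cf[["C"]], rss = sum(residuals(fit)^2),
                 t0 = t0, fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.2f ms, A = %.4g, offset = %.4g (rss %.3g)\n",
              x$tau, x$amplitude, x$offset, x$rss))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(tau = object$tau, amplitude = object$amplitude, offset = object$offset)
}

#' @export
predict.exp_fit <- function(object, time, ...) {
  object$amplitude * exp(-(time - object$t0) / object$tau) + object$offset
}

#' Steady-state inactivation ratio at a test potential
#'
#' Ratio of the current remaining `window` ms after pulse onset to the
#' instantaneous current at onset. The instantaneous amplitude is the
#' linear extrapolation of the first 5 samples after onset back to
#' `t_onset` (capacitive-transient-free traces assumed); the remaining
#' amplitude is linearly interpolated at `t_onset + window`.
#'
#' @param time time points, ms.
#' @param current current samples.
#' @param t_onset pulse onset time, ms.
#' @param window measurement window after onset, ms (default 100).
#' @return list with `ratio` (remaining / instantaneous), `instantaneous`,
#'   `remaining`.
#' @export
steady_state_inactivation <- function(time, current, t_onset = 0,
                                      window = 100) {
  t <- as.numeric(time); y <- as.numeric(current)
  t_end <- t_onset + window
  if (min(t) > t_onset || max(t) < t_end) {
    stop(sprintf("trace does not cover [%g, %g] ms", t_onset, t_end))
  }
  idx <- which(t >= t_onset)[1:5]
  if (anyNA(idx)) stop("need at least 5 samples after onset")
  lf <- lm(y[idx] ~ t[idx])
  inst <- unname(coef(lf)[1] + coef(lf)[2] * t_onset)
  if (abs(inst) < 1e-12) stop("instantaneous amplitude is zero: ratio undefined")
  rem <- stats::approx(t, y, xout = t_end)$y
  list(ratio = rem / inst, instantaneous = inst, remaining = rem)
}

#' Fit steady-state inactivation voltage dependence
#'
#' Boltzmann fit (descending branch) of steady-state inactivation ratios
#' versus test potential; optionally with the slope factor frozen
#' (`k_fixed`), the fixed-slope procedure used when a mutant is assumed not
#' to alter the slope.
#'
#' @param V test potentials, mV.
#' @param ratio steady-state inactivation ratios.
#' @param k_fixed optional fixed slope factor, mV.
#' @return a `boltzmann_fit` (descending).
#' @export
fit_ss_inactivation <- function(V, ratio, k_fixed = NULL) {
  if (!length(V)) stop("no inactivation data")
  fit_boltzmann(V, ratio, direction = "descending", k_fixed = k_fixed)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$V, x$data$y, pch = 19,
                 xlab = "test potential (mV)",
                 ylab = "normalized amplitude", ...)
  vv <- seq(min(x$data$V), max(x$data$V), length.out = 200)
  graphics::lines(vv, predict(x, vv))
  invisible(x)
}
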