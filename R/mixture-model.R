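#' Parameters of the mixed shifted-exponential generation-time model
#'
#' Generation times of proliferating mammalian cells are often described by a
#' shifted exponential: a fixed no-division period `tau0` (the minimum
#' cell-cycle length) followed by an exponentially distributed remainder. A
#' clonal population that harbours a minority of slow-cycling cells requires a
#' mixture of two such components sharing the shift:
#' \deqn{g(\tau) = (1-a)\,\lambda_1 e^{-\lambda_1(\tau-\tau_0)} +
#'       a\,\lambda_2 e^{-\lambda_2(\tau-\tau_0)}, \quad \tau \ge \tau_0,}
#' and 0 below `tau0`. `lambda1` is the fast decay constant, `lambda2` the
#' slow one, and `a` the fraction of cells in the slow-cycling component.
#'
#' @param lambda1 Fast-component decay constant, per hour. Must exceed
#'   `lambda2`.
#' @param lambda2 Slow-component decay constant, per hour. Must be positive.
#' @param tau0 Minimum cell-cycle length in hours (`>= 0`).
#' @param a Fraction in (0, 1) of cells in the slow (`lambda2`) component.
#' @return An object of class `mixture_params`.
#' @seealso [l1210_params()] for the reference parameter set,
#'   [mixture_pdf()], [mixture_survival()], [sample_mixture()].
#' @export
#' @examples
#' p <- mixture_params(0.5, 0.1, 8, 0.05)
#' mixture_mean(p)
mixture_params <- function(lambda1, lambda2, tau0, a) {
  stopifnot(
    is.numeric(lambda1), length(lambda1) == 1L, is.finite(lambda1),
    is.numeric(lambda2), length(lambda2) == 1L, is.finite(lambda2),
    is.numeric(tau0), length(tau0) == 1L, is.finite(tau0),
    is.numeric(a), length(a) == 1L, is.finite(a)
  )
  if (!(lambda2 > 0)) stop("lambda2 must be > 0")
  if (!(lambda1 > lambda2)) stop("lambda1 must exceed lambda2 (fast > slow)")
  if (tau0 < 0) stop("tau0 must be >= 0")
  if (!(a > 0 && a < 1)) stop("a must lie strictly in (0, 1)")
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, tau0 = tau0, a = a),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("Mixed shifted-exponential generation-time model\n")
  cat(sprintf("  lambda1 = %.4g /h (fast), lambda2 = %.4g /h (slow)\n",
              x$lambda1, x$lambda2))
  cat(sprintf("  tau0 = %.4g h, slow fraction a = %.4g\n", x$tau0, x$a))
  cat(sprintf("  mean generation time = %.4g h\n", mixture_mean(x)))
  invisible(x)
}

#' Reference parameter set for L1210 mother-machine generation times
#'
#' The fitted parameter point for the L1210 mouse leukemia cell line growing
#' in a mother-machine device: `lambda1 = 0.571` per hour, `lambda2 = 0.134`
#' per hour, `tau0 = 8.375` h, `a = 0.060`. About 6\% of cells occupy the
#' slow-cycling component; the implied mean generation time is 10.47 h.
#'
#' @return A `mixture_params` object.
#' @export
#' @examples
#' mixture_mean(l1210_params())
l1210_params <- function() {
  mixture_params(lambda1 = 0.571, lambda2 = 0.134, tau0 = 8.375, a = 0.060)
}

as_mixture_params <- function(x) {
  if (inherits(x, "mixture_params")) return(x)
  if (is.list(x) && all(c("lambda1", "lambda2", "tau0", "a") %in% names(x))) {
    return(mixture_params(x$lambda1, x$lambda2, x$tau0, x$a))
  }
  stop("cannot interpret object as mixture_params")
}

#' Density, survival, CDF and quantile of the generation-time mixture
#'
#' `mixture_pdf` evaluates the density g; `mixture_survival` the survival
#' function \eqn{B(\tau) = \int_\tau^\infty g}, i.e. the probability that a
#' newborn cell remains undivided at age `tau` (1 below `tau0`);
#' `mixture_cdf` is `1 - B`; `mixture_quantile` inverts the CDF by bisection;
#' `mixture_mean` returns the closed-form mean
#' \eqn{\tau_0 + (1-a)/\lambda_1 + a/\lambda_2}.
#'
#' @param tau Vector of generation times, hours.
#' @param params A [mixture_params()] object.
#' @return `mixture_pdf`: densities per hour; `mixture_survival`,
#'   `mixture_cdf`: probabilities; `mixture_quantile`: hours.
#' @export
#' @examples
#' p <- l1210_params()
#' mixture_survival(14, p)   # ~ 0.066
mixture_pdf <- function(tau, params) {
  params <- as_mixture_params(params)
  s <- tau - params$tau0
  out <- ifelse(
    s < 0, 0,
    (1 - params$a) * params$lambda1 * exp(-params$lambda1 * s) +
      params$a * params$lambda2 * exp(-params$lambda2 * s)
  )
  out
}

#' @rdname mixture_pdf
#' @export
mixture_survival <- function(tau, params) {
  params <- as_mixture_params(params)
  s <- tau - params$tau0
  ifelse(
    s < 0, 1,
    (1 - params$a) * exp(-params$lambda1 * s) +
      params$a * exp(-params$lambda2 * s)
  )
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(tau, params) 1 - mixture_survival(tau, params)

# survival of the shifted part only (s = tau - tau0 >= 0)
surv_shift <- function(s, params) {
  (1 - params$a) * exp(-params$lambda1 * s) +
    params$a * exp(-params$lambda2 * s)
}

#' @rdname mixture_pdf
#' @param p Vector of probabilities in `[0, 1)`.
#' @param tol Absolute bisection tolerance in hours (default `1e-9`).
#' @export
mixture_quantile <- function(p, params, tol = 1e-9) {
  params <- as_mixture_params(params)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("p must lie in [0, 1)")
  }
  q <- 1 - p                      # target survival value
  lo <- rep(0, length(p))
  hi <- -log(pmax(q, 1e-300)) / params$lambda2  # B(s) <= exp(-lambda2 s)
  hi <- pmax(hi, tol)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    right <- surv_shift(mid, params) > q  # B decreasing: root lies right
    lo[right] <- mid[right]
    hi[!right] <- mid[!right]
    if (max(hi - lo) < tol) break
  }
  params$tau0 + (lo + hi) / 2
}

#' @rdname mixture_pdf
#' @export
mixture_mean <- function(params) {
  params <- as_mixture_params(params)
  params$tau0 + (1 - params$a) / params$lambda1 + params$a / params$lambda2
}
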