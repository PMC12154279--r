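#' Gamma-variate bolus input function
#'
#' Describes the rate at which hyperpolarized pyruvate magnetization
#' arrives in the imaging slice after a hand injection lasting roughly
#' 25 s. The delivery rate is a gamma-variate
#' \deqn{u(t) = A \, (t'/\alpha\beta)^\alpha \exp(\alpha - t'/\beta)}
#' with \eqn{t' = t - t_\mathrm{arrival}} and `u = 0` before arrival.
#' The curve peaks at \eqn{t' = \alpha\beta} with peak value `amplitude`.
#'
#' @param arrival_time delay before the bolus reaches the slice (s)
#' @param alpha dimensionless shape parameter (> 0)
#' @param beta time scale (s, > 0)
#' @param amplitude peak delivery rate (a.u./s, >= 0)
#' @return an object of class `bolus_input`
#' @examples
#' b <- bolus_input(alpha = 3, beta = 4)
#' simulate_bolus(b, seq(0, 40, by = 1))
#' @export
bolus_input <- function(arrival_time = 0, alpha = 3, beta = 4, amplitude = 1) {
  if (amplitude < 0) stop("bolus amplitude must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("bolus alpha and beta must be positive")
  if (arrival_time < 0) stop("bolus arrival_time must be >= 0")
  structure(list(arrival_time = arrival_time, alpha = alpha,
                 beta = beta, amplitude = amplitude),
            class = "bolus_input")
}

#' Evaluate the bolus delivery rate on a timebase
#'
#' @param bolus a [bolus_input()]
#' @param timebase strictly increasing times (s) starting at 0
#' @return numeric vector of delivery rates (a.u./s), zero before arrival
#' @export
simulate_bolus <- function(bolus, timebase) {
  stopifnot(inherits(bolus, "bolus_input"))
  if (length(timebase) < 1 || timebase[1] < 0)
    stop("timebase must start at a non-negative time")
  if (any(diff(timebase) <= 0))
    stop("timebase must be strictly increasing")
  tp <- timebase - bolus$arrival_time
  u <- numeric(length(timebase))
  pos <- tp > 0
  a <- bolus$alpha
  b <- bolus$beta
  u[pos] <- bolus$amplitude * (tp[pos] / (a * b))^a * exp(a - tp[pos] / b)
  u
}
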