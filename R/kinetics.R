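#' Apparent kinetic parameters of a tissue compartment
#'
#' First-order precursor-product model for hyperpolarized pyruvate:
#' injected Pyr is converted unidirectionally into lactate (`k_pl`),
#' bicarbonate (`k_pb`) and alanine (`k_pa`), while every pool loses
#' longitudinal magnetization at an apparent rate `r1_*` that lumps
#' true T1 relaxation with polarization loss. `perfusion_scale`
#' multiplies the bolus delivery into the compartment.
#'
#' @param k_pl,k_pb,k_pa apparent conversion rates Pyr->Lac/Bic/Ala (1/s)
#' @param r1_pyr,r1_lac,r1_bic,r1_ala apparent longitudinal decay rates (1/s)
#' @param perfusion_scale dimensionless delivery scaling (>= 0)
#' @return an object of class `kinetic_params`
#' @export
kinetic_params <- function(k_pl = 0.02, k_pb = 0.010, k_pa = 0.002,
                           r1_pyr = 0.04, r1_lac = 0.04,
                           r1_bic = 0.04, r1_ala = 0.04,
                           perfusion_scale = 1) {
  rates <- c(k_pl = k_pl, k_pb = k_pb, k_pa = k_pa,
             r1_pyr = r1_pyr, r1_lac = r1_lac, r1_bic = r1_bic,
             r1_ala = r1_ala, perfusion_scale = perfusion_scale)
  if (any(rates < 0)) stop("kinetic rates must all be >= 0")
  if (k_pl + k_pb + k_pa >= 1)
    stop("total conversion rate k_pl + k_pb + k_pa must be < 1 /s")
  structure(as.list(rates), class = "kinetic_params")
}

#' Simulate hyperpolarized metabolite dynamics in one compartment
#'
#' Integrates the unidirectional exchange system
#' \deqn{dM_P/dt = u(t) - (r_{1,P} + k_{PL} + k_{PB} + k_{PA}) M_P}
#' \deqn{dM_X/dt = k_{PX} M_P - r_{1,X} M_X, \quad X \in \{L, B, A\}}
#' where `u(t)` is the bolus delivery rate scaled by `perfusion_scale`.
#' Magnetization is non-recoverable: there is no equilibrium term.
#'
#' @param kin a [kinetic_params()]
#' @param input_curve bolus delivery rate evaluated on `timebase`
#'   (a.u./s), e.g. from [simulate_bolus()]
#' @param timebase strictly increasing times (s)
#' @param initial_pyruvate pyruvate magnetization already present at
#'   `timebase[1]` (a.u.); an impulse bolus is `initial_pyruvate = 1`
#'   with a zero input curve
#' @return tibble with columns `time`, `pyruvate`, `lactate`,
#'   `bicarbonate`, `alanine`
#' @export
simulate_metabolite_dynamics <- function(kin, input_curve, timebase,
                                         initial_pyruvate = 0) {
  stopifnot(inherits(kin, "kinetic_params"))
  if (length(input_curve) != length(timebase))
    stop("input_curve and timebase must have the same length")
  if (any(diff(timebase) <= 0)) stop("timebase must be strictly increasing")
  ufun <- stats::approxfun(timebase, input_curve * kin$perfusion_scale,
                           rule = 2)
  lam <- kin$r1_pyr + kin$k_pl + kin$k_pb + kin$k_pa
  deriv <- function(t, y, parms) {
    u <- ufun(t)
    list(c(
      u - lam * y[1],
      kin$k_pl * y[1] - kin$r1_lac * y[2],
      kin$k_pb * y[1] - kin$r1_bic * y[3],
      kin$k_pa * y[1] - kin$r1_ala * y[4]
    ))
  }
  sol <- deSolve::ode(y = c(P = initial_pyruvate, L = 0, B = 0, A = 0),
                      times = timebase, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  out <- tibble::tibble(
    time = sol[, "time"],
    pyruvate = pmax(sol[, "P"], 0),
    lactate = pmax(sol[, "L"], 0),
    bicarbonate = pmax(sol[, "B"], 0),
    alanine = pmax(sol[, "A"], 0)
  )
  out
}

# Metabolite curves for every labeled compartment of a phantom,
# evaluated on `timebase`. Returns a named list of tibbles.
compartment_dynamics <- function(phantom, bolus, timebase) {
  u <- simulate_bolus(bolus, timebase)
  lapply(phantom$kinetics_by_label, function(kin) {
    simulate_metabolite_dynamics(kin, u, timebase)
  })
}
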