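#' Feng-type arterial input function
#'
#' Tri-exponential bolus model
#' `Cp(t) = (A1*t - A2 - A3) * exp(-l1*t) + A2*exp(-l2*t) + A3*exp(-l3*t)`
#' with time in minutes: zero at t = 0, a single early peak, then monotone
#' decay. Drives the synthetic phantoms; amplitudes are in arbitrary
#' activity units.
#'
#' @param t_min times in minutes (>= 0)
#' @param params named vector A1, A2, A3 (amplitude), l1, l2, l3 (1/min)
#' @return activity at each time
#' @export
feng_input <- function(t_min, params = feng_defaults()) {
  if (any(t_min < 0)) stop("time must be non-negative")
  p <- params
  (p[["A1"]] * t_min - p[["A2"]] - p[["A3"]]) * exp(-p[["l1"]] * t_min) +
    p[["A2"]] * exp(-p[["l2"]] * t_min) +
    p[["A3"]] * exp(-p[["l3"]] * t_min)
}

#' @rdname feng_input
#' @export
feng_defaults <- function() {
  c(A1 = 851.1, A2 = 21.88, A3 = 20.81, l1 = 4.134, l2 = 0.1191, l3 = 0.0104)
}

# Causal convolution of f (on a uniform grid, step dt) with exp(-k*t),
# trapezoidal rule, via a first-order recursive filter. dt and k share a
# time unit.
conv_exp <- function(f, dt, k) {
  n <- length(f)
  if (k < 0) stop("rate constant must be non-negative")
  e <- exp(-k * dt)
  if (n < 2) return(numeric(n))
  g <- dt / 2 * (f[-1] + e * f[-n])
  c(0, as.numeric(stats::filter(g, e, method = "recursive")))
}

#' Kinetic parameter set for a reference-tissue model
#'
#' Houses the SRTM quantities: relative delivery `R1`, target efflux `k2`,
#' apparent efflux `k2a`, reference efflux `k2p` (= k2/R1) and binding
#' potential `bp` (= k2/k2a - 1). Any two of (k2, k2a, bp) plus R1 determine
#' the rest; the constructor takes (R1, bp, k2p) and derives the others.
#'
#' @param R1 relative delivery (> 0), unitless
#' @param bp non-displaceable binding potential (>= -1), unitless
#' @param k2p reference-region efflux rate, 1/min (> 0)
#' @return object of class `kinetic_params` with fields R1, k2, k2a, k2p, bp
#' @export
kinetic_params <- function(R1, bp, k2p) {
  if (R1 <= 0) stop("R1 must be positive")
  if (bp < -1) stop("bp must be >= -1")
  if (k2p <= 0) stop("k2p must be positive")
  k2 <- R1 * k2p
  k2a <- k2 / (1 + bp)
  if (k2a <= 0) stop("derived k2a must be positive")
  structure(list(R1 = R1, k2 = k2, k2a = k2a, k2p = k2p, bp = bp),
            class = "kinetic_params")
}

#' Simulate a reference-tissue time-activity curve
#'
#' One-tissue compartment `dC_R/dt = K1*Cp - k2p*C_R` driven by the input
#' function, solved by exponential convolution on a fine uniform grid and
#' averaged over the acquisition frames.
#'
#' @param schedule a [frame_schedule()]
#' @param K1 influx rate, 1/min (>= 0)
#' @param k2p efflux rate, 1/min (> 0)
#' @param dt_s fine grid step in seconds
#' @param input input function of time-in-minutes
#' @return a [tac()]; the fine-grid curve is attached as attribute `fine`
#' @export
simulate_reference_tac <- function(schedule, K1, k2p, dt_s = 1,
                                   input = feng_input) {
  fine <- reference_fine(schedule, K1, k2p, dt_s, input)
  out <- tac(frame_average(fine, schedule, fine_times(schedule, dt_s)), schedule)
  attr(out, "fine") <- fine
  out
}

# fine-grid reference curve, time unit minutes internally
reference_fine <- function(schedule, K1, k2p, dt_s = 1, input = feng_input) {
  if (K1 < 0) stop("K1 must be non-negative")
  if (k2p <= 0) stop("k2p must be positive")
  t_s <- fine_times(schedule, dt_s)
  cp <- input(t_s / 60)
  K1 * conv_exp(cp, dt_s / 60, k2p)
}

#' SRTM forward model for a target-tissue curve
#'
#' Operational simplified-reference-tissue equation
#' `C_T(t) = R1*C_R(t) + (k2 - R1*k2a) * [C_R (x) exp(-k2a t)](t)`,
#' evaluated on the fine grid and averaged over frames. With R1 = 1 and
#' bp = 0 (k2 = k2a) it reproduces the reference curve exactly.
#'
#' @param ref_fine fine-grid reference curve (see [reference_fine] via
#'   `attr(simulate_reference_tac(...), "fine")`)
#' @param params a [kinetic_params()]
#' @param schedule a [frame_schedule()]
#' @param dt_s fine grid step in seconds matching `ref_fine`
#' @return a [tac()]; fine-grid curve attached as attribute `fine`
#' @export
srtm_forward <- function(ref_fine, params, schedule, dt_s = 1) {
  t_s <- fine_times(schedule, dt_s)
  if (length(ref_fine) != length(t_s))
    stop("ref_fine length does not match the schedule's fine grid")
  conv <- conv_exp(ref_fine, dt_s / 60, params$k2a)
  fine <- params$R1 * ref_fine + (params$k2 - params$R1 * params$k2a) * conv
  out <- tac(frame_average(fine, schedule, t_s), schedule)
  attr(out, "fine") <- fine
  out
}
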