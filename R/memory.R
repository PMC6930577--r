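#' Exponential-memory accumulator
#'
#' Realises the exponentially weighted running mean used for every MDOC
#' observable: the mean at time t weights past instantaneous values v(t')
#' with exp(-(t - t')/tau). The discretised recursion is
#' `N <- N exp(-dt/tau) + dt`; `S <- S exp(-dt/tau) + v dt`; mean = S/N,
#' applied componentwise for tensor observables. After 5 tau less than 1
#' percent of the original weight remains.
#'
#' @param tau memory time, ps.
#' @param dim number of components of the observable (9 for a dipolar
#'   tensor, 1 for scalars).
#' @param t0 start time, ps.
#' @return object of class `memory_state`.
#' @export
memory_state <- function(tau, dim = 1, t0 = 0) {
  stopifnot(tau > 0, dim >= 1)
  structure(list(S = numeric(dim), N = 0, tau = tau, t0 = t0, t = t0),
            class = "memory_state")
}

#' Update an exponential-memory accumulator
#'
#' @param mem a `memory_state`.
#' @param value instantaneous observable (length `dim`).
#' @param dt time step since the previous update, ps (> 0).
#' @return the updated `memory_state`.
#' @export
update_memory <- function(mem, value, dt) {
  stopifnot(inherits(mem, "memory_state"), dt > 0,
            length(value) == length(mem$S))
  decay <- exp(-dt / mem$tau)
  mem$N <- mem$N * decay + dt
  mem$S <- mem$S * decay + value * dt
  mem$t <- mem$t + dt
  mem
}

#' Current exponential-memory mean
#'
#' @param mem a `memory_state` that has received at least one update.
#' @return the memory mean (length `dim`).
#' @export
memory_mean <- function(mem) {
  if (mem$N <= 0) stop("memory_state has not been updated yet")
  mem$S / mem$N
}

#' Pseudo-force ramp factor
#'
#' Pseudo-forces are switched on exponentially, `1 - exp(-t/rho)`, so that
#' the early trajectory (before memory means exist) is not distorted.
#'
#' @param t time since the start of the run, ps.
#' @param rho rise time, ps. Defaults to the memory time tau in a full run.
#' @return dimensionless factor in \[0, 1).
#' @export
ramp_factor <- function(t, rho) {
  stopifnot(all(t >= 0), rho > 0)
  1 - exp(-t / rho)
}
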