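# Three-element (RCR) Windkessel outlet model.

#' Windkessel parameters
#'
#' Three-element Windkessel: proximal resistance `Rp` in series with a
#' parallel compliance `C` / distal resistance `Rd` pair.
#'
#' @param Rp Proximal (characteristic) resistance (Pa s/m^3).
#' @param C Compliance (m^3/Pa).
#' @param Rd Distal resistance (Pa s/m^3).
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(Rp, C, Rd) {
  if (any(!is.finite(c(Rp, C, Rd))) || any(c(Rp, C, Rd) <= 0))
    stop("Rp, C and Rd must all be strictly positive")
  structure(list(Rp = Rp, C = C, Rd = Rd), class = "windkessel_params")
}

#' Input impedance of the three-element Windkessel
#'
#' `Z(omega) = Rp + Rd / (1 + i omega Rd C)`. The analytic oracle for the
#' time-domain integrator: a sinusoidal flow of amplitude `Qa` at angular
#' frequency `omega` produces, at periodicity, a pressure oscillation of
#' amplitude `Qa |Z(omega)|`.
#'
#' @param params A `windkessel_params`.
#' @param omega Angular frequency (rad/s), vectorized.
#' @return Complex impedance (Pa s/m^3).
#' @export
impedance <- function(params, omega) {
  if (any(omega < 0)) stop("omega must be >= 0")
  params$Rp + params$Rd / (1 + 1i * omega * params$Rd * params$C)
}

#' Integrate the Windkessel ODE to a periodic pressure solution
#'
#' Integrates `P + Rd C dP/dt = (Rp + Rd) Q + Rp Rd C dQ/dt` with an
#' implicit trapezoidal step (A-stable, second order) over repeated cycles
#' until the maximum absolute pressure difference between consecutive
#' cycles falls below `tol`. `dQ/dt` comes from periodic central
#' differences of the sampled waveform.
#'
#' @param params A `windkessel_params`.
#' @param waveform A `flow_waveform`.
#' @param cycles Maximum number of cycles (>= 1).
#' @param dt Time step (s); must divide the period.
#' @param P0 Initial pressure (Pa).
#' @param tol Cycle-to-cycle max-norm convergence tolerance (Pa).
#' @return An object of class `pressure_trace`: `times` and `P` over the
#'   final cycle, `periodicity_residual` (Pa), `cycles_run`, `converged`.
#'   Non-convergence within the cycle cap is reported with a warning and
#'   the residual.
#' @export
simulate_windkessel <- function(params, waveform, cycles = 50L, dt = NULL,
                                P0 = 0, tol = 1) {
  stopifnot(inherits(params, "windkessel_params"),
            inherits(waveform, "flow_waveform"))
  if (cycles < 1L) stop("cycles must be >= 1")
  T_cyc <- waveform$period
  if (is.null(dt)) dt <- T_cyc / 1000
  n_steps <- round(T_cyc / dt)
  if (abs(n_steps * dt - T_cyc) > 1e-9 * T_cyc)
    stop("dt must divide the period")

  tau <- params$Rd * params$C
  rhs <- function(t) {
    ((params$Rp + params$Rd) * waveform$Q_fun(t) +
       params$Rp * tau * waveform$dQ_fun(t)) / tau
  }
  t_grid <- seq(0, T_cyc, length.out = n_steps + 1L)
  f_grid <- rhs(t_grid)                  # periodic: same every cycle

  a <- dt / (2 * tau)
  P <- P0
  prev_cycle <- NULL
  residual <- Inf
  cycles_run <- 0L
  for (cyc in seq_len(cycles)) {
    trace <- numeric(n_steps + 1L)
    trace[1] <- P
    for (k in seq_len(n_steps)) {
      P <- (P * (1 - a) + (dt / 2) * (f_grid[k] + f_grid[k + 1L])) / (1 + a)
      trace[k + 1L] <- P
    }
    cycles_run <- cyc
    if (!is.null(prev_cycle)) {
      residual <- max(abs(trace - prev_cycle))
      if (residual < tol) { prev_cycle <- trace; break }
    }
    prev_cycle <- trace
  }
  converged <- residual < tol
  if (!converged)
    warning(sprintf("Windkessel not periodic after %d cycles (residual %.3g Pa)",
                    cycles_run, residual))
  structure(list(times = t_grid, P = prev_cycle,
                 periodicity_residual = residual,
                 cycles_run = cycles_run, converged = converged,
                 params = params),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("Periodic pressure trace: P in [%.4g, %.4g] Pa (%.1f-%.1f mmHg)\n",
              min(x$P), max(x$P), min(x$P) / 133.322, max(x$P) / 133.322))
  cat(sprintf("  %d cycles, periodicity residual %.3g Pa (%s)\n",
              x$cycles_run, x$periodicity_residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
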