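#' Radon-222 decay constant
#'
#' Default decay constant for radon-222, 7.56e-3 h-1 (half-life about
#' 3.82 days). All rates in the package are per hour.
#'
#' @export
radon_decay_constant <- 7.56e-3

#' Physical parameters of the three-compartment mass-balance model
#'
#' Bundles every physical symbol of the dynamic indoor-radon model: the
#' effective exhalation rates of soil and building materials, the diffusive
#' and advective transfer coefficients, the soil-indoor pressure difference,
#' the coupling geometry (ground-facing area, material surface area, indoor
#' volume) and the sinks (radioactive decay, outdoor concentration for the
#' ventilation exchange).
#'
#' @param Es effective radon exhalation rate of soil (Bq m-2 h-1).
#' @param Ebm effective radon exhalation rate of building materials
#'   (Bq m-2 h-1).
#' @param kd_s diffusion transfer coefficient of soil (m h-1).
#' @param kd_bm diffusion transfer coefficient of building materials (m h-1).
#' @param ka advection transfer coefficient of soil (m Pa-1 h-1).
#' @param dP_si soil-indoor pressure difference (Pa).
#' @param Sg building area towards the ground (m2), > 0.
#' @param Sbm indoor surface area of radon-containing building materials
#'   (m2), >= 0.
#' @param V indoor volume (m3), > 0.
#' @param lam radon decay constant (h-1); default [radon_decay_constant].
#' @param Co outdoor radon concentration (Bq m-3).
#' @return An object of class \code{mass_balance_params}.
#' @examples
#' p <- mass_balance_params(Es = 20, Ebm = 1, kd_s = 0.1, kd_bm = 0.05,
#'                          ka = 0.02, dP_si = 2, Sg = 80, Sbm = 200,
#'                          V = 240, Co = 10)
#' @export
mass_balance_params <- function(Es, Ebm, kd_s, kd_bm, ka, dP_si,
                                Sg, Sbm, V, lam = radon_decay_constant,
                                Co = 0) {
  check_nonneg(Es, "Es"); check_nonneg(Ebm, "Ebm")
  check_nonneg(kd_s, "kd_s"); check_nonneg(kd_bm, "kd_bm")
  check_nonneg(ka, "ka")
  check_num(dP_si, "dP_si")
  check_pos(Sg, "Sg"); check_nonneg(Sbm, "Sbm"); check_pos(V, "V")
  check_pos(lam, "lam"); check_nonneg(Co, "Co")
  structure(list(Es = Es, Ebm = Ebm, kd_s = kd_s, kd_bm = kd_bm,
                 ka = ka, dP_si = dP_si, Sg = Sg, Sbm = Sbm, V = V,
                 lam = lam, Co = Co),
            class = "mass_balance_params")
}

#' @export
print.mass_balance_params <- function(x, ...) {
  cat("Mass-balance parameters (rates h-1, areas m2, volume m3):\n")
  cat(sprintf("  exhalation Es = %g, Ebm = %g Bq m-2 h-1\n", x$Es, x$Ebm))
  cat(sprintf("  transfer kd_s = %g, kd_bm = %g m h-1; ka = %g m Pa-1 h-1, dP = %g Pa\n",
              x$kd_s, x$kd_bm, x$ka, x$dP_si))
  cat(sprintf("  geometry Sg = %g, Sbm = %g m2, V = %g m3\n", x$Sg, x$Sbm, x$V))
  cat(sprintf("  decay lam = %g h-1, outdoor Co = %g Bq m-3\n", x$lam, x$Co))
  invisible(x)
}

#' Meteorological and behavioural inputs of the ventilation model
#'
#' @param ft temperature fitting parameter (h-1 degC-1), >= 0.
#' @param fw wind fitting parameter (h-1 s2 m-2), >= 0.
#' @param Ti,To indoor and outdoor temperatures (degC).
#' @param u wind speed (m s-1), >= 0.
#' @param N habit-weighted ventilation multiplier (dimensionless), >= 0.
#' @return An object of class \code{ventilation_inputs}.
#' @seealso [ventilation_rate()]
#' @export
ventilation_inputs <- function(ft, fw, Ti, To, u, N = 1) {
  check_nonneg(ft, "ft"); check_nonneg(fw, "fw")
  check_num(Ti, "Ti"); check_num(To, "To")
  check_nonneg(u, "u"); check_nonneg(N, "N")
  structure(list(ft = ft, fw = fw, Ti = Ti, To = To, u = u, N = N),
            class = "ventilation_inputs")
}

#' Ventilation (air-exchange) rate from meteorology and habits
#'
#' The air-exchange sink term for indoor radon is modelled as
#' \deqn{\lambda_v = (f_t |T_i - T_o| + f_w u^2)\,N} in h-1: a stack-effect
#' term proportional to the absolute indoor-outdoor temperature difference
#' plus a wind-pressure term quadratic in wind speed, scaled by the
#' habit-weighted ventilation multiplier N.
#'
#' @param ft temperature fitting parameter (h-1 degC-1), or a
#'   [ventilation_inputs()] object bundling all six inputs.
#' @param fw,Ti,To,u,N individual inputs (ignored when \code{ft} is a
#'   \code{ventilation_inputs} object). Vectorized.
#' @return Ventilation rate(s) in h-1, non-negative, linear in \code{N}.
#' @examples
#' ventilation_rate(ft = 0.01, fw = 0.005, Ti = 20, To = 0, u = 2)  # 0.22
#' @export
ventilation_rate <- function(ft, fw = NULL, Ti = NULL, To = NULL,
                             u = NULL, N = 1) {
  if (inherits(ft, "ventilation_inputs")) {
    v <- ft
    ft <- v$ft; fw <- v$fw; Ti <- v$Ti; To <- v$To; u <- v$u; N <- v$N
  } else {
    check_nonneg(ft, "ft"); check_nonneg(fw, "fw")
    check_num(Ti, "Ti"); check_num(To, "To")
    check_nonneg(u, "u"); check_nonneg(N, "N")
  }
  (ft * abs(Ti - To) + fw * u^2) * N
}

#' Steady-state indoor radon concentration
#'
#' Closed-form fixed point of the indoor compartment: with total entry rate
#' S from soil and building materials, ventilation exchange with outdoor air
#' at rate \code{lam_v}, back-transfer to source compartments at
#' concentrations \code{Cs}, \code{Cbm}, and radioactive decay \code{lam},
#' \deqn{C_i = \frac{S + \lambda_v C_o - \lambda (C_s + C_{bm})}{\lambda + \lambda_v}.}
#'
#' For physically inconsistent inputs the algebraic value can be negative;
#' the value is returned unchanged with a warning (clamping would break the
#' exact inverse relationship with [infiltration_from_measurement()]).
#'
#' @param S infiltration factor, the combined entry concentration rate
#'   (Bq m-3 h-1).
#' @param Cs,Cbm soil and building-material compartment concentrations
#'   (Bq m-3); \code{Cbm} defaults to 0 under the approximation that entry
#'   from building materials is small relative to soil.
#' @param Co outdoor radon concentration (Bq m-3).
#' @param lam radon decay constant (h-1), > 0.
#' @param lam_v ventilation rate (h-1), >= 0.
#' @return Indoor radon concentration(s), Bq m-3. Vectorized.
#' @examples
#' steady_state_ci(S = 10, Cs = 100, Co = 10, lam = 7.56e-3, lam_v = 0.34)
#' @export
steady_state_ci <- function(S, Cs = 0, Cbm = 0, Co = 0,
                            lam = radon_decay_constant, lam_v) {
  check_num(S, "S")
  check_nonneg(Cs, "Cs"); check_nonneg(Cbm, "Cbm"); check_nonneg(Co, "Co")
  check_pos(lam, "lam"); check_nonneg(lam_v, "lam_v")
  ci <- (S + lam_v * Co - lam * (Cs + Cbm)) / (lam + lam_v)
  if (any(ci < 0))
    warning("steady-state indoor concentration is negative for ",
            sum(ci < 0), " input(s); returning the algebraic value")
  ci
}

#' Infiltration factor from a measured indoor concentration
#'
#' Exact algebraic inverse of [steady_state_ci()]: given an (annual-mean)
#' measured indoor concentration and the sink/source environment, the
#' combined radon entry rate from soil and building materials is
#' \deqn{S = C_i(\lambda + \lambda_v) + \lambda (C_s + C_{bm}) - \lambda_v C_o.}
#'
#' @param Ci measured indoor radon concentration (Bq m-3).
#' @inheritParams steady_state_ci
#' @return Infiltration factor(s) S, Bq m-3 h-1. Vectorized.
#' @examples
#' S <- infiltration_from_measurement(Ci = 36.4, Cs = 100, Co = 10,
#'                                    lam = 7.56e-3, lam_v = 0.34)
#' @export
infiltration_from_measurement <- function(Ci, Cs = 0, Cbm = 0, Co = 0,
                                          lam = radon_decay_constant, lam_v) {
  check_num(Ci, "Ci")
  check_nonneg(Cs, "Cs"); check_nonneg(Cbm, "Cbm"); check_nonneg(Co, "Co")
  check_pos(lam, "lam"); check_nonneg(lam_v, "lam_v")
  Ci * (lam + lam_v) + lam * (Cs + Cbm) - lam_v * Co
}

# internal: coefficient matrix A and constant vector b of the linear system
# d/dt (Ci, Cs, Cbm) = A %*% x + b for given parameters and ventilation rate
mass_balance_system <- function(p, lam_v) {
  a1 <- p$Sg / p$V
  a2 <- p$Sbm / p$V
  A <- matrix(c(
    -(p$kd_s * a1 + p$kd_bm * a2 + lam_v + p$lam),
    (p$kd_s + p$ka * p$dP_si) * a1,
    p$kd_bm * a2,
    p$kd_s * a1,
    -((p$kd_s + p$ka * p$dP_si) * a1 + p$lam),
    0,
    p$kd_bm * a2,
    0,
    -(p$kd_bm * a2 + p$lam)
  ), nrow = 3, byrow = TRUE)
  b <- c(lam_v * p$Co, p$Es * a1, p$Ebm * a2)
  list(A = A, b = b)
}

#' Fixed point of the dynamic model by direct linear solve
#'
#' The three coupled compartment equations are linear in the state, so the
#' steady state is the solution of a 3x3 linear system. This is the
#' independent closed-form counterpart of [simulate_dynamics()].
#'
#' @param p a [mass_balance_params()] object.
#' @param v a [ventilation_inputs()] object, or a precomputed ventilation
#'   rate (h-1) given as a plain number.
#' @return Named numeric vector \code{c(Ci, Cs, Cbm)}, Bq m-3.
#' @export
steady_state_solution <- function(p, v) {
  stopifnot(inherits(p, "mass_balance_params"))
  lam_v <- if (inherits(v, "ventilation_inputs")) ventilation_rate(v) else
    check_nonneg(v, "lam_v")
  sys <- mass_balance_system(p, lam_v)
  x <- solve(sys$A, -sys$b)
  names(x) <- c("Ci", "Cs", "Cbm")
  x
}

#' Integrate the dynamic three-compartment radon model
#'
#' Numerically integrates the coupled mass-balance equations for the
#' indoor-air, soil and building-material compartments: diffusive and
#' advective transfer from soil scaled by Sg/V, diffusive transfer from
#' building materials scaled by Sbm/V, ventilation exchange with outdoor
#' air, and radioactive decay of every compartment. Uses a stiff-capable
#' adaptive integrator (\code{deSolve::lsoda}) at rtol 1e-8.
#'
#' @param p a [mass_balance_params()] object.
#' @param v a [ventilation_inputs()] object or a ventilation rate (h-1).
#' @param init named numeric vector \code{c(Ci=, Cs=, Cbm=)} of non-negative
#'   initial concentrations (Bq m-3).
#' @param t_end integration horizon (h), > 0.
#' @param times output times; default \code{seq(0, t_end, length.out = 101)}.
#' @param rtol,atol integrator tolerances.
#' @return A data.frame with columns \code{t, Ci, Cs, Cbm}; the trajectory
#'   converges to [steady_state_solution()] of the same system.
#' @export
simulate_dynamics <- function(p, v, init = c(Ci = 0, Cs = 0, Cbm = 0),
                              t_end, times = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "mass_balance_params"))
  check_pos(t_end, "t_end")
  check_nonneg(init, "init")
  stopifnot(length(init) == 3L)
  lam_v <- if (inherits(v, "ventilation_inputs")) ventilation_rate(v) else
    check_nonneg(v, "lam_v")
  sys <- mass_balance_system(p, lam_v)
  if (is.null(times)) times <- seq(0, t_end, length.out = 101L)
  deriv <- function(t, y, parms) list(as.vector(parms$A %*% y + parms$b))
  y0 <- c(Ci = unname(init[1]), Cs = unname(init[2]), Cbm = unname(init[3]))
  out <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = sys,
                        rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  names(out)[1] <- "t"
  if (any(!is.finite(as.matrix(out))))
    stop("integration produced non-finite values; check parameter magnitudes")
  out
}

#' Annual effective dose from radon exposure
#'
#' The standard dose product \eqn{E = Q \times F \times T \times K}: mean
#' annual radon concentration, equilibrium factor between radon and its
#' short-lived progeny, annual residential time, and the dose conversion
#' coefficient. The result carries the units implied by K (e.g. Sv per
#' Bq h m-3 gives E in Sv).
#'
#' @param Q mean annual radon concentration (Bq m-3), >= 0.
#' @param F_eq equilibrium factor (dimensionless), >= 0.
#' @param T_occ annual residential time (h), >= 0.
#' @param K dose conversion coefficient, >= 0.
#' @return Annual effective dose. Vectorized.
#' @examples
#' annual_effective_dose(Q = 50, F_eq = 0.4, T_occ = 7000, K = 9e-9)
#' @export
annual_effective_dose <- function(Q, F_eq, T_occ, K) {
  check_nonneg(Q, "Q"); check_nonneg(F_eq, "F_eq")
  check_nonneg(T_occ, "T_occ"); check_nonneg(K, "K")
  Q * F_eq * T_occ * K
}
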