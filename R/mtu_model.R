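# Hill-type muscle-tendon-unit mechanics: piecewise serial elastic tendon,
# bell-shaped active force-length, Hill force-velocity with eccentric plateau,
# parallel elastic element, first-order activation dynamics, and the
# initialization/scaling rules used to place every strand in a length
# equilibrium at simulation start.

#' Serial elastic element (tendon) parameters
#'
#' The tendon is modelled as a piecewise force-elongation law with a convex
#' "toe" region followed by a linear region. It is parameterized by the force
#' at the non-linear/linear transition (as a fraction of the strand's maximum
#' isometric force), the relative stretch at that transition, the relative
#' stretch in the linear part that produces one further transition-force
#' increment, and the tendon rest length. The toe exponent
#' `nu_see = dU_see_nll / dU_see_l` is derived so the curve is continuously
#' differentiable at the transition.
#'
#' The shipped defaults are the generic tendon parameter set
#' (`0.4 Fmax`, `0.0425`, `0.017`); the much stiffer tuned set obtained by
#' calibration against positional-tendon stress-strain data is
#' (`0.8 Fmax`, `0.02`, `0.01`), see [fit_see()].
#'
#' @param dF_see_0_frac Force at the non-linear/linear transition, as a
#'   fraction of `Fmax` (dimensionless, `(0, 1.5]`).
#' @param dU_see_nll Relative stretch (engineering strain on the tendon rest
#'   length) at the non-linear/linear transition.
#' @param dU_see_l Relative stretch in the linear part producing a force
#'   increase of `dF_see_0_frac * Fmax`.
#' @param l_see_0 Tendon rest length in m. May be `NA` for curve-level work
#'   (stress-strain calibration) where only strains are involved.
#' @return An object of class `see_params`.
#' @seealso [see_force()], [see_young_modulus()], [init_equilibrium()]
#' @export
see_params <- function(dF_see_0_frac = 0.4, dU_see_nll = 0.0425,
                       dU_see_l = 0.017, l_see_0 = NA_real_) {
  stopifnot(is.numeric(dF_see_0_frac), is.numeric(dU_see_nll),
            is.numeric(dU_see_l))
  if (!all(is.finite(c(dF_see_0_frac, dU_see_nll, dU_see_l)))) {
    stop("SEE parameters must be finite")
  }
  if (dF_see_0_frac <= 0 || dF_see_0_frac > 1.5) {
    stop("dF_see_0_frac must be in (0, 1.5]")
  }
  if (dU_see_nll <= 0 || dU_see_l <= 0) {
    stop("SEE stretch parameters must be strictly positive")
  }
  if (dU_see_nll <= dU_see_l) {
    stop("dU_see_nll must exceed dU_see_l (toe exponent nu_see > 1)")
  }
  if (!is.na(l_see_0) && l_see_0 <= 0) stop("l_see_0 must be positive")
  structure(list(
    dF_see_0_frac = dF_see_0_frac,
    dU_see_nll = dU_see_nll,
    dU_see_l = dU_see_l,
    nu_see = dU_see_nll / dU_see_l,
    l_see_0 = l_see_0
  ), class = "see_params")
}

#' Tendon force from the serial elastic element
#'
#' Evaluates the piecewise tendon force-elongation law at tendon length
#' `l_see`. With engineering strain `eps = (l_see - l_see_0) / l_see_0` and
#' transition force `dF = dF_see_0_frac * Fmax`:
#' zero for `eps <= 0` (slack tendon); `dF * (eps / dU_see_nll)^nu_see` in the
#' toe region `0 < eps < dU_see_nll`; and
#' `dF * (1 + (eps - dU_see_nll) / dU_see_l)` in the linear region. The
#' derived exponent `nu_see = dU_see_nll / dU_see_l` makes force and stiffness
#' continuous at the transition.
#'
#' @param see A [see_params()] object with a finite `l_see_0`.
#' @param Fmax Maximum isometric force of the strand (N).
#' @param l_see Tendon length (m); vectorized.
#' @return Tendon force (N), same length as `l_see`.
#' @export
see_force <- function(see, Fmax, l_see) {
  stopifnot(inherits(see, "see_params"))
  if (!is.finite(see$l_see_0)) stop("see_force needs a finite l_see_0")
  if (!all(is.finite(l_see)) || !all(is.finite(Fmax))) {
    stop("non-finite input to see_force")
  }
  if (any(l_see < 0)) stop("l_see must be non-negative")
  eps <- (l_see - see$l_see_0) / see$l_see_0
  see_force_strain(see, Fmax, eps)
}

# Strain-domain tendon force; shared by see_force() and the stress-strain
# calibration where no rest length is involved.
see_force_strain <- function(see, Fmax, eps) {
  dF <- see$dF_see_0_frac * Fmax
  nu <- see$nu_see
  f <- numeric(length(eps))
  toe <- eps > 0 & eps < see$dU_see_nll
  lin <- eps >= see$dU_see_nll
  if (length(dF) > 1) {
    f[toe] <- dF[toe] * (eps[toe] / see$dU_see_nll)^nu
    f[lin] <- dF[lin] * (1 + (eps[lin] - see$dU_see_nll) / see$dU_see_l)
  } else {
    f[toe] <- dF * (eps[toe] / see$dU_see_nll)^nu
    f[lin] <- dF * (1 + (eps[lin] - see$dU_see_nll) / see$dU_see_l)
  }
  f
}

#' Young's modulus of the tendon model
#'
#' The tendon's Young's modulus is the slope of its linear-branch
#' stress-strain relation:
#' `E = (dF_see_0_frac * Fmax / dU_see_l) / csa`. It is invariant under a
#' simultaneous rescaling of `Fmax` and `csa`, i.e. it depends on the
#' parameter fractions and the normalization stress `Fmax / csa` only.
#'
#' @param see A [see_params()] object.
#' @param Fmax Maximum isometric force (N).
#' @param csa Tendon cross-sectional area (m^2).
#' @return Young's modulus in Pa.
#' @export
see_young_modulus <- function(see, Fmax, csa) {
  stopifnot(inherits(see, "see_params"))
  if (!is.finite(csa) || csa <= 0) stop("csa must be positive")
  if (!is.finite(Fmax) || Fmax <= 0) stop("Fmax must be positive")
  (see$dF_see_0_frac * Fmax / see$dU_see_l) / csa
}

#' Contractile element parameters
#'
#' Bell-shaped active force-length relation
#' `exp(-|((l_ce/l_ce_opt) - 1) / dW|^nu)` with separate ascending and
#' descending branch widths/exponents, classic Hill force-velocity constants
#' on the concentric side, and a plateaued eccentric branch whose slope at
#' zero velocity is `S_ecc` times the concentric slope. Width/exponent and
#' Hill constants are documented defaults (generic skeletal-muscle values);
#' every field is overridable.
#'
#' @param l_ce_opt Optimal fiber length (m).
#' @param dW_asc,dW_desc Bell widths of the ascending/descending branch
#'   (dimensionless, `(0, 1]`).
#' @param nu_asc,nu_desc Bell exponents.
#' @param a_rel,b_rel Hill constants; `a_rel` dimensionless, `b_rel` in 1/s
#'   (normalized to optimal fiber lengths per second).
#' @param F_ecc Eccentric force plateau as a multiple of the isometric force
#'   (> 1).
#' @param S_ecc Eccentric-to-concentric slope factor at zero velocity.
#' @return An object of class `ce_params`.
#' @export
ce_params <- function(l_ce_opt, dW_asc = 0.45, dW_desc = 0.45,
                      nu_asc = 2.0, nu_desc = 2.0,
                      a_rel = 0.25, b_rel = 2.25,
                      F_ecc = 1.5, S_ecc = 2.0) {
  if (!is.finite(l_ce_opt) || l_ce_opt <= 0) stop("l_ce_opt must be positive")
  if (dW_asc <= 0 || dW_asc > 1 || dW_desc <= 0 || dW_desc > 1) {
    stop("bell widths must lie in (0, 1]")
  }
  if (F_ecc <= 1) stop("F_ecc must exceed 1")
  stopifnot(a_rel > 0, b_rel > 0, S_ecc > 0, nu_asc >= 1, nu_desc >= 1)
  structure(list(l_ce_opt = l_ce_opt, dW_asc = dW_asc, dW_desc = dW_desc,
                 nu_asc = nu_asc, nu_desc = nu_desc, a_rel = a_rel,
                 b_rel = b_rel, F_ecc = F_ecc, S_ecc = S_ecc),
            class = "ce_params")
}

#' Isometric force-length factor of the contractile element
#'
#' @param ce A [ce_params()] object.
#' @param l_ce Fiber length (m); vectorized.
#' @return Dimensionless factor in `(0, 1]`, 1 at the optimal fiber length.
#' @export
ce_isometric_factor <- function(ce, l_ce) {
  stopifnot(inherits(ce, "ce_params"))
  if (!all(is.finite(l_ce))) stop("non-finite l_ce")
  if (any(l_ce <= 0)) stop("l_ce must be positive")
  lam <- l_ce / ce$l_ce_opt
  dW <- ifelse(lam < 1, ce$dW_asc, ce$dW_desc)
  nu <- ifelse(lam < 1, ce$nu_asc, ce$nu_desc)
  exp(-abs((lam - 1) / dW)^nu)
}

# Hill force-velocity factor, relative to the current isometric force
# a * Fmax * f_isom. v_hat is the fiber velocity in optimal fiber lengths
# per second, lengthening positive.
fv_factor <- function(ce, v_hat) {
  ar <- ce$a_rel; br <- ce$b_rel
  be <- (ce$F_ecc - 1) * br / (ce$S_ecc * (1 + ar))
  conc <- (1 + ar) * br / (br - pmin(v_hat, 0)) - ar
  ecc <- ce$F_ecc - (ce$F_ecc - 1) * be / (be + pmax(v_hat, 0))
  ifelse(v_hat <= 0, pmax(conc, 0), ecc)
}

#' Parallel elastic element parameters
#'
#' Passive fiber stiffness engaging beyond a slack length expressed as a
#' fraction of the optimal fiber length. The force is scaled so that it
#' reaches `F_pee * Fmax` when the fiber is stretched to the end of the
#' descending force-length limb (`l_ce = l_ce_opt * (1 + dW_desc)`).
#'
#' @param L_pee_0 Slack length as a fraction of `l_ce_opt`.
#' @param F_pee Force scale as a fraction of `Fmax`.
#' @param nu_pee Exponent (>= 1).
#' @return An object of class `pee_params`.
#' @export
pee_params <- function(L_pee_0 = 1.0, F_pee = 0.5, nu_pee = 2.5) {
  stopifnot(L_pee_0 > 0, F_pee >= 0, nu_pee >= 1)
  structure(list(L_pee_0 = L_pee_0, F_pee = F_pee, nu_pee = nu_pee),
            class = "pee_params")
}

#' Passive parallel elastic force
#'
#' @param pee A [pee_params()] object.
#' @param ce The matching [ce_params()] object (for `l_ce_opt`, `dW_desc`).
#' @param Fmax Maximum isometric force (N).
#' @param l_ce Fiber length (m); vectorized.
#' @return Passive force (N), zero below the slack length.
#' @export
pee_force <- function(pee, ce, Fmax, l_ce) {
  lam <- l_ce / ce$l_ce_opt
  span <- 1 + ce$dW_desc - pee$L_pee_0
  out <- numeric(length(lam))
  on <- lam > pee$L_pee_0
  out[on] <- pee$F_pee * Fmax * ((lam[on] - pee$L_pee_0) / span)^pee$nu_pee
  out
}

#' Activation dynamics parameters
#'
#' First-order activation dynamics with asymmetric time constants and a
#' minimum activation floor representing resting muscle tone.
#'
#' @param tau_act Activation time constant (s).
#' @param tau_deact Deactivation time constant (s).
#' @param a_min Minimum activation (dimensionless, `[0, 1)`).
#' @return An object of class `activation_params`.
#' @export
activation_params <- function(tau_act = 0.010, tau_deact = 0.040,
                              a_min = 0.005) {
  stopifnot(tau_act > 0, tau_deact > 0, a_min >= 0, a_min < 1)
  structure(list(tau_act = tau_act, tau_deact = tau_deact, a_min = a_min),
            class = "activation_params")
}

#' One exact step of first-order activation dynamics
#'
#' Uses the closed-form exponential update
#' `a + (u - a) * (1 - exp(-dt / tau))` with `tau = tau_act` when the neural
#' input exceeds the current activation and `tau_deact` otherwise, so the
#' step is independent of the surrounding integrator. The result is clamped
#' to `[a_min, 1]`.
#'
#' @param act An [activation_params()] object.
#' @param a Current activation in `[0, 1]`; vectorized.
#' @param u Neural input in `[0, 1]`; vectorized.
#' @param dt Time step (s).
#' @return Updated activation, same length as `a`.
#' @export
activation_step <- function(act, a, u, dt) {
  stopifnot(inherits(act, "activation_params"), dt > 0)
  stopifnot(all(a >= 0 & a <= 1), all(u >= 0 & u <= 1))
  tau <- ifelse(u >= a, act$tau_act, act$tau_deact)
  a_new <- a + (u - a) * (1 - exp(-dt / tau))
  pmin(1, pmax(act$a_min, a_new))
}

#' Muscle-tendon-unit parameter bundle
#'
#' @param name Strand identifier, conventionally `"<muscle> <digit>"`
#'   (e.g. `"FDP 3"`).
#' @param Fmax Maximum isometric force of this strand (N), typically from
#'   [scale_fmax()].
#' @param csa Tendon cross-sectional area (m^2).
#' @param see,ce,pee,act Component parameter objects.
#' @param group `"flexor"` or `"extensor"`; selects the length-equilibrium
#'   scaling factor in [init_equilibrium()].
#' @param d_se Linear serial damping coefficient (N s/m) acting on the tendon
#'   stretch rate; defaults to `0.02 * Fmax / (b_rel * l_ce_opt)`. The
#'   damping suppresses the undamped force oscillations a purely elastic
#'   series tendon would show at very low activation.
#' @return An object of class `mtu_params`.
#' @export
mtu_params <- function(name, Fmax, csa, see, ce, pee = pee_params(),
                       act = activation_params(),
                       group = c("flexor", "extensor"), d_se = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(see, "see_params"), inherits(ce, "ce_params"),
            inherits(pee, "pee_params"), inherits(act, "activation_params"))
  if (!is.finite(Fmax) || Fmax <= 0) stop("Fmax must be positive")
  if (!is.finite(csa) || csa <= 0) stop("csa must be positive")
  if (is.null(d_se)) d_se <- 0.02 * Fmax / (ce$b_rel * ce$l_ce_opt)
  stopifnot(d_se >= 0)
  structure(list(name = name, Fmax = Fmax, csa = csa, see = see, ce = ce,
                 pee = pee, act = act, group = group, d_se = d_se),
            class = "mtu_params")
}

#' Strand specification for splitting a whole muscle into parallel strands
#'
#' Muscles whose tendons reach several digits are modelled as parallel
#' strands, one per tendon path; the whole-muscle maximum isometric force is
#' divided evenly so the strand forces sum back to the source-table value.
#'
#' @param Fmax_T Whole-muscle maximum isometric force (N).
#' @param n_s Number of parallel strands (integer >= 1).
#' @return An object of class `strand_spec`.
#' @export
strand_spec <- function(Fmax_T, n_s) {
  if (!is.finite(Fmax_T) || Fmax_T <= 0) stop("Fmax_T must be positive")
  if (length(n_s) != 1 || !is.finite(n_s) || n_s < 1 || n_s != round(n_s)) {
    stop("n_s must be a positive integer")
  }
  structure(list(Fmax_T = Fmax_T, n_s = as.integer(n_s)),
            class = "strand_spec")
}

#' Per-strand maximum isometric force
#'
#' `Fmax_s = Fmax_T / n_s`; summing over the strands recovers the
#' whole-muscle value exactly.
#'
#' @param spec A [strand_spec()] object.
#' @return Per-strand maximum isometric force (N).
#' @export
scale_fmax <- function(spec) {
  stopifnot(inherits(spec, "strand_spec"))
  spec$Fmax_T / spec$n_s
}

#' Muscle-tendon-unit dynamic state
#'
#' @param a Activation in `[a_min, 1]`.
#' @param l_ce Fiber length (m).
#' @param l_mtu Current origin-to-insertion path length (m).
#' @return An object of class `mtu_state`.
#' @export
mtu_state <- function(a, l_ce, l_mtu) {
  stopifnot(is.finite(a), is.finite(l_ce), is.finite(l_mtu), l_ce > 0)
  structure(list(a = a, l_ce = l_ce, l_mtu = l_mtu), class = "mtu_state")
}

#' Initial length equilibrium of a strand
#'
#' Places the strand in a length equilibrium at the first simulation step:
#' the fiber starts at its optimal length and the tendon rest length absorbs
#' the remainder of the (scaled) path length,
#' `l_see_0 = c_e_f * l_mtu_i - l_ce_opt`. The scaling factor artificially
#' shortens extensor paths (`c = 0.95`) and elongates flexor paths
#' (`c = 1.05`) to encode their compressed/stretched state in the straight
#' initial finger posture.
#'
#' @param l_mtu_i Initial path length (m).
#' @param l_ce_opt Optimal fiber length (m).
#' @param group `"flexor"` or `"extensor"`.
#' @param c_e_f Named scaling pair, default `c(flexor = 1.05, extensor = 0.95)`.
#' @param name Optional strand name, used in error messages.
#' @return List with `l_ce_i` (= `l_ce_opt`) and the derived tendon rest
#'   length `l_see_0`, satisfying `c_e_f * l_mtu_i = l_ce_i + l_see_0`.
#' @export
init_equilibrium <- function(l_mtu_i, l_ce_opt,
                             group = c("flexor", "extensor"),
                             c_e_f = c(flexor = 1.05, extensor = 0.95),
                             name = NULL) {
  group <- match.arg(group)
  cc <- unname(c_e_f[[group]])
  l_see_0 <- cc * l_mtu_i - l_ce_opt
  if (!is.finite(l_see_0) || l_see_0 <= 0) {
    stop(sprintf("infeasible length equilibrium for strand '%s': l_see_0 = %.4g m",
                 if (is.null(name)) "?" else name, l_see_0))
  }
  list(l_ce_i = l_ce_opt, l_see_0 = l_see_0)
}

#' Static outputs of a muscle-tendon unit
#'
#' Tendon strain `eps_see = (l_mtu - l_ce - l_see_0) / l_see_0` (engineering
#' strain on the tendon rest length; negative when slack) and the transmitted
#' force `F_mtu = see_force(l_see)` (zero when slack).
#'
#' @param params An [mtu_params()] object with a finite `l_see_0`.
#' @param state An [mtu_state()] object.
#' @return List with `F_mtu` (N) and `eps_see` (dimensionless).
#' @export
mtu_outputs <- function(params, state) {
  stopifnot(inherits(params, "mtu_params"), inherits(state, "mtu_state"))
  l_see <- state$l_mtu - state$l_ce
  if (l_see < 0) stop("state not initialized: l_see < 0")
  eps <- (l_see - params$see$l_see_0) / params$see$l_see_0
  list(F_mtu = see_force(params$see, params$Fmax, l_see), eps_see = eps)
}

# Residual of the series force balance at fiber velocity v_ce (m/s):
#   F_see(l_see) + d_se (v_mtu - v_ce)
#     - [ a Fmax f_isom(l_ce) f_v(v_ce) + F_pee(l_ce) ]
mtu_force_residual <- function(params, state, v_mtu, v_ce) {
  l_see <- state$l_mtu - state$l_ce
  F_see <- see_force(params$see, params$Fmax, l_see)
  F_pee <- pee_force(params$pee, params$ce, params$Fmax, state$l_ce)
  f_iso <- ce_isometric_factor(params$ce, state$l_ce)
  f_v <- fv_factor(params$ce, v_ce / params$ce$l_ce_opt)
  F_see + params$d_se * (v_mtu - v_ce) -
    (state$a * params$Fmax * f_iso * f_v + F_pee)
}

#' Fiber contraction rate from the series force balance
#'
#' Solves `F_SEE(l_mtu - l_ce) + F_SDE = a Fmax F_isom(l_ce) f_v(v_ce) +
#' F_PEE(l_ce)` for the fiber velocity `v_ce` with a bracketed scalar root
#' find on `v_ce` in `[-20, 20] * l_ce_opt` per second (absolute tolerance
#' 1e-10 m/s). `F_SDE = d_se * (v_mtu - v_ce)` is the optional serial damping
#' force. Sign contract: when the tendon force exceeds the maximal force the
#' fiber can hold isometrically the fiber lengthens (`v_ce > 0`), and vice
#' versa.
#'
#' @param params An [mtu_params()] object.
#' @param state An [mtu_state()] object (initialized, `l_see >= 0`).
#' @param v_mtu Path lengthening rate (m/s).
#' @return Fiber velocity `v_ce` (m/s), lengthening positive.
#' @seealso [fiber_velocity()] for the vectorized closed-form inversion used
#'   inside the simulator.
#' @export
contraction_rate <- function(params, state, v_mtu = 0) {
  stopifnot(inherits(params, "mtu_params"), inherits(state, "mtu_state"))
  if (state$l_mtu - state$l_ce < 0) stop("state not initialized: l_see < 0")
  vcap <- 20 * params$ce$l_ce_opt
  f <- function(v) mtu_force_residual(params, state, v_mtu, v)
  r_lo <- f(-vcap); r_hi <- f(vcap)
  if (is.na(r_lo) || is.na(r_hi) || r_lo * r_hi > 0) {
    # residual is decreasing in v_ce; same-signed ends mean the root lies
    # outside the physiological bracket
    stop(sprintf(
      "no sign change in contraction-rate bracket: residual(%.3g) = %.6g, residual(%.3g) = %.6g",
      -vcap, r_lo, vcap, r_hi))
  }
  stats::uniroot(f, c(-vcap, vcap), tol = 1e-10)$root
}

#' Closed-form fiber velocity (vectorized)
#'
#' Analytic inversion of the series force balance solved numerically by
#' [contraction_rate()]. Because the Hill force-velocity relation is a
#' hyperbola on each branch, the balance including a linear serial damping
#' term reduces to a quadratic in the fiber velocity per branch; the branch
#' is selected by comparing the elastic tendon + damping load against the
#' isometric force available at zero fiber velocity. Inputs are vectors over
#' strands.
#'
#' @param F_see Tendon elastic force (N).
#' @param F_pee Parallel elastic force (N).
#' @param M Available isometric force `a * Fmax * f_isom` (N).
#' @param ce A [ce_params()] object (shared Hill constants) or a list of
#'   per-strand values `a_rel`, `b_rel`, `F_ecc`, `S_ecc`.
#' @param l_ce_opt Optimal fiber lengths (m).
#' @param d_se Serial damping coefficients (N s/m).
#' @param v_mtu Path lengthening rates (m/s).
#' @return Fiber velocities (m/s), lengthening positive.
#' @export
fiber_velocity <- function(F_see, F_pee, M, ce, l_ce_opt, d_se, v_mtu) {
  ar <- ce$a_rel; br <- ce$b_rel
  Fe <- ce$F_ecc
  be <- (Fe - 1) * br / (ce$S_ecc * (1 + ar))
  A <- F_see + d_se * v_mtu - F_pee
  D <- d_se * l_ce_opt          # damping per unit normalized velocity
  n <- length(A)
  w <- numeric(n)               # normalized fiber velocity (1/s)
  ecc <- A > M
  con <- A < M
  # eccentric branch: D h^2 - (A + D be - M Fe) h - M (Fe - 1) be = 0,
  # h = be + w
  if (any(ecc)) {
    Ae <- A[ecc]; Me <- M[ecc]; De <- D[ecc]
    C <- Ae + De * be - Me * Fe
    hasD <- De > 0
    h <- numeric(length(Ae))
    h[hasD] <- (C[hasD] + sqrt(C[hasD]^2 +
      4 * De[hasD] * Me[hasD] * (Fe - 1) * be)) / (2 * De[hasD])
    if (any(!hasD)) {
      # undamped: invert the eccentric hyperbola, clamped at the bracket cap
      fr <- Ae[!hasD] / pmax(Me[!hasD], .Machine$double.eps)
      wnd <- ifelse(fr < Fe, be * (fr - 1) / (Fe - fr), 20)
      h[!hasD] <- be + pmin(wnd, 20)
    }
    w[ecc] <- h - be
  }
  # concentric branch: D g^2 + (A + M ar - D br) g - M (1 + ar) br = 0,
  # g = br - w
  if (any(con)) {
    Ac <- A[con]; Mc <- M[con]; Dc <- D[con]
    B <- Ac + Mc * ar - Dc * br
    hasD <- Dc > 0
    g <- numeric(length(Ac))
    g[hasD] <- (-B[hasD] + sqrt(B[hasD]^2 +
      4 * Dc[hasD] * Mc[hasD] * (1 + ar) * br)) / (2 * Dc[hasD])
    if (any(!hasD)) {
      denom <- Ac[!hasD] + Mc[!hasD] * ar
      gnd <- ifelse(denom > 0, Mc[!hasD] * (1 + ar) * br / denom, Inf)
      # force demand at or below zero: clamp at maximal shortening speed
      g[!hasD] <- pmin(gnd, br + br / ar)
    }
    wc <- br - g
    # past the maximal shortening speed the active force is clamped at
    # zero and the serial damping alone balances the (negative) demand
    past <- wc < -br / ar
    if (any(past)) {
      wc[past] <- ifelse(Dc[past] > 0, Ac[past] / Dc[past], -br / ar)
    }
    w[con] <- wc
  }
  # wide safety clamp only; the damped balance keeps velocities finite
  pmax(pmin(w, 1000), -1000) * l_ce_opt
}
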