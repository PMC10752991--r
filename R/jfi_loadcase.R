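# Two-stage grip-and-rod-retraction load case. Stage 1 (0 to t_R): the
# flexor strands receive a step neural input and close the digits around a
# rigid cylindrical rod held fixed in the palm; a tied coupling engages at
# the tie activation time to keep the grip from being pushed open. Stage 2
# (t_R to t_end, optional): the rod is retracted with a semi-instantaneous
# prescribed velocity, forcing the digits open and loading the flexors
# eccentrically. Rod motion is kinematic; digit chains and muscle fiber
# lengths are integrated with a fixed-step 4th-order Runge-Kutta scheme.

#' Rigid rod configuration
#'
#' @param length Rod length (m); geometric bookkeeping only, the planar
#'   model sees the circular cross-section.
#' @param diameter Rod diameter (m).
#' @param center Rod center position in the hand frame (m).
#' @param retraction_velocity Retraction speed (m/s).
#' @param velocity_ramp_time Time to ramp linearly from rest to the
#'   retraction speed (s); the "semi-instantaneous" pull.
#' @param direction Unit retraction direction in the hand frame (default:
#'   palmar, straight out of the grip).
#' @return An object of class `rod_config`.
#' @export
rod_config <- function(length = 0.100, diameter = 0.020,
                       center = c(0.025, -0.030),
                       retraction_velocity = 11.615,
                       velocity_ramp_time = 0.001,
                       direction = c(0, -1)) {
  stopifnot(diameter > 0, retraction_velocity >= 0, velocity_ramp_time > 0,
            length(center) == 2, length(direction) == 2)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(length = length, diameter = diameter, radius = diameter / 2,
                 center = center, retraction_velocity = retraction_velocity,
                 velocity_ramp_time = velocity_ramp_time,
                 direction = direction),
            class = "rod_config")
}

#' Contact and tie parameters
#'
#' Penalty contact between finger surface nodes and the rod circle with
#' regularized Coulomb friction, plus a stiff elastic tie engaging at the
#' tie activation time for nodes then in contact. A tie releases permanently
#' once its elongation exceeds the breakaway value, after which only the
#' unilateral penalty contact acts (the rod can slip free).
#'
#' @param mu_static,mu_dynamic Static/dynamic friction coefficients.
#' @param penalty_stiffness Contact normal stiffness (N/m).
#' @param penalty_damping Contact normal damping (N s/m).
#' @param tie_activation_time Time at which the tie engages (s).
#' @param tie_stiffness Tie spring stiffness (N/m).
#' @param tie_damping Tie damping (N s/m).
#' @param tie_breakaway_elongation Tie breakaway elongation (m).
#' @param v_reg Friction regularization velocity (m/s) of the stateless
#'   [contact_force()] law: sliding faster than a few `v_reg` sees the
#'   dynamic coefficient.
#' @param fr_stiffness Tangential stick stiffness (N/m) of the
#'   elastic-anchor Coulomb friction used inside the integrator.
#' @param fr_damping Tangential damping (N s/m) of the same.
#' @param node_radius Effective surface radius of a finger contact node (m),
#'   added to the rod radius.
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(mu_static = 0.4, mu_dynamic = 0.3,
                           penalty_stiffness = 1e5, penalty_damping = 50,
                           tie_activation_time = 0.080,
                           tie_stiffness = 2e5, tie_damping = 50,
                           tie_breakaway_elongation = 0.005,
                           v_reg = 1e-3, fr_stiffness = 2e4,
                           fr_damping = 10, node_radius = 0.004) {
  stopifnot(mu_dynamic >= 0, mu_dynamic <= mu_static,
            penalty_stiffness > 0, penalty_damping >= 0, tie_stiffness > 0,
            tie_breakaway_elongation > 0, v_reg > 0, fr_stiffness > 0,
            fr_damping >= 0, node_radius >= 0)
  structure(list(mu_static = mu_static, mu_dynamic = mu_dynamic,
                 penalty_stiffness = penalty_stiffness,
                 penalty_damping = penalty_damping,
                 tie_activation_time = tie_activation_time,
                 tie_stiffness = tie_stiffness, tie_damping = tie_damping,
                 tie_breakaway_elongation = tie_breakaway_elongation,
                 v_reg = v_reg, fr_stiffness = fr_stiffness,
                 fr_damping = fr_damping, node_radius = node_radius),
            class = "contact_params")
}

#' Load case configuration
#'
#' @param activation Flexor activation level `a` in `[0, 1]` (step neural
#'   input at t = 0, filtered by the activation dynamics).
#' @param retract Retract the rod in stage 2? (`FALSE` for the model-check
#'   run.)
#' @param t_R Start of rod retraction / end of the grip phase (s).
#' @param t_end Simulation end time (s).
#' @param dt Integration step (s).
#' @param sample_dt Output sampling interval (s), at least 1 kHz.
#' @param seed Integer seed (stored for provenance; the load case itself is
#'   deterministic).
#' @return An object of class `load_case_config`.
#' @export
load_case_config <- function(activation = 1, retract = TRUE, t_R = 0.100,
                             t_end = 0.200, dt = 2e-5, sample_dt = 5e-4,
                             seed = 1L) {
  stopifnot(activation >= 0, activation <= 1, t_R < t_end, dt > 0,
            sample_dt >= dt, sample_dt <= 1e-3)
  structure(list(activation = activation, retract = isTRUE(retract),
                 t_R = t_R, t_end = t_end, dt = dt, sample_dt = sample_dt,
                 seed = as.integer(seed)),
            class = "load_case_config")
}

#' Penalty contact force between a point and the rod
#'
#' Zero when separated. Under penetration the normal force is
#' `penalty_stiffness * penetration + penalty_damping * penetration rate`
#' (clamped non-negative) along the outward circle normal; the tangential
#' friction force opposes the sliding velocity with a regularized Coulomb
#' magnitude that approaches `mu_dynamic * normal` beyond a few `v_reg` of
#' sliding speed and never exceeds `mu_static * normal`.
#'
#' @param rod A [rod_config()] object.
#' @param point Length-2 point position (m).
#' @param params A [contact_params()] object.
#' @param rel_velocity Velocity of the point relative to the rod (m/s).
#' @param rod_center Rod center (defaults to the configured pose).
#' @return Length-2 contact force vector (N) acting on the point.
#' @export
contact_force <- function(rod, point, params, rel_velocity = c(0, 0),
                          rod_center = rod$center) {
  stopifnot(all(is.finite(point)), all(is.finite(rel_velocity)))
  d <- point - rod_center
  dist <- sqrt(sum(d^2))
  reff <- rod$radius + params$node_radius
  if (dist >= reff || dist == 0) return(c(0, 0))
  n <- d / dist
  pen <- reff - dist
  pen_dot <- -sum(n * rel_velocity)
  Fn <- max(0, params$penalty_stiffness * pen + params$penalty_damping * pen_dot)
  tvec <- c(-n[2], n[1])
  vt <- sum(tvec * rel_velocity)
  mu <- params$mu_dynamic + (params$mu_static - params$mu_dynamic) *
    exp(-abs(vt) / (3 * params$v_reg))
  Ft <- -mu * Fn * tanh(vt / params$v_reg)
  Fn * n + Ft * tvec
}

# Rod center and velocity at time t.
rod_state <- function(rod, cfg, t) {
  if (!cfg$retract || t <= cfg$t_R) {
    return(list(c = rod$center, v = c(0, 0)))
  }
  s <- t - cfg$t_R
  vr <- rod$retraction_velocity
  ramp <- rod$velocity_ramp_time
  if (s < ramp) {
    v <- vr * s / ramp
    disp <- vr * s^2 / (2 * ramp)
  } else {
    v <- vr
    disp <- vr * (ramp / 2 + (s - ramp))
  }
  list(c = rod$center + rod$direction * disp, v = rod$direction * v)
}

# Flatten per-strand parameters into vectors ordered like the scene paths.
strand_table <- function(model) {
  sc <- model$scene
  mt <- model$mtus[sc$path_names]
  ce1 <- mt[[1]]$ce
  list(
    names = sc$path_names,
    muscle = vapply(strsplit(sc$path_names, " "), `[[`, "", 1),
    Fmax = vapply(mt, `[[`, 1, "Fmax"),
    d_se = vapply(mt, `[[`, 1, "d_se"),
    flexor = vapply(mt, function(m) m$group == "flexor", TRUE),
    dF = vapply(mt, function(m) m$see$dF_see_0_frac * m$Fmax, 1),
    nll = vapply(mt, function(m) m$see$dU_see_nll, 1),
    dl = vapply(mt, function(m) m$see$dU_see_l, 1),
    nu = vapply(mt, function(m) m$see$nu_see, 1),
    l0 = vapply(mt, function(m) m$see$l_see_0, 1),
    l_opt = vapply(mt, function(m) m$ce$l_ce_opt, 1),
    dW_asc = ce1$dW_asc, dW_desc = ce1$dW_desc,
    nu_asc = ce1$nu_asc, nu_desc = ce1$nu_desc,
    ce = ce1,
    pee_L0 = vapply(mt, function(m) m$pee$L_pee_0, 1),
    pee_F = vapply(mt, function(m) m$pee$F_pee * m$Fmax, 1),
    pee_nu = vapply(mt, function(m) m$pee$nu_pee, 1),
    a_min = vapply(mt, function(m) m$act$a_min, 1),
    tau_act = vapply(mt, function(m) m$act$tau_act, 1),
    tau_deact = vapply(mt, function(m) m$act$tau_deact, 1))
}

see_force_vec <- function(st, l_see) {
  eps <- (l_see - st$l0) / st$l0
  f <- numeric(length(eps))
  toe <- eps > 0 & eps < st$nll
  lin <- eps >= st$nll
  f[toe] <- st$dF[toe] * (eps[toe] / st$nll[toe])^st$nu[toe]
  f[lin] <- st$dF[lin] * (1 + (eps[lin] - st$nll[lin]) / st$dl[lin])
  f
}

pee_force_vec <- function(st, l_ce) {
  lam <- l_ce / st$l_opt
  span <- 1 + st$dW_desc - st$pee_L0
  x <- pmax(0, (lam - st$pee_L0) / span)
  st$pee_F * x^st$pee_nu
}

f_isom_vec <- function(st, l_ce) {
  lam <- l_ce / st$l_opt
  dW <- ifelse(lam < 1, st$dW_asc, st$dW_desc)
  nu <- ifelse(lam < 1, st$nu_asc, st$nu_desc)
  exp(-abs((lam - 1) / dW)^nu)
}

# Chain accelerations for all digits from origins and applied torques.
chain_qdd <- function(sc, Ox, Oy, cTH, sTH, tau, density) {
  nd <- sc$nd
  L <- sc$Lseg
  tipx <- Ox[, 4] + L[, 3] * cTH[, 4]
  tipy <- Oy[, 4] + L[, 3] * sTH[, 4]
  # segment endpoints: joints 1..3 at Ox[,2:4], distal end of segment k
  ex <- cbind(Ox[, 3], Ox[, 4], tipx)
  ey <- cbind(Oy[, 3], Oy[, 4], tipy)
  comx <- (Ox[, 2:4] + ex) / 2
  comy <- (Oy[, 2:4] + ey) / 2
  cx <- Ox[, 2:4, drop = FALSE]; cy <- Oy[, 2:4, drop = FALSE]
  m <- t(density * t(L)); Ic <- m * L^2 / 12
  qdd <- matrix(0, nd, 3)
  for (d in seq_len(nd)) {
    M <- matrix(0, 3, 3)
    for (k in 1:3) {
      for (i in 1:k) for (j in i:k) {
        v <- m[d, k] * ((comy[d, k] - cy[d, i]) * (comy[d, k] - cy[d, j]) +
                        (comx[d, k] - cx[d, i]) * (comx[d, k] - cx[d, j])) +
          Ic[d, k]
        M[i, j] <- M[i, j] + v
        if (i != j) M[j, i] <- M[j, i] + v
      }
    }
    qdd[d, ] <- solve(M, tau[d, ])
  }
  qdd
}

#' Run the two-stage grip and rod-retraction load case
#'
#' Stage 1: the FDP/FDS strands receive neural input `u = activation`
#' (extensors stay at their minimum activation) and flex the digits around
#' the fixed rod; the tie coupling engages at the configured time for nodes
#' then in contact. Stage 2 (if `retract`): the rod velocity ramps to the
#' retraction speed and the rod is pulled out of the grip. The run is
#' deterministic given its configuration.
#'
#' @param model A [hand_model()] (e.g. from [gen_hand_fixture()]).
#' @param cfg A [load_case_config()].
#' @param rod A [rod_config()].
#' @param contact A [contact_params()].
#' @return An object of class `jfi_simulation`: time grid, per-strand MTU
#'   force, tendon strain, fiber length and activation matrices, joint
#'   angle/velocity matrices, per-digit contact normal force, rod position,
#'   a `gripped` flag (contact present at `t_R`) and the configuration
#'   echo.
#' @export
run_load_case <- function(model, cfg = load_case_config(),
                          rod = rod_config(), contact = contact_params()) {
  stopifnot(inherits(model, "hand_model"), inherits(cfg, "load_case_config"),
            inherits(rod, "rod_config"), inherits(contact, "contact_params"))
  sc <- model$scene
  st <- strand_table(model)
  nd <- sc$nd; nm <- length(st$names)
  reff <- rod$radius + contact$node_radius

  # per-joint passive parameter vectors [nd, 3]
  jp <- function(f) t(vapply(names(model$digits), function(d)
    vapply(model$joints[[d]], `[[`, 1, f), numeric(3)))
  k_j <- jp("stiffness"); c_j <- jp("damping")
  kl_j <- jp("limit_stiffness"); cl_j <- jp("limit_damping")
  qr_j <- jp("q_rest")
  rom_lo <- t(vapply(names(model$digits), function(d)
    vapply(model$joints[[d]], function(j) j$rom[1], 1), numeric(3)))
  rom_hi <- t(vapply(names(model$digits), function(d)
    vapply(model$joints[[d]], function(j) j$rom[2], 1), numeric(3)))

  u <- ifelse(st$flexor & st$muscle %in% c("FDP", "FDS"),
              cfg$activation, st$a_min)
  u <- pmax(u, st$a_min)

  q <- matrix(0, nd, 3); qd <- matrix(0, nd, 3)
  l_ce <- st$l_opt            # initial length equilibrium: fiber at optimum
  a <- pmax(st$a_min, 0)

  tie_node <- integer(0); tie_offx <- numeric(0); tie_offy <- numeric(0)
  tie_on <- logical(0)
  tie_engaged <- FALSE
  n_nodes <- length(sc$node_d)
  # tangential stick anchors of the elastic Coulomb friction, stored as
  # node offsets in the (translating) rod frame; NA = no anchor
  fr_ax <- rep(NA_real_, n_nodes); fr_ay <- rep(NA_real_, n_nodes)

  rhs <- function(t, q, qd, l_ce, diag = FALSE) {
    sev <- scene_eval(sc, q, qdot = qd, need_nodes = TRUE)
    l_mtu <- sev$L
    v_mtu <- sev$v_path
    l_see <- l_mtu - l_ce
    F_see <- see_force_vec(st, pmax(l_see, 0))
    F_pee <- pee_force_vec(st, l_ce)
    M_iso <- a * st$Fmax * f_isom_vec(st, l_ce)
    v_ce <- fiber_velocity(F_see, F_pee, M_iso, st$ce, st$l_opt, st$d_se,
                           v_mtu)
    F_mtu <- pmax(0, F_see + st$d_se * (v_mtu - v_ce))

    # joint torques: muscle (r_j = -dL/dq_j), passive, ROM penalty
    tau <- -k_j * (q - qr_j) - c_j * qd
    over <- q > rom_hi; under <- q < rom_lo
    tau[over] <- tau[over] - kl_j[over] * (q[over] - rom_hi[over]) -
      cl_j[over] * qd[over]
    tau[under] <- tau[under] - kl_j[under] * (q[under] - rom_lo[under]) -
      cl_j[under] * qd[under]
    mus <- -sev$dL * F_mtu
    for (j in 1:3) {
      agg <- rowsum(mus[, j], sc$path_digit)
      dd <- as.integer(rownames(agg))
      tau[cbind(dd, j)] <- tau[cbind(dd, j)] + as.numeric(agg)
    }

    rs <- rod_state(rod, cfg, t)
    dx <- sev$Nx - rs$c[1]; dy <- sev$Ny - rs$c[2]
    dist <- sqrt(dx * dx + dy * dy)
    pen <- reff - dist
    act <- pen > 0 & dist > 0
    Fx <- numeric(length(dx)); Fy <- numeric(length(dx))
    if (any(act)) {
      ai <- which(act)
      nx <- dx[ai] / dist[ai]; ny <- dy[ai] / dist[ai]
      rvx <- sev$Nvx[ai] - rs$v[1]; rvy <- sev$Nvy[ai] - rs$v[2]
      pen_dot <- -(nx * rvx + ny * rvy)
      Fn <- pmax(0, contact$penalty_stiffness * pen[ai] +
                   contact$penalty_damping * pen_dot)
      vt <- -ny * rvx + nx * rvy
      # elastic-anchor Coulomb friction: tangential spring from the stick
      # anchor, clamped by the static cone (anchors slip between steps)
      Ft <- numeric(length(ai))
      have <- !is.na(fr_ax[ai])
      if (any(have)) {
        ddx <- dx[ai] - fr_ax[ai]; ddy <- dy[ai] - fr_ay[ai]
        disp_t <- -ny * ddx + nx * ddy
        Ftr <- -contact$fr_stiffness * disp_t - contact$fr_damping * vt
        cap <- contact$mu_static * Fn
        Ft[have] <- pmax(pmin(Ftr[have], cap[have]), -cap[have])
      }
      Fx[ai] <- Fn * nx + Ft * (-ny)
      Fy[ai] <- Fn * ny + Ft * nx
    }
    if (length(tie_node) && any(tie_on)) {
      tn <- tie_node[tie_on]
      tx <- rs$c[1] + tie_offx[tie_on] - sev$Nx[tn]
      ty <- rs$c[2] + tie_offy[tie_on] - sev$Ny[tn]
      Fx[tn] <- Fx[tn] + contact$tie_stiffness * tx +
        contact$tie_damping * (rs$v[1] - sev$Nvx[tn])
      Fy[tn] <- Fy[tn] + contact$tie_stiffness * ty +
        contact$tie_damping * (rs$v[2] - sev$Nvy[tn])
    }
    has_f <- Fx != 0 | Fy != 0
    if (any(has_f)) {
      for (j in 1:3) {
        contrib <- sev$NJx[has_f, j] * Fx[has_f] +
          sev$NJy[has_f, j] * Fy[has_f]
        agg <- rowsum(contrib, sc$node_d[has_f])
        dd <- as.integer(rownames(agg))
        tau[cbind(dd, j)] <- tau[cbind(dd, j)] + as.numeric(agg)
      }
    }

    qdd <- chain_qdd(sc, sev$Ox, sev$Oy, sev$cTH, sev$sTH, tau,
                     model$density)
    out <- list(qd = qd, qdd = qdd, dl_ce = v_ce)
    if (diag) {
      eps_see <- (l_see - st$l0) / st$l0
      ncf <- numeric(nd)
      if (any(act)) {
        Fn_all <- numeric(length(dx)); Fn_all[act] <- Fn
        agg <- rowsum(Fn_all, sc$node_d)
        ncf[as.integer(rownames(agg))] <- as.numeric(agg)
      }
      out$F_mtu <- F_mtu; out$eps_see <- eps_see
      out$contact_n <- ncf; out$pen <- pen; out$rod_c <- rs$c
      out$tau_net <- tau
    }
    out
  }

  dt <- cfg$dt
  n_steps <- round(cfg$t_end / dt)
  sample_every <- max(1L, round(cfg$sample_dt / dt))
  nt <- floor(n_steps / sample_every) + 1
  Tm <- numeric(nt)
  Fm <- matrix(0, nt, nm, dimnames = list(NULL, st$names))
  Em <- matrix(0, nt, nm, dimnames = list(NULL, st$names))
  Lm <- matrix(0, nt, nm, dimnames = list(NULL, st$names))
  Am <- matrix(0, nt, nm, dimnames = list(NULL, st$names))
  Qm <- matrix(0, nt, nd * 3, dimnames = list(NULL, paste0(
    rep(names(model$digits), each = 3), "_", c("MCP", "PIP", "DIP"))))
  Cm <- matrix(0, nt, nd, dimnames = list(NULL, names(model$digits)))
  Rm <- matrix(0, nt, 2, dimnames = list(NULL, c("rod_x", "rod_y")))
  TauM <- matrix(0, nt, nd * 3, dimnames = list(NULL, colnames(Qm)))
  Qdm <- matrix(0, nt, nd * 3, dimnames = list(NULL, colnames(Qm)))
  record <- function(row, t) {
    dg <- rhs(t, q, qd, l_ce, diag = TRUE)
    Tm[row] <<- t
    Fm[row, ] <<- dg$F_mtu; Em[row, ] <<- dg$eps_see
    Lm[row, ] <<- l_ce; Am[row, ] <<- a
    Qm[row, ] <<- as.numeric(t(q)); Qdm[row, ] <<- as.numeric(t(qd))
    Cm[row, ] <<- dg$contact_n
    Rm[row, ] <<- dg$rod_c; TauM[row, ] <<- as.numeric(t(dg$tau_net))
    dg
  }
  record(1, 0)
  gripped <- FALSE
  row <- 1
  for (step in seq_len(n_steps)) {
    t0 <- (step - 1) * dt
    # exact exponential activation update, integrator-independent
    tau_a <- ifelse(u >= a, st$tau_act, st$tau_deact)
    a <- pmin(1, pmax(st$a_min, a + (u - a) * (1 - exp(-dt / tau_a))))

    k1 <- rhs(t0, q, qd, l_ce)
    k2 <- rhs(t0 + dt / 2, q + dt / 2 * k1$qd, qd + dt / 2 * k1$qdd,
              l_ce + dt / 2 * k1$dl_ce)
    k3 <- rhs(t0 + dt / 2, q + dt / 2 * k2$qd, qd + dt / 2 * k2$qdd,
              l_ce + dt / 2 * k2$dl_ce)
    k4 <- rhs(t0 + dt, q + dt * k3$qd, qd + dt * k3$qdd,
              l_ce + dt * k3$dl_ce)
    q <- q + dt / 6 * (k1$qd + 2 * k2$qd + 2 * k3$qd + k4$qd)
    qd <- qd + dt / 6 * (k1$qdd + 2 * k2$qdd + 2 * k3$qdd + k4$qdd)
    l_ce <- l_ce + dt / 6 * (k1$dl_ce + 2 * k2$dl_ce + 2 * k3$dl_ce +
                             k4$dl_ce)
    l_ce <- pmax(l_ce, 0.2 * st$l_opt)
    t1 <- step * dt
    if (!all(is.finite(q)) || !all(is.finite(qd)) || !all(is.finite(l_ce))) {
      stop(sprintf("integration diverged at t = %.5f s", t1))
    }

    # contact-state management between steps: friction anchors and ties
    sev <- scene_eval(sc, q, need_nodes = TRUE)
    rs <- rod_state(rod, cfg, t1)
    dxx <- sev$Nx - rs$c[1]; dyy <- sev$Ny - rs$c[2]
    dist <- sqrt(dxx^2 + dyy^2)
    inc <- dist < reff & dist > 0
    fr_ax[!inc] <- NA_real_; fr_ay[!inc] <- NA_real_
    if (any(inc)) {
      fresh <- inc & is.na(fr_ax)
      fr_ax[fresh] <- dxx[fresh]; fr_ay[fresh] <- dyy[fresh]
      held <- which(inc & !is.na(fr_ax))
      if (length(held)) {
        nx <- dxx[held] / dist[held]; ny <- dyy[held] / dist[held]
        disp_t <- -ny * (dxx[held] - fr_ax[held]) +
          nx * (dyy[held] - fr_ay[held])
        N_est <- contact$penalty_stiffness * (reff - dist[held])
        slip_max <- contact$mu_dynamic * N_est / contact$fr_stiffness
        disp_new <- pmax(pmin(disp_t, slip_max), -slip_max)
        # re-anchor: keep only the admissible tangential offset
        fr_ax[held] <- dxx[held] - (-ny) * disp_new
        fr_ay[held] <- dyy[held] - nx * disp_new
      }
    }
    if (!tie_engaged && t1 >= contact$tie_activation_time) {
      sel <- which(dist < reff + 5e-4)
      tie_node <- sel
      tie_offx <- dxx[sel]; tie_offy <- dyy[sel]
      tie_on <- rep(TRUE, length(sel))
      tie_engaged <- TRUE
    } else if (tie_engaged && any(tie_on)) {
      tn <- tie_node
      el <- sqrt((rs$c[1] + tie_offx - sev$Nx[tn])^2 +
                 (rs$c[2] + tie_offy - sev$Ny[tn])^2)
      tie_on <- tie_on & el <= contact$tie_breakaway_elongation
    }

    if (step %% sample_every == 0) {
      row <- row + 1
      dg <- record(row, t1)
      if (!gripped && t1 <= cfg$t_R && any(dg$pen > 0)) gripped <- TRUE
    }
  }
  if (!gripped) {
    warning("grip failure: no rod contact established during stage 1")
  }
  structure(list(time = Tm, F_mtu = Fm, eps_see = Em, l_ce = Lm,
                 activation = Am, q = Qm, qdot = Qdm, contact_n = Cm,
                 rod = Rm, tau_net = TauM,
                 strand_names = st$names, muscle = st$muscle,
                 flexor = st$flexor, Fmax = st$Fmax, l_opt = st$l_opt,
                 gripped = gripped, cfg = cfg, rod_cfg = rod,
                 contact_cfg = contact),
            class = "jfi_simulation")
}

#' Muscle activation effectiveness
#'
#' `eta_a = F_bar_MTU / F_bar_max * 100`, where `F_bar_MTU` is the mean over
#' the FDP and FDS strands of each strand's maximum MTU force during the
#' grip phase (`0` to `t_R`) and `F_bar_max` is the mean of the same
#' strands' maximum isometric forces.
#'
#' @param result A `jfi_simulation` from [run_load_case()].
#' @return List of class `effectiveness_result` with `a`, `F_bar_mtu`,
#'   `F_bar_max` (N) and `eta_a` (percent).
#' @export
activation_effectiveness <- function(result) {
  stopifnot(inherits(result, "jfi_simulation"))
  sel <- result$muscle %in% c("FDP", "FDS") & result$flexor
  if (!any(sel)) stop("no FDP/FDS flexor strands in result")
  win <- result$time <= result$cfg$t_R
  peak <- apply(result$F_mtu[win, sel, drop = FALSE], 2, max)
  F_bar <- mean(peak)
  F_bar_max <- mean(result$Fmax[sel])
  structure(list(a = result$cfg$activation, F_bar_mtu = F_bar,
                 F_bar_max = F_bar_max,
                 eta_a = 100 * F_bar / F_bar_max),
            class = "effectiveness_result")
}

#' Injury assessment of one simulation
#'
#' Applies the avulsion force criterion to each FDP/FDS strand's MTU force
#' series, the tendon strain criterion to its tendon strain series, and the
#' muscle strain criterion (when thresholds are configured) to its fiber
#' strain series.
#'
#' @param result A `jfi_simulation`.
#' @param thresholds An [injury_thresholds()] object.
#' @return List of `injury_finding` objects (three per strand; the muscle
#'   strain finding is marked not evaluated when no thresholds are set).
#' @export
assess_run <- function(result, thresholds = injury_thresholds()) {
  sel <- which(result$muscle %in% c("FDP", "FDS") & result$flexor)
  out <- list()
  for (i in sel) {
    nm <- result$strand_names[i]
    out[[length(out) + 1]] <- assess_avulsion(result$time, result$F_mtu[, i],
                                              thresholds, nm)
    out[[length(out) + 1]] <- assess_tsic(result$time, result$eps_see[, i],
                                          thresholds, nm)
    fib <- result$l_ce[, i] / result$l_opt[i] - 1
    out[[length(out) + 1]] <- assess_msic(result$time, fib,
                                          thresholds$msic, nm)
  }
  out
}

#' Run the full simulation protocol
#'
#' Eight retraction runs on the activation grid 0, 20, 40, 60, 70, 80, 90,
#' 100% plus one model-check run at 100% activation without retraction, for
#' nine simulations total. Each run is assessed with the injury criteria and
#' aggregated into a report table; a failed run is flagged and the protocol
#' continues.
#'
#' @param model A [hand_model()].
#' @param activations Activation grid for the retraction runs.
#' @param cfg Base [load_case_config()] (activation/retract overridden per
#'   run).
#' @param rod A [rod_config()].
#' @param contact A [contact_params()].
#' @param thresholds An [injury_thresholds()] object.
#' @return List of class `jfi_protocol`: per-run `results`, `findings`,
#'   `eta` (effectiveness per run) and the aggregated `report` data frame.
#' @export
run_protocol <- function(model,
                         activations = c(0, 0.2, 0.4, 0.6, 0.7, 0.8, 0.9, 1),
                         cfg = load_case_config(), rod = rod_config(),
                         contact = contact_params(),
                         thresholds = injury_thresholds()) {
  runs <- c(lapply(activations, function(a) list(a = a, retract = TRUE)),
            list(list(a = 1, retract = FALSE)))
  results <- vector("list", length(runs))
  findings <- vector("list", length(runs))
  eta <- rep(NA_real_, length(runs))
  failed <- logical(length(runs))
  for (i in seq_along(runs)) {
    ci <- cfg
    ci$activation <- runs[[i]]$a
    ci$retract <- runs[[i]]$retract
    res <- tryCatch(
      suppressWarnings(run_load_case(model, ci, rod, contact)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      findings[[i]] <- list()
      next
    }
    results[[i]] <- res
    findings[[i]] <- assess_run(res, thresholds)
    eta[i] <- activation_effectiveness(res)$eta_a
  }
  meta <- data.frame(
    simulation = seq_along(runs),
    a_pct = 100 * vapply(runs, `[[`, 1, "a"),
    eta_a_pct = eta,
    rod_retraction = vapply(runs, function(r) if (r$retract) "Yes" else "No",
                            ""),
    failed = failed)
  report <- build_report(findings, meta)
  structure(list(results = results, findings = findings, eta = eta,
                 report = report),
            class = "jfi_protocol")
}
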