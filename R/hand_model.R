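# Reduced-order planar digit mechanics: rigid phalanx chains with revolute
# MCP/PIP/DIP joints, via-point muscle routing, tendon-excursion moment arms
# and forward chain dynamics with passive stiffness and range-of-motion
# limits.
#
# Conventions: per-segment frames with x along the segment toward the distal
# tip and the palmar side at negative y; joint flexion angles in radians,
# flexion positive, 0 = straight finger. Segment ids: 0 = metacarpal (fixed
# base frame), 1 = proximal, 2 = middle, 3 = distal phalanx. Joint j
# (1 = MCP, 2 = PIP, 3 = DIP) connects segments j-1 and j.

#' Planar digit geometry
#'
#' @param digit_id Digit number, 2 (index) to 5 (little finger).
#' @param segment_lengths Numeric length-3 vector: proximal, middle, distal
#'   phalanx lengths (m).
#' @param metacarpal_anchor Fixed base position of the MCP joint center in
#'   the hand frame (m).
#' @return An object of class `digit_geometry`.
#' @export
digit_geometry <- function(digit_id, segment_lengths,
                           metacarpal_anchor = c(0, 0)) {
  stopifnot(digit_id %in% 2:5, length(segment_lengths) == 3,
            all(is.finite(segment_lengths)), all(segment_lengths > 0),
            length(metacarpal_anchor) == 2)
  structure(list(digit_id = as.integer(digit_id),
                 segment_lengths = as.numeric(segment_lengths),
                 metacarpal_anchor = as.numeric(metacarpal_anchor),
                 joint_order = c("MCP", "PIP", "DIP")),
            class = "digit_geometry")
}

#' Revolute joint parameters
#'
#' Passive rotational stiffness pulls toward the rest angle; a stiff penalty
#' torque engages beyond the range-of-motion limits.
#'
#' @param rom Length-2 vector of angle limits (rad), `rom[1] < rom[2]`.
#' @param stiffness Passive rotational stiffness (N m/rad).
#' @param damping Rotational damping (N m s/rad).
#' @param limit_stiffness Penalty stiffness beyond the ROM limits (N m/rad).
#' @param limit_damping Extra damping while beyond a limit (N m s/rad).
#' @param q_rest Rest angle of the passive stiffness (rad).
#' @return An object of class `revolute_joint`.
#' @export
revolute_joint <- function(rom = c(0, pi / 2), stiffness = 0.01,
                           damping = 0.001, limit_stiffness = 20,
                           limit_damping = 0.01, q_rest = 0) {
  stopifnot(length(rom) == 2, rom[1] < rom[2], stiffness >= 0, damping >= 0,
            limit_stiffness >= 0, limit_damping >= 0)
  structure(list(rom = as.numeric(rom), stiffness = stiffness,
                 damping = damping, limit_stiffness = limit_stiffness,
                 limit_damping = limit_damping, q_rest = q_rest),
            class = "revolute_joint")
}

#' Via-point routing path of one muscle strand
#'
#' @param mtu_name Name of the [mtu_params()] strand routed along this path.
#' @param via_points Data frame with columns `segment` (0..3), `x`, `y`
#'   (local coordinates in the segment frame, m), ordered from origin to
#'   insertion; at least two points, consecutive points on the same or an
#'   adjacent segment.
#' @param digit_id Digit the path belongs to.
#' @return An object of class `routing_path`.
#' @export
routing_path <- function(mtu_name, via_points, digit_id) {
  stopifnot(is.data.frame(via_points),
            all(c("segment", "x", "y") %in% names(via_points)))
  if (nrow(via_points) < 2) stop("a routing path needs at least two points")
  seg <- as.integer(via_points$segment)
  if (any(seg < 0 | seg > 3)) stop("segment ids must be 0..3")
  if (any(abs(diff(seg)) > 1)) {
    stop("consecutive via points must lie on the same or adjacent segments")
  }
  if (is.unsorted(seg)) stop("via points must be ordered from origin to insertion")
  structure(list(mtu_name = mtu_name,
                 via_points = data.frame(segment = seg,
                                         x = as.numeric(via_points$x),
                                         y = as.numeric(via_points$y)),
                 digit_id = as.integer(digit_id)),
            class = "routing_path")
}

#' Hand model: digit chains, joints, routing paths and muscle strands
#'
#' @param digits List of [digit_geometry()] objects (digits 2..5 or a
#'   subset).
#' @param joints List (parallel to `digits`) of length-3 lists of
#'   [revolute_joint()] objects in MCP, PIP, DIP order. A single length-3
#'   list is recycled across digits.
#' @param paths List of [routing_path()] objects.
#' @param mtus List of [mtu_params()] objects; names must cover every
#'   `mtu_name` referenced by `paths`. Flexor-group paths must run on the
#'   palmar side (all phalanx-frame via points at `y < 0`).
#' @param density Linear segment density (kg/m) used for chain inertia.
#' @param dt_max Largest admissible integration step (s) for
#'   [step_dynamics()].
#' @return An object of class `hand_model`.
#' @export
hand_model <- function(digits, joints, paths, mtus, density = 0.4,
                       dt_max = 2e-5) {
  stopifnot(length(digits) >= 1, density > 0)
  if (inherits(joints[[1]], "revolute_joint")) {
    joints <- rep(list(joints), length(digits))
  }
  stopifnot(length(joints) == length(digits))
  names(digits) <- paste0("d", vapply(digits, `[[`, 1L, "digit_id"))
  names(joints) <- names(digits)
  mtu_names <- vapply(mtus, `[[`, "", "name")
  names(mtus) <- mtu_names
  for (p in paths) {
    stopifnot(inherits(p, "routing_path"))
    if (!p$mtu_name %in% mtu_names) {
      stop(sprintf("path references unknown strand '%s'", p$mtu_name))
    }
    grp <- mtus[[p$mtu_name]]$group
    phal <- p$via_points$segment >= 1
    if (grp == "flexor" && any(p$via_points$y[phal] >= 0)) {
      stop(sprintf("flexor path '%s' must stay on the palmar side (y < 0)",
                   p$mtu_name))
    }
  }
  names(paths) <- vapply(paths, `[[`, "", "mtu_name")
  m <- structure(list(digits = digits, joints = joints, paths = paths,
                      mtus = mtus, density = density, dt_max = dt_max),
                 class = "hand_model")
  m$scene <- build_scene(m)
  m
}

#' Hand kinematic state
#'
#' @param q Matrix of joint angles (rad), one row per digit, columns MCP,
#'   PIP, DIP; a length-3 vector is treated as a single digit.
#' @param qdot Matching joint angular velocities (rad/s), defaults to zero.
#' @return An object of class `hand_state`.
#' @export
hand_state <- function(q, qdot = NULL) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (is.null(qdot)) qdot <- matrix(0, nrow(q), ncol(q))
  if (is.null(dim(qdot))) qdot <- matrix(qdot, nrow = 1)
  stopifnot(ncol(q) == 3, all(dim(q) == dim(qdot)),
            all(is.finite(q)), all(is.finite(qdot)))
  structure(list(q = q, qdot = qdot), class = "hand_state")
}

# Forward kinematics of one digit: segment-frame origins (rows: segment
# 0..3 origin, then fingertip) and world angles of segments 1..3.
fk_digit <- function(digit, q) {
  L <- digit$segment_lengths
  th <- -cumsum(q)
  o <- matrix(0, 5, 2)
  o[1, ] <- digit$metacarpal_anchor            # base frame / MCP center
  o[2, ] <- o[1, ]                             # proximal phalanx origin
  o[3, ] <- o[2, ] + L[1] * c(cos(th[1]), sin(th[1]))
  o[4, ] <- o[3, ] + L[2] * c(cos(th[2]), sin(th[2]))
  o[5, ] <- o[4, ] + L[3] * c(cos(th[3]), sin(th[3]))
  list(origins = o, th = th)
}

# World position of a point given in a segment frame of one digit.
point_world <- function(digit, q, segment, local) {
  fk <- fk_digit(digit, q)
  if (segment == 0) return(digit$metacarpal_anchor + local)
  th <- fk$th[segment]
  fk$origins[segment + 1, ] +
    c(cos(th) * local[1] - sin(th) * local[2],
      sin(th) * local[1] + cos(th) * local[2])
}

#' Length of a routing path at a given posture
#'
#' Polyline length through the via points after forward kinematics.
#'
#' @param digit A [digit_geometry()] object.
#' @param path A [routing_path()] object on that digit.
#' @param q Length-3 vector of joint angles (rad).
#' @return Path length (m).
#' @export
path_length <- function(digit, path, q) {
  stopifnot(length(q) == 3, all(is.finite(q)), all(abs(q) <= 2 * pi))
  vp <- path$via_points
  P <- t(vapply(seq_len(nrow(vp)), function(i) {
    point_world(digit, q, vp$segment[i], c(vp$x[i], vp$y[i]))
  }, numeric(2)))
  d <- sqrt(rowSums(diff(P)^2))
  if (any(d < 1e-12)) stop("coincident consecutive via points")
  sum(d)
}

#' Tendon-excursion moment arm
#'
#' The moment arm of a routing path about joint `joint_idx` is minus the
#' partial derivative of the path length with respect to that joint angle,
#' computed by central difference with `h = 1e-6` rad. Palmar (flexor) paths
#' yield positive flexion arms; mirroring a path to the dorsal side flips
#' the sign.
#'
#' @param digit A [digit_geometry()] object.
#' @param path A [routing_path()] object.
#' @param q Length-3 vector of joint angles (rad).
#' @param joint_idx Joint index: 1 = MCP, 2 = PIP, 3 = DIP.
#' @return Moment arm (m); zero with a warning if the path does not cross
#'   the joint.
#' @export
moment_arm <- function(digit, path, q, joint_idx) {
  stopifnot(joint_idx %in% 1:3)
  seg <- path$via_points$segment
  if (!(min(seg) < joint_idx && max(seg) >= joint_idx)) {
    warning(sprintf("path '%s' does not cross joint %d", path$mtu_name,
                    joint_idx))
    return(0)
  }
  h <- 1e-6
  qp <- q; qp[joint_idx] <- q[joint_idx] + h
  qm <- q; qm[joint_idx] <- q[joint_idx] - h
  -(path_length(digit, path, qp) - path_length(digit, path, qm)) / (2 * h)
}

# Passive joint torque: linear stiffness toward rest, viscous damping, and
# a penalty restoring torque (with extra damping) beyond the ROM limits.
passive_torque <- function(joint, q, qdot) {
  tau <- -joint$stiffness * (q - joint$q_rest) - joint$damping * qdot
  if (q > joint$rom[2]) {
    tau <- tau - joint$limit_stiffness * (q - joint$rom[2]) -
      joint$limit_damping * qdot
  } else if (q < joint$rom[1]) {
    tau <- tau - joint$limit_stiffness * (q - joint$rom[1]) -
      joint$limit_damping * qdot
  }
  tau
}

#' Joint torques from muscle forces and passive joint structures
#'
#' `tau_j = sum_strands r_j F_mtu - k (q_j - q_rest) - c qdot_j - ROM
#' penalty`, with moment arms from the tendon-excursion relation.
#'
#' @param model A [hand_model()] object.
#' @param q Named list or matrix of joint angles per digit (as in
#'   [hand_state()]).
#' @param mtu_forces Named numeric vector of strand forces (N), names
#'   matching the model's strands; forces must be non-negative.
#' @param qdot Joint angular velocities, defaults to zero.
#' @return Matrix of torques (N m), one row per digit, columns MCP/PIP/DIP.
#' @export
joint_torques <- function(model, q, mtu_forces, qdot = NULL) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1,
                                   dimnames = list(names(model$digits)[1]))
  if (is.null(rownames(q))) rownames(q) <- names(model$digits)[seq_len(nrow(q))]
  if (is.null(qdot)) qdot <- 0 * q
  if (is.null(dim(qdot))) qdot <- matrix(qdot, nrow = nrow(q))
  stopifnot(all(mtu_forces >= 0))
  tau <- 0 * q
  colnames(tau) <- c("MCP", "PIP", "DIP")
  for (d in rownames(q)) {
    dig <- model$digits[[d]]
    for (j in 1:3) {
      jt <- model$joints[[d]][[j]]
      tau[d, j] <- passive_torque(jt, q[d, j], qdot[d, j])
    }
  }
  for (p in model$paths) {
    d <- paste0("d", p$digit_id)
    if (!d %in% rownames(q)) next
    f <- mtu_forces[[p$mtu_name]]
    if (is.null(f) || f == 0) next
    seg <- p$via_points$segment
    for (j in 1:3) {
      if (min(seg) < j && max(seg) >= j) {
        r <- moment_arm(model$digits[[d]], p, q[d, ], j)
        tau[d, j] <- tau[d, j] + r * f
      }
    }
  }
  tau
}

# Chain mass matrix of one digit (3x3) from segment linear density:
# point-mass-at-midpoint plus rod inertia about the center of mass.
digit_mass_matrix <- function(digit, q, density) {
  L <- digit$segment_lengths
  m <- density * L
  Ic <- m * L^2 / 12
  fk <- fk_digit(digit, q)
  o <- fk$origins
  M <- matrix(0, 3, 3)
  for (k in 1:3) {
    com <- (o[k + 1, ] + o[k + 2, ]) / 2
    Jk <- matrix(0, 2, 3)
    for (j in 1:k) {
      cj <- o[j + 1, ]
      Jk[, j] <- c(com[2] - cj[2], -(com[1] - cj[1]))
    }
    M <- M + m[k] * crossprod(Jk)
    M[1:k, 1:k] <- M[1:k, 1:k] + Ic[k]
  }
  M
}

#' One fixed step of forward chain dynamics
#'
#' Integrates the per-digit chain equations `M(q) qddot = tau_applied +
#' tau_passive` over one step of a fixed-step 4th-order Runge-Kutta scheme.
#' The applied torques are held constant over the step; passive joint
#' stiffness, damping and ROM penalties are evaluated at every substage.
#' Velocity-product (Coriolis) terms are neglected: finger segments are
#' light and joint/contact damping dominates at the speeds of interest.
#'
#' @param model A [hand_model()] object.
#' @param state A [hand_state()] object.
#' @param torques Applied torque matrix (N m), same shape as `state$q`.
#' @param dt Time step (s); must not exceed `model$dt_max`.
#' @return The updated [hand_state()].
#' @export
step_dynamics <- function(model, state, torques, dt) {
  stopifnot(inherits(state, "hand_state"), dt > 0)
  if (dt > model$dt_max) {
    stop(sprintf("dt = %g exceeds the stability-checked dt_max = %g",
                 dt, model$dt_max))
  }
  if (is.null(dim(torques))) torques <- matrix(torques, nrow = 1)
  q <- state$q; qd <- state$qdot
  if (is.null(rownames(q))) rownames(q) <- names(model$digits)[seq_len(nrow(q))]
  deriv <- function(q, qd) {
    qdd <- 0 * q
    for (i in seq_len(nrow(q))) {
      d <- rownames(q)[i]
      tau <- torques[i, ]
      for (j in 1:3) {
        tau[j] <- tau[j] + passive_torque(model$joints[[d]][[j]], q[i, j],
                                          qd[i, j])
      }
      M <- digit_mass_matrix(model$digits[[d]], q[i, ], model$density)
      qdd[i, ] <- solve(M, tau)
    }
    list(qd = qd, qdd = qdd)
  }
  k1 <- deriv(q, qd)
  k2 <- deriv(q + dt / 2 * k1$qd, qd + dt / 2 * k1$qdd)
  k3 <- deriv(q + dt / 2 * k2$qd, qd + dt / 2 * k2$qdd)
  k4 <- deriv(q + dt * k3$qd, qd + dt * k3$qdd)
  q_new <- q + dt / 6 * (k1$qd + 2 * k2$qd + 2 * k3$qd + k4$qd)
  qd_new <- qd + dt / 6 * (k1$qdd + 2 * k2$qdd + 2 * k3$qdd + k4$qdd)
  if (!all(is.finite(q_new)) || !all(is.finite(qd_new))) {
    stop("non-finite state in step_dynamics")
  }
  hand_state(q_new, qd_new)
}
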