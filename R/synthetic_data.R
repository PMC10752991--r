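# Synthetic reference data generators. The literature inputs the pipeline
# calibrates against (digitized moment-arm curves, tendon stress-strain
# measurements, whole-muscle parameter tables) are not redistributable, so
# parameterized surrogates with controlled statistical structure stand in
# for them. Everything here is labelled synthetic; anchor values (the
# FDP-MCP mean moment arm of 9.7 mm with 2.0 mm scatter, a 2.4 GPa
# linear-region tendon modulus) keep the surrogates in the physiological
# range reported for the real data.

#' Default synthetic moment-arm reference specification
#'
#' One row per (muscle, joint, digit) curve of the full flexor topology:
#' FDP crossing MCP/PIP/DIP and FDS crossing MCP/PIP on digits 2..5 (20
#' curves). Mean arms are plausible literature-scale values with the FDP-MCP
#' mean anchored at 9.7 mm; the angle dependence is a mild quadratic;
#' `noise_sd` defaults to zero (noise-free references).
#'
#' @param noise_sd Measurement noise SD (m), recycled over curves.
#' @param n Samples per curve.
#' @return Data frame with columns `muscle`, `digit`, `joint`, `mean_arm`,
#'   `c1`, `c2`, `noise_sd`, `angle_min`, `angle_max`, `n`.
#' @export
default_moment_arm_spec <- function(noise_sd = 0, n = 46) {
  rows <- expand.grid(digit = 2:5, joint = 1:3, muscle = c("FDP", "FDS"),
                      stringsAsFactors = FALSE)
  rows <- rows[!(rows$muscle == "FDS" & rows$joint == 3), ]
  means <- c(FDP.1 = 0.0097, FDP.2 = 0.0075, FDP.3 = 0.0050,
             FDS.1 = 0.0110, FDS.2 = 0.0060)
  rom_max <- c(pi / 2, 100 * pi / 180, 80 * pi / 180)
  rows$mean_arm <- means[paste(rows$muscle, rows$joint, sep = ".")]
  # small per-digit size scaling: middle finger largest, little smallest
  scale <- c(`2` = 1.0, `3` = 1.08, `4` = 1.0, `5` = 0.85)
  rows$mean_arm <- rows$mean_arm * scale[as.character(rows$digit)]
  rows$c1 <- 0.10; rows$c2 <- -0.05
  rows$noise_sd <- rep_len(noise_sd, nrow(rows))
  rows$angle_min <- 0
  rows$angle_max <- rom_max[rows$joint]
  rows$n <- n
  rownames(rows) <- NULL
  rows
}

#' Generate synthetic moment-arm reference curves
#'
#' Each curve is `mean_arm * (1 + c1 * z + c2 * (z^2 - mean(z^2)))` with
#' `z = angle - mean(grid)`, so the curve's grid mean equals `mean_arm`
#' exactly before noise; independent Gaussian noise of SD `noise_sd` is
#' added per sample. Deterministic given `seed`.
#'
#' @param spec Specification data frame as from [default_moment_arm_spec()].
#' @param seed Integer seed.
#' @return Named list of [moment_arm_curve()] objects
#'   (`source = "reference"`).
#' @export
gen_moment_arm_reference <- function(spec = default_moment_arm_spec(),
                                     seed = 1) {
  stopifnot(all(spec$mean_arm > 0), all(spec$noise_sd >= 0))
  with_seed(seed, {
    out <- lapply(seq_len(nrow(spec)), function(i) {
      r <- spec[i, ]
      grid <- seq(r$angle_min, r$angle_max, length.out = r$n)
      z <- grid - mean(grid)
      arms <- r$mean_arm * (1 + r$c1 * z + r$c2 * (z^2 - mean(z^2)))
      arms <- arms + stats::rnorm(r$n, 0, r$noise_sd)
      moment_arm_curve(r$digit, r$muscle, r$joint, grid, arms, "reference")
    })
    names(out) <- sprintf("%s %d J%d", spec$muscle, spec$digit, spec$joint)
    out
  })
}

#' Default synthetic tendon stress-strain specification
#'
#' A positional-tendon-like curve: power-law toe region to
#' `toe_end_strain`, linear region with modulus `linear_modulus` to
#' `linear_end_strain`, then a necking region with tangent modulus reduced
#' by `necking_modulus_fraction` up to `failure_strain`, constant beyond.
#' The toe stress scale is derived from the linear modulus and toe exponent
#' so the curve is continuously differentiable at the toe/linear transition
#' (set `necking_modulus_fraction = 1` to disable necking, which makes the
#' curve lie exactly in the serial-elastic model family).
#'
#' @param linear_modulus Linear-region Young's modulus (Pa).
#' @param toe_end_strain,linear_end_strain,failure_strain Region boundaries.
#' @param toe_exponent Toe power-law exponent.
#' @param necking_modulus_fraction Tangent-modulus fraction in the necking
#'   region.
#' @param grid Strain sample grid.
#' @param noise_sd Additive stress noise SD (Pa).
#' @return List of class `tendon_reference_spec`.
#' @export
default_tendon_spec <- function(linear_modulus = 2.4e9,
                                toe_end_strain = 0.015,
                                linear_end_strain = 0.04,
                                failure_strain = 0.08,
                                toe_exponent = 2,
                                necking_modulus_fraction = 0.25,
                                grid = seq(0, 0.05, by = 5e-4),
                                noise_sd = 0) {
  stopifnot(toe_end_strain < linear_end_strain,
            linear_end_strain < failure_strain,
            linear_modulus > 0, necking_modulus_fraction > 0,
            toe_exponent > 1, noise_sd >= 0)
  structure(list(linear_modulus = linear_modulus,
                 toe_end_strain = toe_end_strain,
                 linear_end_strain = linear_end_strain,
                 failure_strain = failure_strain,
                 toe_exponent = toe_exponent,
                 necking_modulus_fraction = necking_modulus_fraction,
                 grid = grid, noise_sd = noise_sd),
            class = "tendon_reference_spec")
}

#' Generate a synthetic tendon stress-strain reference curve
#'
#' @param spec A [default_tendon_spec()] specification.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A [stress_strain_curve()] with `label = "reference"`.
#' @export
gen_tendon_reference <- function(spec = default_tendon_spec(), seed = 1) {
  stopifnot(inherits(spec, "tendon_reference_spec"))
  E <- spec$linear_modulus
  t1 <- spec$toe_end_strain; t2 <- spec$linear_end_strain
  tf <- spec$failure_strain
  nu <- spec$toe_exponent
  s_toe <- E * t1 / nu                       # C1 at the toe/linear transition
  s_lin_end <- s_toe + E * (t2 - t1)
  s_fail <- s_lin_end + spec$necking_modulus_fraction * E * (tf - t2)
  eps <- spec$grid
  s <- ifelse(eps <= 0, 0,
       ifelse(eps < t1, s_toe * (eps / t1)^nu,
       ifelse(eps <= t2, s_toe + E * (eps - t1),
       ifelse(eps <= tf, s_lin_end + spec$necking_modulus_fraction *
                E * (eps - t2),
              s_fail))))
  if (spec$noise_sd > 0) {
    s <- with_seed(seed, s + stats::rnorm(length(s), 0, spec$noise_sd))
  }
  stress_strain_curve(eps, pmax(s, 0), "reference")
}

#' Default synthetic hand fixture specification
#'
#' Planar digits 2..5 with per-digit phalanx lengths, palmar wrap radii for
#' FDP/FDS, dorsal radii for one extensor strand per digit, whole-muscle
#' maximum isometric forces split evenly across the four digit strands, and
#' tendon material parameters (defaulting to the tuned stiff set). All
#' numeric values are synthetic, chosen in the physiological range for an
#' adult hand.
#'
#' @param see Tendon parameter set used for every strand (fractions only;
#'   rest lengths are derived per strand by [init_equilibrium()]).
#' @param sigma_norm Normalization stress `Fmax / csa` (Pa) used to derive
#'   each strand's tendon cross-sectional area.
#' @param Fmax_T Named whole-muscle maximum isometric forces (N).
#' @return List of class `hand_fixture_spec`.
#' @export
default_hand_spec <- function(see = see_params(0.8, 0.02, 0.01),
                              sigma_norm = 30e6,
                              Fmax_T = c(FDP = 400, FDS = 380, EXT = 160)) {
  structure(list(
    segment_lengths = list(
      d2 = c(0.040, 0.022, 0.016),
      d3 = c(0.045, 0.026, 0.017),
      d4 = c(0.042, 0.024, 0.017),
      d5 = c(0.033, 0.018, 0.015)),
    rom = list(MCP = c(0, pi / 2), PIP = c(0, 100 * pi / 180),
               DIP = c(0, 80 * pi / 180)),
    joint_stiffness = 0.01, joint_damping = 0.001,
    limit_stiffness = 20, limit_damping = 0.01,
    radii = list(FDP = c(0.0097, 0.0075, 0.0050),
                 FDS = c(0.0110, 0.0060),
                 EXT = c(0.0060, 0.0050, 0.0040)),
    Fmax_T = Fmax_T, n_s = 4L,
    l_ce_opt = c(FDP = 0.090, FDS = 0.090, EXT = 0.060),
    dW_asc = 1.0,
    see = see, sigma_norm = sigma_norm,
    origin_x = c(flexor = -0.200, extensor = -0.080),
    density = 0.4), class = "hand_fixture_spec")
}

# Build the via-point table of one muscle on one digit.
fixture_path <- function(muscle, digit_id, L, radii, origin_x) {
  sgn <- if (muscle == "EXT") 1 else -1
  r <- radii * sgn
  oy <- sgn * 0.005
  if (muscle == "FDP") {
    vp <- data.frame(
      segment = c(0, 0, 1, 1, 2, 2, 3, 3),
      x = c(origin_x, -0.012, 0.012, L[1] - 0.010, 0.010, L[2] - 0.008,
            0.008, 0.6 * L[3]),
      y = c(oy, r[1], r[1], r[2], r[2], r[3], r[3], sgn * 0.002))
  } else if (muscle == "FDS") {
    vp <- data.frame(
      segment = c(0, 0, 1, 1, 2, 2),
      x = c(origin_x, -0.012, 0.012, L[1] - 0.010, 0.010, 0.55 * L[2]),
      y = c(oy, r[1], r[1], r[2], r[2], sgn * 0.002))
  } else {
    vp <- data.frame(
      segment = c(0, 0, 1, 1, 2, 2, 3, 3),
      x = c(origin_x + 0.010, -0.010, 0.010, L[1] - 0.008, 0.008,
            L[2] - 0.007, 0.007, 0.5 * L[3]),
      y = c(oy, r[1], r[1], r[2], r[2], r[3], r[3], sgn * 0.002))
  }
  routing_path(paste(muscle, digit_id), vp, digit_id)
}

#' Generate the synthetic planar hand fixture
#'
#' Builds the full reduced-order model: 4 digits, 3 revolute joints each,
#' FDP/FDS flexor strands plus one extensor strand per digit (12 strands),
#' via-point routings, and per-strand muscle-tendon parameters with rest
#' lengths from the initial length equilibrium at the straight posture.
#'
#' @param spec A [default_hand_spec()] specification.
#' @return A [hand_model()] object whose strands are all initialized
#'   (finite tendon rest lengths).
#' @export
gen_hand_fixture <- function(spec = default_hand_spec()) {
  stopifnot(inherits(spec, "hand_fixture_spec"))
  for (L in spec$segment_lengths) {
    if (any(L <= 0)) stop("degenerate digit geometry: non-positive segment length")
  }
  digits <- lapply(seq_along(spec$segment_lengths), function(i) {
    digit_geometry(i + 1, spec$segment_lengths[[i]])
  })
  joints <- lapply(c("MCP", "PIP", "DIP"), function(j) {
    revolute_joint(rom = spec$rom[[j]], stiffness = spec$joint_stiffness,
                   damping = spec$joint_damping,
                   limit_stiffness = spec$limit_stiffness,
                   limit_damping = spec$limit_damping)
  })
  paths <- list(); mtus <- list()
  for (d in seq_along(digits)) {
    did <- digits[[d]]$digit_id
    L <- spec$segment_lengths[[d]]
    for (muscle in names(spec$Fmax_T)) {
      ox <- if (muscle == "EXT") spec$origin_x[["extensor"]] else
        spec$origin_x[["flexor"]]
      p <- fixture_path(muscle, did, L, spec$radii[[muscle]], ox)
      paths[[p$mtu_name]] <- p
      group <- if (muscle == "EXT") "extensor" else "flexor"
      Fmax_s <- scale_fmax(strand_spec(spec$Fmax_T[[muscle]], spec$n_s))
      l_opt <- spec$l_ce_opt[[muscle]]
      l_mtu_i <- path_length(digits[[d]], p, c(0, 0, 0))
      eq <- init_equilibrium(l_mtu_i, l_opt, group, name = p$mtu_name)
      see <- see_params(spec$see$dF_see_0_frac, spec$see$dU_see_nll,
                        spec$see$dU_see_l, l_see_0 = eq$l_see_0)
      mtus[[p$mtu_name]] <- mtu_params(
        name = p$mtu_name, Fmax = Fmax_s, csa = Fmax_s / spec$sigma_norm,
        see = see, ce = ce_params(l_ce_opt = l_opt, dW_asc = spec$dW_asc),
        group = group)
    }
  }
  hand_model(digits, joints, paths, mtus, density = spec$density)
}
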