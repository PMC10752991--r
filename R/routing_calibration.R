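# Routing calibration: fit via-point positions so model moment-arm curves
# match reference curves, scored with MAE and NMAE (mean absolute error
# normalized to the mean of the measured data, reported in percent).

#' Moment-arm curve container
#'
#' @param digit Digit number (2..5).
#' @param muscle Muscle name (`"FDP"`, `"FDS"`, ...).
#' @param joint Joint index (1 = MCP, 2 = PIP, 3 = DIP).
#' @param angles Sample grid of joint flexion angles (rad), strictly
#'   increasing, at least 3 samples.
#' @param arms Moment arms (m) on the grid.
#' @param source `"reference"` or `"model"`.
#' @return An object of class `moment_arm_curve`.
#' @export
moment_arm_curve <- function(digit, muscle, joint, angles, arms,
                             source = c("reference", "model")) {
  source <- match.arg(source)
  stopifnot(length(angles) >= 3, length(arms) == length(angles),
            all(diff(angles) > 0), all(is.finite(angles)), all(is.finite(arms)))
  structure(list(digit = as.integer(digit), muscle = muscle,
                 joint = as.integer(joint), angles = as.numeric(angles),
                 arms = as.numeric(arms), source = source),
            class = "moment_arm_curve")
}

curve_key <- function(cv) sprintf("%s %d J%d", cv$muscle, cv$digit, cv$joint)

#' Mean absolute error and normalized mean absolute error
#'
#' `MAE = sum(|pred - meas|) / n`; `NMAE = MAE / mean(meas)`, reported as
#' percent. NMAE is invariant under a common positive rescaling of both
#' series.
#'
#' @param pred Predicted samples.
#' @param meas Measured samples (same length, non-zero mean).
#' @return List with `mae` (input units) and `nmae_pct` (percent).
#' @export
nmae <- function(pred, meas) {
  stopifnot(length(pred) == length(meas), length(meas) >= 1,
            all(is.finite(pred)), all(is.finite(meas)))
  mbar <- mean(meas)
  if (mbar == 0) stop("normalization undefined: mean of measured data is zero")
  mae <- mean(abs(pred - meas))
  list(mae = mae, nmae_pct = 100 * mae / mbar)
}

# Model moment-arm curve of one path about one joint: vary that joint over
# the grid with the other joints held at `posture`, central differences on
# the path length.
model_arm_curve <- function(digit, path, joint, angles, posture = c(0, 0, 0),
                            h = 1e-6) {
  arms <- vapply(angles, function(ang) {
    q <- posture; q[joint] <- ang
    qp <- q; qp[joint] <- ang + h
    qm <- q; qm[joint] <- ang - h
    -(path_length(digit, path, qp) - path_length(digit, path, qm)) / (2 * h)
  }, numeric(1))
  arms
}

#' All model moment-arm curves of a hand model
#'
#' Enumerates every (muscle strand, crossed joint) pair and evaluates the
#' tendon-excursion moment arm over the joint's range of motion (2 degree
#' grid), other joints held straight. The full flexor topology (FDP over 3
#' joints and FDS over 2 joints, digits 2..5) yields exactly 20 curves.
#'
#' @param model A [hand_model()] object.
#' @param muscles Muscle name prefixes to include.
#' @param step_deg Grid spacing in degrees.
#' @return List of [moment_arm_curve()] objects with `source = "model"`.
#' @export
model_moment_arm_curves <- function(model, muscles = c("FDP", "FDS"),
                                    step_deg = 2) {
  out <- list()
  for (p in model$paths) {
    muscle <- strsplit(p$mtu_name, " ")[[1]][1]
    if (!muscle %in% muscles) next
    d <- paste0("d", p$digit_id)
    dig <- model$digits[[d]]
    seg <- p$via_points$segment
    for (j in 1:3) {
      if (!(min(seg) < j && max(seg) >= j)) next
      rom <- model$joints[[d]][[j]]$rom
      angles <- seq(rom[1], rom[2], by = step_deg * pi / 180)
      arms <- model_arm_curve(dig, p, j, angles)
      out[[length(out) + 1]] <- moment_arm_curve(p$digit_id, muscle, j,
                                                 angles, arms, "model")
    }
  }
  names(out) <- vapply(out, curve_key, "")
  out
}

# Resample a reference curve to a regular grid (default 2 degrees) by linear
# interpolation, clipped to the curve's own support.
resample_curve <- function(cv, step_deg = 2) {
  grid <- seq(min(cv$angles), max(cv$angles), by = step_deg * pi / 180)
  arms <- stats::approx(cv$angles, cv$arms, xout = grid)$y
  moment_arm_curve(cv$digit, cv$muscle, cv$joint, grid, arms, cv$source)
}

# The free routing parameters of one path: one palmar wrap radius per
# crossed joint (the |y| offset shared by the via-point pair adjacent to
# that joint). Returns the indices of the pair rows per joint.
path_wrap_pairs <- function(path) {
  seg <- path$via_points$segment
  pairs <- list()
  for (j in 1:3) {
    if (!(min(seg) < j && max(seg) >= j)) next
    # last point on a segment < j and first point on a segment >= j
    i1 <- max(which(seg < j))
    i2 <- min(which(seg >= j))
    pairs[[as.character(j)]] <- c(i1, i2)
  }
  pairs
}

set_path_radii <- function(path, radii, sign = -1) {
  pairs <- path_wrap_pairs(path)
  stopifnot(length(radii) == length(pairs))
  for (k in seq_along(pairs)) {
    path$via_points$y[pairs[[k]]] <- sign * radii[k]
  }
  path
}

get_path_radii <- function(path) {
  pairs <- path_wrap_pairs(path)
  vapply(pairs, function(ix) mean(abs(path$via_points$y[ix])), numeric(1))
}

#' Optimize via-point routing against reference moment-arm curves
#'
#' Adjusts the palmar wrap radii of a muscle's via points (one radius per
#' crossed joint and digit) so the model's tendon-excursion moment-arm
#' curves match the reference curves, by bounded Levenberg-Marquardt least
#' squares pooled over all curves of each digit. Digits are independent in
#' the planar model and are fit separately; seeded multi-start hedges local
#' minima.
#'
#' @param model A [hand_model()] object.
#' @param muscle Muscle to optimize (`"FDP"` or `"FDS"`).
#' @param reference List of [moment_arm_curve()] objects covering every
#'   joint the muscle crosses on every digit to fit.
#' @param bounds Length-2 vector: lower/upper bound on the wrap radii (m);
#'   keeps via points palmar and inside the segment envelope.
#' @param init Optional named list `digit -> radius vector` overriding the
#'   model's current radii as the starting point.
#' @param n_starts Number of multi-start restarts (first start is `init`).
#' @param seed Seed for the restart sampling.
#' @param step_deg Resampling grid spacing for the references (degrees).
#' @return List of class `routing_fit`: the updated `model`, per-curve
#'   `mae`/`nmae_pct`, the optimized radii, iteration counts and a
#'   `converged` flag.
#' @export
optimize_routing <- function(model, muscle, reference,
                             bounds = c(0.002, 0.02), init = NULL,
                             n_starts = 5, seed = 1, step_deg = 2) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  refs <- lapply(reference, resample_curve, step_deg = step_deg)
  names(refs) <- vapply(refs, curve_key, "")
  paths <- Filter(function(p) startsWith(p$mtu_name, paste0(muscle, " ")),
                  model$paths)
  if (length(paths) == 0) stop(sprintf("no paths for muscle '%s'", muscle))
  per_curve <- list(); radii_out <- list(); iters <- 0; conv <- TRUE
  for (p in paths) {
    dig <- model$digits[[paste0("d", p$digit_id)]]
    pairs <- path_wrap_pairs(p)
    joints <- as.integer(names(pairs))
    my_refs <- refs[vapply(joints, function(j)
      sprintf("%s %d J%d", muscle, p$digit_id, j), "")]
    if (any(vapply(my_refs, is.null, TRUE))) {
      stop(sprintf("reference curves missing for %s digit %d", muscle,
                   p$digit_id))
    }
    resid_fn <- function(r) {
      pp <- set_path_radii(p, r, sign = -1)
      unlist(lapply(seq_along(joints), function(k) {
        cv <- my_refs[[k]]
        model_arm_curve(dig, pp, joints[k], cv$angles) - cv$arms
      }))
    }
    r0 <- get_path_radii(p)
    if (!is.null(init) && !is.null(init[[as.character(p$digit_id)]])) {
      r0 <- init[[as.character(p$digit_id)]]
    }
    r0 <- pmin(pmax(r0, bounds[1]), bounds[2])
    starts <- list(r0)
    if (n_starts > 1) {
      extra <- with_seed(seed + p$digit_id, {
        lapply(seq_len(n_starts - 1), function(i)
          stats::runif(length(r0), bounds[1], bounds[2]))
      })
      starts <- c(starts, extra)
    }
    best <- NULL
    for (r_init in starts) {
      fit <- minpack.lm::nls.lm(par = r_init, fn = resid_fn,
                                lower = rep(bounds[1], length(r0)),
                                upper = rep(bounds[2], length(r0)),
                                control = minpack.lm::nls.lm.control(
                                  ftol = 1e-10, ptol = 1e-10, maxiter = 500))
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    iters <- iters + best$niter
    if (!best$info %in% 1:4) conv <- FALSE
    r_hat <- as.numeric(best$par)
    # never accept a start worse than the initial iterate
    if (sum(resid_fn(r_hat)^2) > sum(resid_fn(r0)^2)) r_hat <- r0
    radii_out[[p$mtu_name]] <- r_hat
    p_hat <- set_path_radii(p, r_hat, sign = -1)
    model$paths[[p$mtu_name]] <- p_hat
    for (k in seq_along(joints)) {
      cv <- my_refs[[k]]
      m_arms <- model_arm_curve(dig, p_hat, joints[k], cv$angles)
      per_curve[[curve_key(cv)]] <- nmae(m_arms, cv$arms)
    }
  }
  model$scene <- build_scene(model)
  structure(list(model = model, radii = radii_out,
                 mae = vapply(per_curve, `[[`, numeric(1), "mae"),
                 nmae_pct = vapply(per_curve, `[[`, numeric(1), "nmae_pct"),
                 iterations = iters, converged = conv),
            class = "routing_fit")
}

#' Summarize per-curve NMAE values
#'
#' @param nmae_values Numeric vector of per-curve NMAE values (percent).
#' @param thresholds Thresholds (percent) at which to count curves below.
#' @return List with `n`, `min`, `max`, `mean` and a named `count_below`
#'   vector (one entry per threshold).
#' @export
summarize_fit <- function(nmae_values, thresholds = c(5, 25)) {
  stopifnot(length(nmae_values) >= 1, all(is.finite(nmae_values)))
  counts <- vapply(thresholds, function(th) sum(nmae_values < th), numeric(1))
  if (length(thresholds)) names(counts) <- paste0("below_", thresholds, "pct")
  list(n = length(nmae_values), min = min(nmae_values),
       max = max(nmae_values), mean = mean(nmae_values),
       count_below = counts)
}
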