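# Plain-text interchange formats: muscle parameter tables (SI units),
# moment-arm curve tables (degrees / mm) and tendon stress-strain tables
# (strain / MPa). Numeric columns are written with 17 significant digits so
# a write/read round trip is bit-exact.

fmt_num <- function(x) vapply(x, function(v) sprintf("%.17g", v), "")

#' Write a muscle parameter table
#'
#' One row per strand: name, digit, group, Fmax (N), csa (m^2), optimal
#' fiber length (m), serial-elastic parameters and tendon rest length (m),
#' serial damping (N s/m). Values round-trip bit-exactly through
#' [read_muscle_params()].
#'
#' @param mtus Named list of [mtu_params()] objects.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_muscle_params <- function(mtus, path) {
  df <- do.call(rbind, lapply(mtus, function(m) {
    parts <- strsplit(m$name, " ")[[1]]
    data.frame(name = m$name,
               digit = if (length(parts) > 1) parts[2] else NA,
               group = m$group,
               Fmax = fmt_num(m$Fmax), csa = fmt_num(m$csa),
               l_ce_opt = fmt_num(m$ce$l_ce_opt),
               dF_see_0_frac = fmt_num(m$see$dF_see_0_frac),
               dU_see_nll = fmt_num(m$see$dU_see_nll),
               dU_see_l = fmt_num(m$see$dU_see_l),
               l_see_0 = fmt_num(m$see$l_see_0),
               d_se = fmt_num(m$d_se),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a muscle parameter table
#'
#' @param path CSV path written by [write_muscle_params()].
#' @return Named list of [mtu_params()] objects (with default contractile /
#'   parallel-elastic / activation parameters around the stored fields).
#' @export
read_muscle_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num_cols <- c("Fmax", "csa", "l_ce_opt", "dF_see_0_frac", "dU_see_nll",
                "dU_see_l", "l_see_0", "d_se")
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    mtu_params(name = r$name, Fmax = r$Fmax, csa = r$csa,
               see = see_params(r$dF_see_0_frac, r$dU_see_nll, r$dU_see_l,
                                r$l_see_0),
               ce = ce_params(l_ce_opt = r$l_ce_opt),
               group = r$group, d_se = r$d_se)
  })
  names(out) <- df$name
  out
}

#' Write moment-arm curves as a long-format table
#'
#' Columns: `digit`, `muscle`, `joint`, `angle_deg`, `arm_mm`, `source`.
#'
#' @param curves List of [moment_arm_curve()] objects.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_moment_arm_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(digit = cv$digit, muscle = cv$muscle, joint = cv$joint,
               angle_deg = fmt_num(rad2deg(cv$angles)),
               arm_mm = fmt_num(cv$arms * 1000),
               source = cv$source, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read moment-arm curves from a long-format table
#'
#' @param path CSV path written by [write_moment_arm_curves()].
#' @return Named list of [moment_arm_curve()] objects.
#' @export
read_moment_arm_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$muscle, df$digit, df$joint)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$angle_deg), ]
    moment_arm_curve(g$digit[1], g$muscle[1], g$joint[1],
                     deg2rad(g$angle_deg), g$arm_mm / 1000,
                     g$source[1])
  })
  names(out) <- vapply(out, curve_key, "")
  out
}

#' Write a stress-strain curve
#'
#' Columns: `strain` (dimensionless), `stress_MPa`.
#'
#' @param curve A [stress_strain_curve()] object.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_stress_strain <- function(curve, path) {
  df <- data.frame(strain = fmt_num(curve$strains),
                   stress_MPa = fmt_num(curve$stresses / 1e6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a stress-strain curve
#'
#' @param path CSV path written by [write_stress_strain()].
#' @param label Curve label.
#' @return A [stress_strain_curve()] object.
#' @export
read_stress_strain <- function(path, label = "reference") {
  df <- utils::read.csv(path)
  stress_strain_curve(df$strain, df$stress_MPa * 1e6, label)
}

#' Write a simulation result's time series
#'
#' One row per sample: time, per-strand MTU force (N), tendon strain and
#' activation, joint angles (rad), per-digit contact normal force (N) and
#' rod position (m).
#'
#' @param result A `jfi_simulation` from [run_load_case()].
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_simulation_csv <- function(result, path) {
  df <- data.frame(t_s = result$time)
  for (nm in result$strand_names) {
    df[[paste0("F_", gsub(" ", "", nm), "_N")]] <- result$F_mtu[, nm]
    df[[paste0("eps_", gsub(" ", "", nm))]] <- result$eps_see[, nm]
    df[[paste0("a_", gsub(" ", "", nm))]] <- result$activation[, nm]
  }
  df <- cbind(df, result$q, result$contact_n, result$rod)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
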