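# Injury assessment: avulsion-force threshold on MTU force, tendon strain
# severity grades on tendon strain, and a configurable muscle strain
# criterion on fiber strain. Crossings are inclusive (>=): a peak exactly at
# a threshold counts as that grade.

#' Injury threshold set
#'
#' Tendon strain grades mark the start of the strain-hardening region
#' (minor), the start of the necking region (major) and material failure
#' (rupture). The avulsion force threshold is the lowest experimentally
#' reported distal-insertion avulsion load, 10.8 kg under standard gravity.
#' Muscle strain thresholds have no shipped default: the criterion is
#' evaluated only when a threshold triple is supplied.
#'
#' @param tsic_minor,tsic_major,tsic_rupture Tendon strain grade thresholds
#'   (engineering strain on the tendon rest length).
#' @param avulsion_force Avulsion force threshold (N).
#' @param msic Optional increasing numeric triple of fiber strain thresholds
#'   (minor, major, rupture), or `NULL` (not evaluated).
#' @return An object of class `injury_thresholds`.
#' @export
injury_thresholds <- function(tsic_minor = 0.04, tsic_major = 0.08,
                              tsic_rupture = 0.10,
                              avulsion_force = load_to_force(10.8),
                              msic = NULL) {
  stopifnot(tsic_minor > 0, tsic_minor < tsic_major,
            tsic_major < tsic_rupture, avulsion_force > 0)
  if (!is.null(msic)) {
    if (length(msic) != 3 || any(diff(msic) <= 0) || any(msic <= 0)) {
      stop("msic thresholds must be an increasing positive triple")
    }
  }
  structure(list(tsic_minor = tsic_minor, tsic_major = tsic_major,
                 tsic_rupture = tsic_rupture,
                 avulsion_force = avulsion_force, msic = msic),
            class = "injury_thresholds")
}

#' Convert a hanging mass to its weight force
#'
#' `force = mass * 9.80665 m/s^2` (standard gravity); rounding happens only
#' at reporting. The 10.8 kg avulsion load converts to 105.91 N (2
#' decimals).
#'
#' @param mass Mass (kg), non-negative.
#' @return Force (N).
#' @export
load_to_force <- function(mass) {
  if (!all(is.finite(mass)) || any(mass < 0)) stop("mass must be non-negative")
  mass * 9.80665
}

new_finding <- function(mtu_name, criterion, severity, first_crossing_time,
                        peak_value, evaluated = TRUE) {
  structure(list(mtu_name = mtu_name, criterion = criterion,
                 severity = severity,
                 first_crossing_time = first_crossing_time,
                 peak_value = peak_value, evaluated = evaluated),
            class = "injury_finding")
}

# Shared grading: peak against an increasing threshold triple, inclusive
# crossings; first_crossing_time is the first sample at/above the highest
# attained grade.
grade_series <- function(time, series, thresholds, grades) {
  stopifnot(length(time) == length(series))
  if (length(series) == 0) stop("empty series")
  if (!all(is.finite(series)) || !all(is.finite(time))) {
    stop("non-finite values in series")
  }
  peak <- max(series)
  level <- sum(peak >= thresholds)
  if (level == 0) {
    list(severity = "none", t_cross = NA_real_, peak = peak)
  } else {
    list(severity = grades[level],
         t_cross = time[which(series >= thresholds[level])[1]],
         peak = peak)
  }
}

#' Grade a tendon strain time series
#'
#' @param time Sample times (s).
#' @param strain_series Tendon strain time series (engineering strain).
#' @param thresholds An [injury_thresholds()] object.
#' @param mtu_name Strand name for the report.
#' @return An `injury_finding` with criterion `"TSIC"` and severity
#'   `none`/`minor`/`major`/`rupture`.
#' @export
assess_tsic <- function(time, strain_series, thresholds = injury_thresholds(),
                        mtu_name = "") {
  g <- grade_series(time, strain_series,
                    c(thresholds$tsic_minor, thresholds$tsic_major,
                      thresholds$tsic_rupture),
                    c("minor", "major", "rupture"))
  new_finding(mtu_name, "TSIC", g$severity, g$t_cross, g$peak)
}

#' Grade an MTU force time series against the avulsion threshold
#'
#' Avulsion is scored per strand (per digit): the underlying experiments
#' loaded single distal tendon insertions.
#'
#' @param time Sample times (s).
#' @param force_series MTU force time series (N), non-negative.
#' @param thresholds An [injury_thresholds()] object.
#' @param mtu_name Strand name for the report.
#' @return An `injury_finding` with criterion `"AVULSION"` and severity
#'   `none` or `avulsion`.
#' @export
assess_avulsion <- function(time, force_series,
                            thresholds = injury_thresholds(), mtu_name = "") {
  if (length(force_series) > 0 && any(force_series < 0, na.rm = TRUE)) {
    stop("force series must be non-negative")
  }
  g <- grade_series(time, force_series, thresholds$avulsion_force, "avulsion")
  new_finding(mtu_name, "AVULSION", g$severity, g$t_cross, g$peak)
}

#' Grade a fiber strain time series (muscle strain criterion)
#'
#' Same grading semantics as [assess_tsic()], applied to the contractile
#' element strain `l_ce / l_ce_opt - 1`. Threshold values are not shipped;
#' without them the finding is marked not evaluated.
#'
#' @param time Sample times (s).
#' @param fiber_strain_series Fiber strain series.
#' @param msic_thresholds Increasing triple (minor, major, rupture) or
#'   `NULL`.
#' @param mtu_name Strand name for the report.
#' @return An `injury_finding` with criterion `"MSIC"`.
#' @export
assess_msic <- function(time, fiber_strain_series, msic_thresholds = NULL,
                        mtu_name = "") {
  if (is.null(msic_thresholds)) {
    return(new_finding(mtu_name, "MSIC", "not-evaluated", NA_real_,
                       if (length(fiber_strain_series)) {
                         max(fiber_strain_series)
                       } else NA_real_,
                       evaluated = FALSE))
  }
  if (length(msic_thresholds) != 3 || any(diff(msic_thresholds) <= 0)) {
    stop("msic thresholds must be an increasing triple")
  }
  g <- grade_series(time, fiber_strain_series, msic_thresholds,
                    c("minor", "major", "rupture"))
  new_finding(mtu_name, "MSIC", g$severity, g$t_cross, g$peak)
}

injury_type_label <- function(finding) {
  switch(finding$criterion,
         AVULSION = "Tendon Avulsion",
         TSIC = sprintf("Tendon Strain (%s)", finding$severity),
         MSIC = sprintf("Muscle Strain (%s)", finding$severity),
         finding$criterion)
}

#' Build a protocol-level injury report table
#'
#' One row per simulation with the injury count, the distinct injury types
#' and the injured strands, in the digit naming scheme `"FDP 3"`
#' (3 = middle finger).
#'
#' @param findings List (one element per simulation) of lists of
#'   `injury_finding` objects.
#' @param metadata Data frame with one row per simulation; columns
#'   `simulation`, `a_pct`, `eta_a_pct`, `rod_retraction` are carried
#'   through when present.
#' @return Data frame with columns `simulation`, `a_pct`, `eta_a_pct`,
#'   `rod_retraction`, `n_injuries`, `injury_types`, `injured_mtus`.
#' @export
build_report <- function(findings, metadata = NULL) {
  n <- length(findings)
  if (is.null(metadata)) metadata <- data.frame(simulation = seq_len(n))
  stopifnot(nrow(metadata) == n)
  rows <- lapply(seq_len(n), function(i) {
    fs <- findings[[i]]
    inj <- Filter(function(f) f$evaluated && f$severity != "none", fs)
    data.frame(
      n_injuries = length(inj),
      injury_types = paste(unique(vapply(inj, injury_type_label, "")),
                           collapse = ", "),
      injured_mtus = paste(vapply(inj, `[[`, "", "mtu_name"),
                           collapse = ", "),
      stringsAsFactors = FALSE)
  })
  cbind(metadata, do.call(rbind, rows))
}
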