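#' Service-time distribution specification
#'
#' @param family One of `"lognormal"`, `"exponential"`, `"fixed"`.
#' @param mean Mean duration in minutes.
#' @param cv Coefficient of variation (lognormal only).
#' @return A list of class `mci_dist`.
#' @export
service_dist <- function(family = c("lognormal", "exponential", "fixed"),
                         mean, cv = 0.4) {
  family <- match.arg(family)
  if (!is.finite(mean) || mean < 0) stop("mean duration must be non-negative")
  if (family == "lognormal" && (!is.finite(cv) || cv <= 0))
    stop("cv must be positive for lognormal durations")
  structure(list(family = family, mean = mean, cv = cv), class = "mci_dist")
}

# draw n durations from a service distribution using the given stream
draw_service <- function(dist, n, stream) {
  if (n <= 0) return(numeric(0))
  switch(dist$family,
    fixed = rep(dist$mean, n),
    exponential = stream_draw(stream, n, function(k) stats::rexp(k, rate = 1 / dist$mean)),
    lognormal = {
      s2 <- log(1 + dist$cv^2)
      ml <- log(dist$mean) - s2 / 2
      stream_draw(stream, n, function(k) stats::rlnorm(k, ml, sqrt(s2)))
    })
}

# staffing requirement group: n staff drawn from any of the listed categories
staff_group <- function(cats, n = 1L) list(cats = cats, n = as.integer(n))

# shallow named-entry replacement (whole entries, no recursive merge)
replace_entries <- function(defaults, user) {
  if (is.null(user) || !length(user)) return(defaults)
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

#' Health-dynamics parameters
#'
#' Patients carry a health score from 99 (perfect health) down to 0 (death).
#' While a patient awaits their first clinical treatment the score falls at a
#' category-specific deterioration rate; during treatment it rises at the
#' improvement rate; death at score 0 is absorbing (triage black). Score
#' thresholds map the score to a triage category for progressive re-triage.
#'
#' @param d_red,d_yellow,d_green Deterioration rates in points/min while
#'   awaiting first treatment (must satisfy `d_red >= d_yellow >= d_green >= 0`).
#' @param r Improvement rate in points/min during treatment.
#' @param theta_red,theta_yellow Re-triage thresholds on the score,
#'   `0 < theta_red < theta_yellow < 99`; a score below `theta_red` is red,
#'   below `theta_yellow` yellow, otherwise green.
#' @param h0_red,h0_yellow,h0_green Initial scores per initial triage category
#'   (must be consistent with the thresholds).
#' @return A list of class `mci_health`.
#' @export
health_dynamics <- function(d_red = 0.25, d_yellow = 0.05, d_green = 0,
                            r = 0.5, theta_red = 30, theta_yellow = 70,
                            h0_red = 25, h0_yellow = 55, h0_green = 85) {
  if (!(d_red >= d_yellow && d_yellow >= d_green && d_green >= 0))
    stop("need d_red >= d_yellow >= d_green >= 0")
  if (!(theta_red > 0 && theta_red < theta_yellow && theta_yellow < 99))
    stop("need 0 < theta_red < theta_yellow < 99")
  if (!(h0_red > 0 && h0_red < theta_red))
    stop("h0_red must lie in (0, theta_red)")
  if (!(h0_yellow >= theta_red && h0_yellow < theta_yellow))
    stop("h0_yellow must lie in [theta_red, theta_yellow)")
  if (!(h0_green >= theta_yellow && h0_green <= 99))
    stop("h0_green must lie in [theta_yellow, 99]")
  structure(list(d_red = d_red, d_yellow = d_yellow, d_green = d_green, r = r,
                 theta_red = theta_red, theta_yellow = theta_yellow,
                 h0_red = h0_red, h0_yellow = h0_yellow, h0_green = h0_green),
            class = "mci_health")
}

#' Simulator calibration
#'
#' Service-time distributions, health dynamics, pathway probabilities, task
#' staffing matrices and the routine operating-room workload. The original
#' hospital's durations are not public; the shipped defaults are documented
#' design values chosen once so that the disaster-plan baseline reproduces the
#' qualitative pattern of an overloaded trauma pathway (severe patients wait
#' beyond their 120-min surgery benchmark while moderate patients stay far
#' below 720 min). Every element is a tunable fixture, not code.
#'
#' @param service Named list of [service_dist()] objects for
#'   `triage`, `red_stabilization`, `yellow_exam`, `xray`, `ct`,
#'   `red_surgery`, `yellow_surgery`, `transfer_out`, `routine_case`.
#' @param health An [health_dynamics()] object.
#' @param p_surgery_red,p_surgery_yellow Probability a patient of the category
#'   needs surgery.
#' @param p_ct_red,p_xray_red Probability a severely injured patient needs CT
#'   resp. X-ray imaging (remainder: none).
#' @param p_ct_yellow,p_xray_yellow Same for moderately injured patients.
#' @param p_ct_downgrade_eligible Probability a CT-indicated patient is
#'   clinically eligible to be downgraded to X-ray when every CT machine is
#'   busy at request time.
#' @param staffing Named list of task staffing requirements; each task is a
#'   list of groups `list(cats = <category names>, n = <count>)`, where a
#'   group's staff may come from any listed category.
#' @param routine_rate_per_min Function of time-of-day (minutes since
#'   midnight) giving the arrival intensity of routine central-OR cases, or a
#'   single number for a constant rate.
#' @param green_per_nurse,green_per_rotation_physician Supervision ratios in
#'   the dining hall (slightly injured patients per staff member).
#' @return A list of class `mci_calibration`.
#' @export
calibration <- function(service = NULL, health = health_dynamics(),
                        p_surgery_red = 0.9, p_surgery_yellow = 0.5,
                        p_ct_red = 0.9, p_xray_red = 0.1,
                        p_ct_yellow = 0.2, p_xray_yellow = 0.7,
                        p_ct_downgrade_eligible = 0.5,
                        staffing = NULL,
                        routine_rate_per_min = default_routine_rate,
                        green_per_nurse = 10L,
                        green_per_rotation_physician = 25L) {
  default_service <- list(
    triage            = service_dist("lognormal", 2, 0.3),
    red_stabilization = service_dist("lognormal", 25, 0.3),
    yellow_exam       = service_dist("lognormal", 20, 0.4),
    xray              = service_dist("lognormal", 8, 0.3),
    ct                = service_dist("lognormal", 15, 0.3),
    red_surgery       = service_dist("lognormal", 90, 0.35),
    yellow_surgery    = service_dist("lognormal", 60, 0.4),
    transfer_out      = service_dist("lognormal", 20, 0.5),
    routine_case      = service_dist("lognormal", 60, 0.5))
  service <- replace_entries(default_service, service)
  default_staffing <- list(
    triage            = list(staff_group("rotation_physicians"),
                             staff_group("general_nurses")),
    red_stabilization = list(staff_group("medical_specialists"),
                             staff_group("medical_assistants"),
                             staff_group("general_nurses")),
    yellow_exam       = list(staff_group(c("medical_assistants",
                                           "rotation_physicians")),
                             staff_group("general_nurses")),
    imaging           = list(staff_group("radiology_assistants")),
    red_surgery       = list(staff_group("medical_specialists", 2),
                             staff_group("surgical_nurses"),
                             staff_group("surgical_assistants")),
    yellow_surgery    = list(staff_group("medical_specialists"),
                             staff_group("surgical_nurses")))
  staffing <- replace_entries(default_staffing, staffing)
  routine_rate_spec <- if (is.numeric(routine_rate_per_min))
    routine_rate_per_min
  else if (identical(routine_rate_per_min, default_routine_rate)) "default"
  else "custom"
  if (is.numeric(routine_rate_per_min)) {
    rate <- routine_rate_per_min
    routine_rate_per_min <- function(tod) rep(rate, length(tod))
  }
  structure(list(service = service, health = health,
                 p_surgery_red = p_surgery_red,
                 p_surgery_yellow = p_surgery_yellow,
                 p_ct_red = p_ct_red, p_xray_red = p_xray_red,
                 p_ct_yellow = p_ct_yellow, p_xray_yellow = p_xray_yellow,
                 p_ct_downgrade_eligible = p_ct_downgrade_eligible,
                 staffing = staffing,
                 routine_rate_per_min = routine_rate_per_min,
                 routine_rate_spec = routine_rate_spec,
                 green_per_nurse = as.integer(green_per_nurse),
                 green_per_rotation_physician =
                   as.integer(green_per_rotation_physician)),
            class = "mci_calibration")
}

#' Shipped default calibration
#'
#' Convenience wrapper equal to [calibration()] with all defaults.
#'
#' @return An `mci_calibration`.
#' @export
default_calibration <- function() calibration()

#' Default routine operating-room caseload intensity
#'
#' Time-of-day-modulated arrival rate (cases per minute) of routine surgical
#' cases occupying the central operating rooms: one case every two hours
#' during the day shift, sparser in the evening, and roughly one case every
#' eight hours at night — so that around a 10 p.m. incident an ongoing routine
#' case is occasional rather than typical.
#'
#' @param tod Time of day in minutes since midnight (vectorized; values are
#'   taken modulo 1440).
#' @return Arrival rate(s) in cases per minute.
#' @export
default_routine_rate <- function(tod) {
  tod <- tod %% 1440
  rate <- numeric(length(tod))
  day <- tod >= 480 & tod < 960      # 08:00-16:00
  eve <- tod >= 960 & tod < 1320     # 16:00-22:00
  rate[day] <- 1 / 120
  rate[eve] <- 1 / 360
  rate[!day & !eve] <- 1 / 480       # 22:00-08:00
  rate
}

validate_calibration <- function(cal) {
  v <- character(0)
  probs <- c(cal$p_surgery_red, cal$p_surgery_yellow, cal$p_ct_red,
             cal$p_xray_red, cal$p_ct_yellow, cal$p_xray_yellow,
             cal$p_ct_downgrade_eligible)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    v <- c(v, "calibration probabilities must lie in [0, 1]")
  if (cal$p_ct_red + cal$p_xray_red > 1 || cal$p_ct_yellow + cal$p_xray_yellow > 1)
    v <- c(v, "per-category imaging probabilities must sum to at most 1")
  for (nm in names(cal$service)) {
    d <- cal$service[[nm]]
    if (!is.finite(d$mean) || d$mean < 0)
      v <- c(v, sprintf("service %s has a negative mean", nm))
  }
  v
}
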