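## Outcome metrics, benchmark compliance, cross-replication summaries and
## sequential replication control.

#' Waiting time for critical treatment
#'
#' For surgical patients the time from arrival to the start of surgery; for
#' non-surgical patients the time from arrival to the start of the first
#' clinical treatment. Patients deceased before the defining event get `NA`
#' (they are excluded from waiting-time means and counted separately).
#'
#' @param patients Per-patient record data frame from [run_replication()]
#'   (column `surgical` is inferred: a patient counts as surgical if surgery
#'   started or was still needed at death).
#' @return Numeric vector of waiting times in minutes (`NA` for excluded
#'   patients and for patients with no clinical treatment, e.g. slightly
#'   injured ones).
#' @export
critical_wait <- function(patients) {
  surgical <- !is.na(patients$surgery_start) |
    (patients$needs_surgery & patients$deceased)
  # the defining timestamp is NA for patients deceased before reaching it,
  # which is exactly the stated exclusion rule
  ifelse(surgical, patients$surgery_start - patients$arrival,
         patients$first_treatment_start - patients$arrival)
}

#' Total system time
#'
#' Time from arrival to exit from the trauma pathway. Errors if any requested
#' patient is still in the system.
#'
#' @param patients Per-patient record data frame.
#' @return Numeric vector in minutes (`NA` for deceased patients).
#' @export
total_system_time <- function(patients) {
  alive <- !patients$deceased
  if (any(alive & is.na(patients$exit_time)))
    stop("patient still in system: no exit time recorded")
  ifelse(alive, patients$exit_time - patients$arrival, NA_real_)
}

#' Benchmark compliance fraction
#'
#' Share of eligible patients of a triage category whose critical-treatment
#' waiting time is within the category's benchmark (120 min for red, 720 min
#' for yellow). Eligibility: category at the defining event, not deceased
#' before it.
#'
#' @param patients Per-patient record data frame (possibly pooled across
#'   replications).
#' @param category `"red"` or `"yellow"`.
#' @param bm An [benchmarks()] object.
#' @return Fraction in [0, 1].
#' @export
compliance_fraction <- function(patients, category, bm = benchmarks()) {
  w <- critical_wait(patients)
  keep <- patients$final_category == category & !is.na(w)
  if (!any(keep)) stop("no eligible ", category, " patients")
  limit <- switch(category, red = bm$red_surgery_limit,
                  yellow = bm$yellow_surgery_limit,
                  stop("no benchmark for category ", category))
  mean(w[keep] <= limit)
}

#' Summary-table row
#'
#' The six cross-replication summary statistics reported per metric: mean,
#' sample standard deviation (n-1 denominator), median, minimum, maximum and
#' range.
#'
#' @param x Non-empty numeric sample.
#' @return Named numeric vector `mean, sd, median, min, max, range`.
#' @export
summarize_metric <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty sample")
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
    median = stats::median(x), min = min(x), max = max(x),
    range = max(x) - min(x))
}

#' Sequential replication control
#'
#' Smallest replication count at which the t-based confidence interval of the
#' running mean is narrower than a relative half-width target — the stopping
#' rule used to decide how many simulation runs a scenario needs for a given
#' statistical accuracy.
#'
#' @param x Stream of per-replication means (numeric vector, consumed in
#'   order).
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @param relative_halfwidth Target half-width as a fraction of the absolute
#'   running mean, default 0.05 (the "95% accuracy" reading; use 0.01 for
#'   "99%").
#' @param pilot Minimum number of replications before the rule may stop
#'   (default 10).
#' @return List with `n` (replications needed, `NA` if the stream ended
#'   before the target was met), `mean`, `halfwidth` at the stopping point,
#'   and `satisfied`.
#' @export
required_replications <- function(x, confidence = 0.95,
                                  relative_halfwidth = 0.05, pilot = 10L) {
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (relative_halfwidth <= 0) stop("relative_halfwidth must be positive")
  pilot <- max(2L, as.integer(pilot))
  if (length(x) < pilot) stop("stream shorter than the pilot size")
  alpha <- 1 - confidence
  for (n in pilot:length(x)) {
    m <- mean(x[1:n]); s <- stats::sd(x[1:n])
    hw <- stats::qt(1 - alpha / 2, n - 1) * s / sqrt(n)
    if (s == 0)
      return(list(n = n, mean = m, halfwidth = 0, satisfied = TRUE))
    if (m == 0) stop("running mean is zero: relative precision undefined, ",
                     "use an absolute-precision rule")
    if (hw <= relative_halfwidth * abs(m))
      return(list(n = n, mean = m, halfwidth = hw, satisfied = TRUE))
  }
  list(n = NA_integer_, mean = mean(x), halfwidth = hw, satisfied = FALSE)
}

# per-replication outcome metrics of one replication result
replication_metrics <- function(rep, bm = benchmarks()) {
  p <- rep$patients
  w <- critical_wait(p)
  tst <- total_system_time(p)
  red <- p$final_category == "red" & !is.na(w)
  yel <- p$final_category == "yellow" & !is.na(w)
  red_t <- p$final_category == "red" & !is.na(tst)
  c(red_critical_wait = if (any(red)) mean(w[red]) else NA_real_,
    yellow_critical_wait = if (any(yel)) mean(w[yel]) else NA_real_,
    red_total_system_time = if (any(red_t)) mean(tst[red_t]) else NA_real_,
    red_compliance = if (any(red)) mean(w[red] <= bm$red_surgery_limit)
                     else NA_real_,
    yellow_compliance = if (any(yel)) mean(w[yel] <= bm$yellow_surgery_limit)
                        else NA_real_,
    deaths = rep$deaths)
}

#' Run a scenario over replications
#'
#' Fixed-replication evaluation of one scenario: runs `replications`
#' independent replications (seeds `seed + 1 ... seed + replications`, so two
#' scenarios evaluated with the same `seed` are coupled by common random
#' numbers) and collects per-replication outcome metrics plus their six-way
#' summaries.
#'
#' @param scenario An [scenario_config()].
#' @param replications Number of replications (default: the scenario's).
#' @param seed Base seed (default: the scenario's master seed).
#' @param bm An [benchmarks()] object.
#' @return List of class `mci_simulation` with `metrics` (one row per
#'   replication), `summary` (metric x statistic matrix), `scenario`,
#'   and `replications`.
#' @export
run_scenario <- function(scenario, replications = scenario$replications,
                         seed = scenario$seed, bm = benchmarks()) {
  rows <- vector("list", replications)
  for (r in seq_len(replications)) {
    rep <- run_replication(scenario, seed = seed + r)
    rows[[r]] <- replication_metrics(rep, bm)
  }
  metrics <- do.call(rbind, rows)
  metrics <- as.data.frame(metrics)
  metrics$replication <- seq_len(replications)
  summ <- t(vapply(setdiff(names(metrics), "replication"), function(nm) {
    v <- metrics[[nm]]
    if (all(is.na(v))) rep(NA_real_, 6) else summarize_metric(v)
  }, numeric(6)))
  colnames(summ) <- c("mean", "sd", "median", "min", "max", "range")
  structure(list(metrics = metrics, summary = summ, scenario = scenario,
                 replications = replications, seed = seed, benchmarks = bm),
            class = "mci_simulation")
}

#' @export
print.mci_simulation <- function(x, ...) {
  cat("MCI simulation:", x$scenario$label, "-", x$replications,
      "replications\n\n")
  print(round(x$summary, 2))
  invisible(x)
}

#' @export
summary.mci_simulation <- function(object, ...) {
  s <- object$summary
  bm <- object$benchmarks
  cat("Scenario:", object$scenario$label, "\n")
  cat(sprintf("Mean waiting time for critical treatment, severely injured: %.1f min (benchmark %g)\n",
              s["red_critical_wait", "mean"], bm$red_surgery_limit))
  cat(sprintf("Mean waiting time for critical treatment, moderately injured: %.1f min (benchmark %g)\n",
              s["yellow_critical_wait", "mean"], bm$yellow_surgery_limit))
  cat(sprintf("Mean total system time, severely injured: %.1f min (limit %g)\n",
              s["red_total_system_time", "mean"], bm$red_total_system_limit))
  cat(sprintf("Red benchmark compliance: %.1f%%; mean deaths per replication: %.2f\n",
              100 * s["red_compliance", "mean"], s["deaths", "mean"]))
  invisible(s)
}
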