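## Analytic multi-server queue used as an independent oracle for the engine.

#' Erlang-C mean waiting time
#'
#' Closed-form steady-state mean queue wait of an M/M/c queue: the Erlang-C
#' delay probability divided by `c*mu - lambda`.
#'
#' @param lambda Arrival rate (per minute).
#' @param mu Per-server service rate (per minute).
#' @param c Number of servers.
#' @return List with `p_wait` (delay probability) and `wq` (mean queue wait,
#'   minutes).
#' @export
erlang_c_wait <- function(lambda, mu, c) {
  if (lambda <= 0 || mu <= 0 || c < 1) stop("need lambda, mu > 0 and c >= 1")
  a <- lambda / mu
  rho <- a / c
  if (rho >= 1) stop("unstable queue: lambda >= c * mu")
  # Erlang-C via the stable recurrence on the Erlang-B blocking probability
  b <- 1
  for (k in 1:c) b <- a * b / (k + a * b)
  p_wait <- b / (1 - rho * (1 - b))
  list(p_wait = p_wait, wq = p_wait / (c * mu - lambda))
}

#' Degenerate single-station scenario (M/M/c reduction)
#'
#' Collapses the simulator to a single-station queue: `n` moderately injured
#' patients arrive as a Poisson process of rate `lambda`, pass a zero-length
#' unstaffed triage, and queue for an exponential examination of rate `mu`
#' served by `c` identical servers; no imaging, no surgery, no health
#' dynamics, no routine load. The engine's mean examination queue wait can
#' then be validated against [erlang_c_wait()].
#'
#' @param n Number of arrivals to simulate.
#' @param lambda Arrival rate per minute.
#' @param mu Service rate per minute.
#' @param c Number of servers.
#' @param seed Master seed.
#' @return An `mci_scenario`.
#' @export
make_mmc_scenario <- function(n, lambda, mu, c, seed = 1L) {
  h <- health_dynamics(d_red = 0, d_yellow = 0, d_green = 0)
  cal <- calibration(
    service = list(triage = service_dist("fixed", 0),
                   yellow_exam = service_dist("exponential", 1 / mu),
                   transfer_out = service_dist("fixed", 0)),
    health = h,
    p_surgery_red = 0, p_surgery_yellow = 0,
    p_ct_red = 0, p_xray_red = 0, p_ct_yellow = 0, p_xray_yellow = 0,
    staffing = list(triage = list(),
                    yellow_exam = list(staff_group("general_nurses"))),
    routine_rate_per_min = 0)
  scenario_config(
    label = sprintf("M/M/%d reduction", c),
    staff = staff_vector(1, 1, 1, c, 1, 1, 1),
    load = patient_load(0, n, 0, arrival_window_min = n / lambda,
                        incident_time_of_day = 0),
    resources = resource_set(n_yellow_treatment_slots = c),
    calibration = cal, seed = seed)
}

#' Simulated mean queue wait of the M/M/c reduction
#'
#' Runs [make_mmc_scenario()] replications and returns per-replication mean
#' examination queue waits after discarding a warm-up fraction of arrivals.
#'
#' @param n Arrivals per replication.
#' @param lambda,mu,c Queue parameters as in [erlang_c_wait()].
#' @param replications Number of independent replications.
#' @param seed Base seed.
#' @param warmup Fraction of earliest arrivals discarded per replication.
#' @return Numeric vector of per-replication mean waits.
#' @export
simulate_mmc_waits <- function(n, lambda, mu, c, replications = 10,
                               seed = 1L, warmup = 0.1) {
  sc <- make_mmc_scenario(n, lambda, mu, c, seed = seed)
  vapply(seq_len(replications), function(r) {
    rep <- run_replication(sc, seed = seed + r)
    p <- rep$patients
    w <- p$first_treatment_start - p$arrival
    keep <- rank(p$arrival) > warmup * n
    mean(w[keep])
  }, numeric(1))
}
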