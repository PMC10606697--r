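# build a minimal patient record data frame for metric tests
record <- function(arrival, first = NA, surgery = NA, exit = NA,
                   category = "red", needs_surgery = !is.na(surgery),
                   deceased = FALSE) {
  data.frame(arrival = arrival, first_treatment_start = first,
             surgery_start = surgery, exit_time = exit,
             final_category = category, needs_surgery = needs_surgery,
             deceased = deceased, stringsAsFactors = FALSE)
}

test_that("critical wait uses surgery start for surgical and first treatment otherwise", {
  surg <- record(10, first = 60, surgery = 150)
  expect_equal(critical_wait(surg), 140)
  nonsurg <- record(0, first = 35, category = "yellow")
  expect_equal(critical_wait(nonsurg), 35)
  # deceased before the defining event: excluded (NA), tallied separately
  dead <- record(0, deceased = TRUE, needs_surgery = TRUE)
  expect_true(is.na(critical_wait(dead)))
})

test_that("total system time is exit minus arrival and errors for in-system patients", {
  p <- record(0, first = 10, exit = 200)
  expect_equal(total_system_time(p), 200)
  # exit without surgery still counts from arrival to exit
  p2 <- record(5, first = 10, exit = 120)
  expect_equal(total_system_time(p2), 115)
  p3 <- record(0, first = 10)          # never exited, not deceased
  expect_error(total_system_time(p3), "still in system")
})

test_that("compliance fraction counts waits within the category benchmark", {
  p <- do.call(rbind, list(record(0, first = 1, surgery = 100),
                           record(0, first = 1, surgery = 130),
                           record(0, first = 1, surgery = 110)))
  expect_equal(compliance_fraction(p, "red"), 2 / 3)
  all_ok <- record(0, first = 1, surgery = 50)
  expect_equal(compliance_fraction(all_ok, "red"), 1)
  expect_error(compliance_fraction(record(0, first = 1, category = "green"),
                                   "red"), "no eligible")
  # antitone in the limit: lowering a benchmark never raises compliance
  waits <- seq(20, 300, by = 20)
  p4 <- do.call(rbind, lapply(waits, function(w)
    record(0, first = 1, surgery = w)))
  lims <- c(50, 100, 150, 250, 400)
  comp <- vapply(lims, function(L)
    compliance_fraction(p4, "red", benchmarks(red_surgery_limit = L)),
    numeric(1))
  expect_true(all(diff(comp) >= 0))
})

test_that("summary rows satisfy their identities", {
  s <- summarize_metric(c(1, 2, 3, 4))
  expect_equal(unname(s["mean"]), 2.5)
  expect_equal(unname(s["median"]), 2.5)
  expect_equal(unname(s["sd"]), sd(c(1, 2, 3, 4)))
  expect_equal(unname(s["range"]), unname(s["max"] - s["min"]))

  s1 <- summarize_metric(7)
  expect_equal(unname(s1[c("mean", "median", "min", "max")]), rep(7, 4))
  expect_equal(unname(s1[c("sd", "range")]), c(0, 0))
  expect_error(summarize_metric(numeric(0)), "empty")

  # property: identities on random samples
  set.seed(99)
  for (k in 1:25) {
    x <- rnorm(sample(2:40, 1), sd = sample(1:10, 1))
    s <- summarize_metric(x)
    expect_lte(s[["min"]], s[["median"]])
    expect_lte(s[["median"]], s[["max"]])
    expect_equal(s[["range"]], s[["max"]] - s[["min"]])
    expect_gte(s[["sd"]], 0)
  }
})

test_that("replication stopping matches the closed-form sample size within 10%", {
  mu <- 100; sigma <- 12; gamma <- 0.05
  n_star <- (qnorm(0.975) * sigma / (gamma * mu))^2
  set.seed(7)
  stops <- replicate(300, {
    required_replications(rnorm(800, mu, sigma), 0.95, gamma)$n
  })
  expect_true(all(!is.na(stops)))
  expect_lt(abs(mean(stops) - n_star) / n_star, 0.10)
})

test_that("replication stopping handles degenerate and monotone cases", {
  expect_equal(required_replications(rep(5, 50))$n, 10)
  set.seed(3)
  x <- rnorm(4000, 50, 10)
  n5 <- required_replications(x, relative_halfwidth = 0.05)$n
  n1 <- required_replications(x, relative_halfwidth = 0.01)$n
  expect_gte(n1, n5)
  n90 <- required_replications(x, confidence = 0.90,
                               relative_halfwidth = 0.05)$n
  expect_lte(n90, n5)
  expect_error(required_replications(rep(c(-1, 1), 5), pilot = 2), "zero")
  expect_error(required_replications(rnorm(5), pilot = 10), "pilot")
  expect_error(required_replications(rnorm(50), confidence = 1.2), "confidence")
})

test_that("stopped intervals achieve close to nominal coverage", {
  set.seed(11)
  mu <- 40; sigma <- 6
  hits <- replicate(700, {
    x <- rnorm(400, mu, sigma)
    st <- required_replications(x, 0.95, 0.05)
    abs(st$mean - mu) <= st$halfwidth
  })
  expect_lt(abs(mean(hits) - 0.95), 0.04)
})

test_that("run_scenario returns per-replication metrics and coherent summaries", {
  sc <- tiny_scenario()
  sim <- run_scenario(sc, replications = 8, seed = 100)
  expect_equal(nrow(sim$metrics), 8)
  s <- sim$summary
  expect_true(all(s[, "min"] <= s[, "median"] & s[, "median"] <= s[, "max"]))
  expect_equal(unname(s[, "range"]), unname(s[, "max"] - s[, "min"]))
  # determinism of the whole pipeline
  sim2 <- run_scenario(sc, replications = 8, seed = 100)
  expect_equal(sim$metrics, sim2$metrics)
})
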