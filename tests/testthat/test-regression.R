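# staff grid with a response generated from the reference surface
surface_data <- function(noise_sd = 0, seed = NULL) {
  g <- factorial_grid()
  g$y <- reference_surface_predict(g)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    g$y <- g$y + rnorm(nrow(g), 0, noise_sd)
  }
  g
}

test_that("a noise-free response on the balanced grid is recovered exactly", {
  g <- surface_data()
  m <- fit_ols(g, "y", main_effect_terms(staff_categories()))
  expect_lt(max(abs(coef(m) - reference_surface())), 1e-8)
  # orthogonal balanced design: every VIF and tolerance exactly 1
  expect_equal(m$coefficients$vif[-1], rep(1, 7), tolerance = 1e-10)
  expect_equal(m$coefficients$tolerance[-1], rep(1, 7), tolerance = 1e-10)
  expect_gt(m$r_squared, 1 - 1e-12)
  # predict at the zero staff vector returns the intercept
  zero <- setNames(as.list(rep(0, 7)), staff_categories())
  expect_equal(predict(m, zero), 335.88, tolerance = 1e-8)
})

test_that("prediction is the linear combination of terms", {
  g <- surface_data()
  m <- fit_ols(g, "y", main_effect_terms(staff_categories()))
  base <- setNames(as.list(c(11, 5, 6, 23, 2, 5, 2)), staff_categories())
  # independent term-by-term arithmetic on the printed coefficients
  hand <- 335.88 - 0.71 * 11 - 3.34 * 5 - 9.57 * 6 - 0.17 * 23 -
    2.98 * 2 - 8.88 * 5 - 34.61 * 2
  expect_equal(predict(m, base), hand, tolerance = 1e-8)
  # additivity in a single coordinate
  bumped <- base; bumped$radiology_assistants <- 3
  expect_equal(predict(m, bumped) - predict(m, base), -34.61,
               tolerance = 1e-8)
})

test_that("rank deficiency and undersized fits are refused", {
  g <- surface_data()
  g$dup <- g$radiology_assistants
  expect_error(fit_ols(g, "y", c("radiology_assistants", "dup")),
               "rank-deficient|aliased")
  small <- g[1:3, ]
  expect_error(fit_ols(small, "y", main_effect_terms(staff_categories())),
               "more rows")
})

test_that("coefficient estimates are invariant to dropping other main effects on the balanced grid", {
  g <- surface_data(noise_sd = 21, seed = 123)
  full <- fit_ols(g, "y", main_effect_terms(staff_categories()))
  reduced <- fit_ols(g, "y", c("radiology_assistants", "surgical_nurses"))
  for (tm in c("radiology_assistants", "surgical_nurses")) {
    b_full <- full$coefficients$B[full$coefficients$term == tm]
    b_red <- reduced$coefficients$B[reduced$coefficients$term == tm]
    expect_equal(b_full, b_red, tolerance = 1e-8)
  }
})

test_that("the F statistic satisfies its R-squared identity", {
  for (s in c(10, 40)) {
    g <- surface_data(noise_sd = s, seed = s)
    m <- fit_ols(g, "y", main_effect_terms(staff_categories()))
    p <- 7; n <- m$n
    expect_equal(m$f_statistic,
                 (m$r_squared / (1 - m$r_squared)) * ((n - p - 1) / p),
                 tolerance = 1e-10)
  }
})

test_that("PRESS predicted R2 equals brute-force leave-one-out on small fits", {
  set.seed(42)
  n <- 60
  d <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  d$y <- 3 + 2 * d$x1 - d$x2 + rnorm(n, 0, 2)
  m <- fit_ols(d, "y", c("x1", "x2"))
  press_loo <- sum(vapply(seq_len(n), function(i) {
    fi <- lm(y ~ x1 + x2, data = d[-i, ])
    (d$y[i] - predict(fi, d[i, ]))^2
  }, numeric(1)))
  expect_equal(m$press, press_loo, tolerance = 1e-10)
  expect_equal(m$predicted_r_squared,
               1 - press_loo / sum((d$y - mean(d$y))^2), tolerance = 1e-10)
})

test_that("confidence intervals cover the generating coefficients at nominal rate", {
  true <- reference_surface()
  g0 <- factorial_grid()
  mu <- reference_surface_predict(g0)
  set.seed(2024)
  n_rep <- 400
  hits <- matrix(FALSE, n_rep, 8)
  for (r in seq_len(n_rep)) {
    g0$y <- mu + rnorm(nrow(g0), 0, 21)
    m <- fit_ols(g0, "y", main_effect_terms(staff_categories()))
    hits[r, ] <- m$coefficients$ci_lower <= true &
      true <= m$coefficients$ci_upper
  }
  cover <- colMeans(hits)
  expect_true(all(abs(cover - 0.95) < 0.035))
})

test_that("standardized-effect Pareto ranking is ordered, tie-stable and matches |Beta| on orthogonal designs", {
  g <- surface_data(noise_sd = 21, seed = 7)
  m <- fit_ols(g, "y", main_effect_terms(staff_categories()))
  pe <- pareto_standardized_effects(m)
  expect_true(all(diff(pe$abs_t) <= 1e-12))
  # on the balanced grid |t| ranking equals |Beta| ranking
  expect_equal(order(-pe$abs_t), order(-abs(pe$Beta)))
  # the documented dominant effects: radiology assistants, then rotation
  # physicians, mirror the generating surface scaled by the level spreads
  expect_equal(pe$term[1], "radiology_assistants")
  expect_equal(pe$term[2], "rotation_physicians")
  expect_equal(attr(pe, "reference_line"), qt(0.975, m$df_residual))

  # exact ties break stably by term name: orthogonal +/-1 design with a
  # residual vector orthogonal to both columns gives identical t statistics
  d <- data.frame(a = rep(c(-1, 1), 20), b = rep(c(-1, 1), each = 20))
  e <- rep(c(1, -1, -1, 1), 10)
  d$y <- d$a + d$b + e
  mt <- fit_ols(d, "y", c("b", "a"))
  pt <- pareto_standardized_effects(mt)
  expect_equal(pt$abs_t[1], pt$abs_t[2])
  expect_equal(pt$term, c("a", "b"))

  m0 <- fit_ols(data.frame(z = rnorm(20), y = rnorm(20)), "y", "1")
  expect_error(pareto_standardized_effects(m0), "intercept-only")
})

test_that("forward stepwise picks true structure before noise and stops when stuck", {
  set.seed(31)
  n <- 300
  d <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
                  n1 = rnorm(n), n2 = rnorm(n))
  d$y <- 5 + 4 * d$x1 + rnorm(n, 0, 0.5)
  rep1 <- stepwise_build(c("x1", "n1", "n2"), d, "y")
  expect_equal(rep1$term[1], "x1")

  # pure noise: nothing improves adjusted R2 enough to build a model of
  # more than chance size
  d$z <- rnorm(n)
  rep0 <- stepwise_build(c("n1", "n2"), d, "z")
  expect_lte(nrow(rep0), 1)

  # strong curvature and interaction enter before weak linear terms
  d$y2 <- 10 + 8 * d$x1^2 + 6 * d$x1 * d$x2 + 0.1 * d$n1 + rnorm(n, 0, 0.5)
  cands <- c("x1", "x2", "n1", "n2", quadratic_terms(c("x1", "x2")),
             interaction_terms(c("x1", "x2")))
  rep2 <- stepwise_build(cands, d, "y2")
  quad_step <- match("I(x1^2)", rep2$term)
  noise_steps <- match(c("n1", "n2"), rep2$term)
  expect_true(quad_step <= 2)
  expect_true(all(is.na(noise_steps) | noise_steps > quad_step))
  # the report records adjusted R2 at every step, non-decreasing
  expect_true(all(diff(rep2$adj_r_squared) >= 0))

  # hierarchy mode delays higher-order terms until their parents entered
  rep3 <- stepwise_build(cands, d, "y2", hierarchy = TRUE)
  for (k in seq_len(nrow(rep3))) {
    tm <- rep3$term[k]
    if (grepl("\\^2|:", tm)) {
      pars <- if (grepl(":", tm)) strsplit(tm, ":")[[1]]
              else sub("^I\\((.+)\\^2\\)$", "\\1", tm)
      expect_true(all(pars %in% rep3$term[seq_len(k - 1)]))
    }
  }
  expect_error(stepwise_build(character(0), d, "y"), "no candidate")
})

test_that("residual diagnostics calibrate on normal data and detect heavy tails", {
  set.seed(77)
  n <- 1200
  d <- data.frame(x = runif(n, 0, 10))
  # normal residuals: all four tests should rarely reject
  rejections <- replicate(120, {
    d$y <- 1 + 2 * d$x + rnorm(n)
    m <- fit_ols(d, "y", "x")
    rd <- residual_diagnostics(m)
    rd$normality$p_value < 0.05
  })
  rates <- rowMeans(rejections)
  expect_true(all(rates < 0.12))

  # heavy-tailed residuals: all four tests reject decisively
  d$y <- 1 + 2 * d$x + rt(n, df = 2)
  m <- fit_ols(d, "y", "x")
  rd <- residual_diagnostics(m)
  expect_true(all(rd$normality$p_value < 1e-4))
  expect_setequal(rd$normality$test,
                  c("anderson_darling", "lilliefors", "shapiro_francia",
                    "jarque_bera"))

  # heteroscedastic residuals are flagged by the Breusch-Pagan check
  d$y <- 1 + 2 * d$x + rnorm(n, 0, 0.2 + 0.4 * d$x)
  mh <- fit_ols(d, "y", "x")
  expect_lt(residual_diagnostics(mh)$heteroscedasticity$p_value, 0.01)

  # degenerate input
  d$y <- 2 * d$x + 3
  md <- fit_ols(d, "y", "x")
  expect_error(residual_diagnostics(md), "degenerate|constant")
})
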