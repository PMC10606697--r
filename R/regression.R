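## Response-surface OLS toolkit: main-effects fits with the full diagnostic
## suite (standardized effects, VIF/tolerance, PRESS/predicted R2, ANOVA F),
## Pareto ranking of standardized effects, and forward stepwise building with
## interactions and quadratic terms.

#' Term constructors for response-surface models
#'
#' Build term labels for [fit_ols()] and [stepwise_build()]: linear main
#' effects, quadratic terms and two-way interactions over named predictors.
#'
#' @param vars Character vector of predictor names.
#' @return Character vector of model-term labels.
#' @export
main_effect_terms <- function(vars) vars

#' @rdname main_effect_terms
#' @export
quadratic_terms <- function(vars) sprintf("I(%s^2)", vars)

#' @rdname main_effect_terms
#' @export
interaction_terms <- function(vars) {
  if (length(vars) < 2) return(character(0))
  cmb <- utils::combn(vars, 2)
  sprintf("%s:%s", cmb[1, ], cmb[2, ])
}

#' Fit a response-surface OLS model
#'
#' Ordinary least squares of a response on the given model terms, with the
#' full diagnostic suite: per-term unstandardized (B) and standardized (Beta)
#' coefficients, standard errors, t and two-sided p values, 95% confidence
#' intervals; R2, adjusted R2, predicted R2 (leave-one-out PRESS via the hat
#' matrix), residual standard error, ANOVA F, and per-term variance inflation
#' factors with tolerances.
#'
#' @param data Data frame of predictors (e.g. an enumerated staff grid with
#'   simulated responses attached).
#' @param response Name of the response column.
#' @param terms Character vector of term labels (see [main_effect_terms()]).
#' @return Object of class `mci_ols`.
#' @export
fit_ols <- function(data, response, terms) {
  if (!response %in% names(data)) stop("response column not found: ", response)
  n <- nrow(data)
  if (n <= length(terms) + 1) stop("need more rows than model terms")
  f <- stats::reformulate(terms, response = response)
  fit <- stats::lm(f, data = data)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: aliased or duplicated model terms")
  # zero-noise validation responses legitimately produce perfect fits
  perfect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  sm <- perfect(summary(fit))
  ct <- sm$coefficients
  y <- data[[response]]
  sdy <- stats::sd(y)
  beta <- c(NA_real_, vapply(colnames(X)[-1], function(cn)
    unname(stats::coef(fit)[cn]) * stats::sd(X[, cn]) / sdy, numeric(1)))
  ci <- perfect(stats::confint(fit, level = 0.95))
  # VIF via the auxiliary regression of each model column on the others
  vif <- rep(NA_real_, ncol(X))
  for (j in seq(2, length.out = max(0, ncol(X) - 1))) {
    aux <- stats::lm.fit(X[, -j, drop = FALSE], X[, j])
    xj <- X[, j]
    ssr <- sum(aux$residuals^2)
    sst <- sum((xj - mean(xj))^2)
    vif[j] <- if (sst > 0) sst / ssr else NA_real_
  }
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  e <- stats::residuals(fit)
  press <- sum((e / (1 - h))^2)
  sst_y <- sum((y - mean(y))^2)
  p <- length(stats::coef(fit)) - 1L
  fstat <- if (p > 0) unname(sm$fstatistic[1]) else NA_real_
  fp <- if (p > 0)
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE) else NA_real_
  coef_table <- data.frame(
    term = rownames(ct), B = ct[, 1], Beta = beta, se = ct[, 2],
    t = ct[, 3], p = ct[, 4], ci_lower = ci[, 1], ci_upper = ci[, 2],
    vif = vif, tolerance = 1 / vif, row.names = NULL,
    stringsAsFactors = FALSE)
  structure(list(
    fit = fit, terms = terms, response = response,
    coefficients = coef_table,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    predicted_r_squared = 1 - press / sst_y, press = press,
    sigma = sm$sigma, f_statistic = fstat, f_p_value = fp,
    df_residual = fit$df.residual, n = n), class = "mci_ols")
}

#' @export
print.mci_ols <- function(x, ...) {
  cat("Response-surface OLS:", x$response, "~",
      paste(x$terms, collapse = " + "), "\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("R2 = %.4f, adjusted R2 = %.4f, predicted R2 = %.4f\n",
              x$r_squared, x$adj_r_squared, x$predicted_r_squared))
  cat(sprintf("Residual SE = %.4f on %d df; F = %.2f (p %s)\n", x$sigma,
              x$df_residual, x$f_statistic,
              format.pval(x$f_p_value, digits = 3)))
  invisible(x)
}

#' @export
summary.mci_ols <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.mci_ols <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.mci_ols <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.mci_ols <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Pareto ranking of standardized effects
#'
#' Non-intercept model terms ranked by the absolute value of their t
#' statistic (equivalently, on orthogonal designs, by |Beta|), with the
#' two-sided critical t at the residual degrees of freedom as the
#' significance reference line. Ties break alphabetically by term name.
#'
#' @param model An `mci_ols`.
#' @param alpha Significance level of the reference line.
#' @return Data frame (term, t, abs_t, Beta, p) in descending |t| order with
#'   attribute `reference_line`.
#' @export
pareto_standardized_effects <- function(model, alpha = 0.05) {
  tab <- model$coefficients[-1, , drop = FALSE]
  if (!nrow(tab)) stop("intercept-only model has no effects to rank")
  out <- data.frame(term = tab$term, t = tab$t, abs_t = abs(tab$t),
                    Beta = tab$Beta, p = tab$p, stringsAsFactors = FALSE)
  out <- out[order(-out$abs_t, out$term), ]
  rownames(out) <- NULL
  attr(out, "reference_line") <-
    stats::qt(1 - alpha / 2, model$df_residual)
  out
}

#' @export
plot.mci_ols <- function(x, ...) {
  par_eff <- pareto_standardized_effects(x)
  graphics::barplot(rev(par_eff$abs_t), names.arg = rev(par_eff$term),
                    horiz = TRUE, las = 1, xlab = "|t|",
                    main = "Pareto chart of standardized effects", ...)
  graphics::abline(v = attr(par_eff, "reference_line"), lty = 2)
  invisible(par_eff)
}

#' Forward stepwise model building
#'
#' Adds, one at a time, the candidate term with the largest adjusted-R2 gain
#' and stops when no candidate improves adjusted R2. By default terms may
#' enter in any order (a quadratic or interaction may precede its parent
#' main effects); with `hierarchy = TRUE` a higher-order term may only enter
#' once its parents are in the model.
#'
#' @param candidates Character vector of candidate term labels.
#' @param data Data frame of predictors plus response.
#' @param response Response column name.
#' @param hierarchy Enforce hierarchical entry (default `FALSE`).
#' @return Data frame of class `mci_buildreport`: one row per building step
#'   (step, term, adj_r_squared, r_squared).
#' @export
stepwise_build <- function(candidates, data, response, hierarchy = FALSE) {
  if (!length(candidates)) stop("no candidate terms")
  parents <- function(term) {
    if (grepl("^I\\((.+)\\^2\\)$", term))
      return(sub("^I\\((.+)\\^2\\)$", "\\1", term))
    if (grepl(":", term)) return(strsplit(term, ":", fixed = TRUE)[[1]])
    character(0)
  }
  chosen <- character(0)
  cur_adj <- 0
  cur_r2 <- 0
  steps <- list()
  repeat {
    pool <- setdiff(candidates, chosen)
    if (hierarchy)
      pool <- pool[vapply(pool, function(tm)
        all(parents(tm) %in% chosen), TRUE)]
    if (!length(pool)) break
    gains <- vapply(pool, function(tm) {
      m <- tryCatch(fit_ols(data, response, c(chosen, tm)),
                    error = function(e) NULL)
      if (is.null(m)) -Inf else m$adj_r_squared
    }, numeric(1))
    best <- which.max(gains)
    if (!is.finite(gains[best]) || gains[best] <= cur_adj) break
    chosen <- c(chosen, pool[best])
    m <- fit_ols(data, response, chosen)
    cur_adj <- m$adj_r_squared
    cur_r2 <- m$r_squared
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(chosen), term = pool[best], adj_r_squared = cur_adj,
      r_squared = cur_r2, stringsAsFactors = FALSE)
  }
  out <- if (length(steps)) do.call(rbind, steps)
         else data.frame(step = integer(0), term = character(0),
                         adj_r_squared = numeric(0), r_squared = numeric(0))
  class(out) <- c("mci_buildreport", "data.frame")
  out
}

#' Residual diagnostics
#'
#' Four residual-normality tests — Anderson-Darling and Lilliefors
#' (EDF-based), Shapiro-Francia (correlation-based) and Jarque-Bera
#' (moment-based) — plus a Breusch-Pagan heteroscedasticity check regressing
#' squared residuals on fitted values.
#'
#' @param model An `mci_ols`.
#' @return List with `normality` (data frame: test, statistic, p_value) and
#'   `heteroscedasticity` (statistic, p_value).
#' @export
residual_diagnostics <- function(model) {
  e <- stats::residuals(model$fit)
  if (length(e) < 8) stop("too few residuals for the diagnostic suite")
  if (stats::sd(e) < 1e-10 * (stats::sd(stats::fitted(model$fit)) + 1))
    stop("degenerate (constant or numerically zero) residuals")
  jb <- jarque_bera(e)
  tests <- list(
    anderson_darling = nortest::ad.test(e),
    lilliefors = nortest::lillie.test(e),
    shapiro_francia = nortest::sf.test(e),
    jarque_bera = jb)
  normality <- data.frame(
    test = names(tests),
    statistic = vapply(tests, function(t) unname(t$statistic), numeric(1)),
    p_value = vapply(tests, function(t) unname(t$p.value), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  fv <- stats::fitted(model$fit)
  bp <- lmtest::bptest(model$fit, varformula = ~ fv,
                       data = data.frame(fv = fv))
  list(normality = normality,
       heteroscedasticity = list(statistic = unname(bp$statistic),
                                 p_value = unname(bp$p.value)))
}

# moment-based normality test (skewness/kurtosis), chi-squared with 2 df
jarque_bera <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  stat <- n * (skew^2 / 6 + (kurt - 3)^2 / 24)
  list(statistic = c(JB = stat),
       p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Reference main-effects response surface
#'
#' A fixed linear surface over the seven staff categories — mean red total
#' system time in minutes as a function of headcounts — used as a validation
#' oracle for the fitting machinery (fitting a response generated from these
#' coefficients on the balanced staff grid must recover them exactly).
#'
#' @return Named coefficient vector (intercept first).
#' @export
reference_surface <- function() {
  c("(Intercept)" = 335.88,
    medical_specialists = -0.71, medical_assistants = -3.34,
    rotation_physicians = -9.57, general_nurses = -0.17,
    surgical_assistants = -2.98, surgical_nurses = -8.88,
    radiology_assistants = -34.61)
}

#' Evaluate the reference surface at staff values
#'
#' @param staff Named staff counts (a staff vector or data frame of rows).
#' @param coefs Coefficient vector as from [reference_surface()].
#' @return Predicted response value(s).
#' @export
reference_surface_predict <- function(staff, coefs = reference_surface()) {
  if (is.data.frame(staff)) {
    X <- as.matrix(staff[, names(coefs)[-1], drop = FALSE])
  } else {
    X <- matrix(unlist(staff[names(coefs)[-1]]), nrow = 1,
                dimnames = list(NULL, names(coefs)[-1]))
  }
  unname(coefs[1] + drop(X %*% coefs[-1]))
}
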