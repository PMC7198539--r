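#' Propensity model specification
#'
#' The default covariate set for the probability of initiating brand
#' treatment: sex, age (continuous), low-income (CMU) status, polypharmacy,
#' Charlson class (0 / 1-2 / >=3), fracture history, year of initiation
#' (categorical), administration frequency, prescriber specialty, plus a
#' year-by-frequency interaction. Rows with unknown prescriber specialty
#' are treated as missing, dropped and counted.
#'
#' @param formula Model formula with the brand indicator on the left.
#' @return An object of class `propensity_spec`.
#' @export
propensity_spec <- function(formula = brand ~ sex + age + cmu + polypharmacy +
                              charlson + fracture_history +
                              factor(year) * frequency + specialty) {
  structure(list(formula = formula), class = "propensity_spec")
}

#' Fit the propensity of brand initiation
#'
#' Logistic regression of the brand indicator on the specified covariates.
#' Rows with missing prescriber specialty (level `"unknown"` or `NA`) are
#' excluded and counted. Non-convergence and separation (fitted
#' probabilities collapsing to 0/1, or runaway coefficients) raise errors
#' naming the offending covariate.
#'
#' @param cohort Analysis cohort table (needs `group` plus the model
#'   covariates).
#' @param spec A [propensity_spec()].
#' @return A list of class `propensity_fit`: `data` (rows used, with
#'   `pscore`), `fit`, `n_excluded_missing`, `marginal` (empirical brand
#'   share of the rows used).
#' @export
fit_propensity <- function(cohort, spec = propensity_spec()) {
  dat <- as.data.frame(cohort)
  dat$brand <- as.integer(dat$group == "brand")
  miss <- rep(FALSE, nrow(dat))
  if ("specialty" %in% names(dat)) {
    miss <- is.na(dat$specialty) | dat$specialty == "unknown"
  }
  vars <- all.vars(spec$formula)
  for (v in setdiff(vars, "brand")) {
    if (v %in% names(dat)) miss <- miss | is.na(dat[[v]])
  }
  used <- dat[!miss, , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(spec$formula, data = used, family = stats::binomial()))
  ps <- stats::fitted(fit)
  # separation: a non-negligible share of fitted probabilities pinned at
  # 0/1 (a single sparse interaction cell saturating is tolerated; scores
  # stay strictly inside (0,1) at machine precision)
  extreme <- ps < 1e-8 | ps > 1 - 1e-8
  if (mean(extreme) > 0.01) {
    cf <- stats::coef(fit)
    cf <- cf[!is.na(cf) & names(cf) != "(Intercept)"]
    worst <- names(cf)[which.max(abs(cf))]
    stop("separation detected in propensity model (",
         round(100 * mean(extreme)), "% of fitted probabilities at 0/1); ",
         "largest coefficient: ", worst, call. = FALSE)
  }
  if (!fit$converged) {
    stop("propensity model did not converge", call. = FALSE)
  }
  # numerical guard: keep scores strictly inside (0,1) at double precision
  used$pscore <- pmin(pmax(as.numeric(ps), 1e-12), 1 - 1e-12)
  structure(list(data = used, fit = fit,
                 n_excluded_missing = sum(miss),
                 marginal = mean(used$brand)),
            class = "propensity_fit")
}

#' Stabilized inverse probability of treatment weight
#'
#' Treated (brand) patients receive `marginal / score`, controls
#' `(1 - marginal) / (1 - score)`: the inverse-probability weight
#' stabilized by the marginal prevalence of the received treatment, so the
#' weights average to about 1 and the pseudo-population keeps the original
#' size.
#'
#' @param score Propensity score(s) strictly in (0, 1).
#' @param treated Logical (or 0/1) indicator of brand initiation.
#' @param marginal Marginal prevalence of brand initiation.
#' @return Numeric weights.
#' @examples
#' stabilized_weight(0.8, TRUE, 0.4)  # 0.5
#' stabilized_weight(0.8, FALSE, 0.4) # 3.0
#' @export
stabilized_weight <- function(score, treated, marginal) {
  if (any(score <= 0 | score >= 1)) {
    stop("propensity scores must lie strictly in (0, 1)", call. = FALSE)
  }
  treated <- as.logical(treated)
  ifelse(treated, marginal / score, (1 - marginal) / (1 - score))
}

#' Standardized difference between treatment groups
#'
#' Continuous: `(m1 - m0) / sqrt((s1^2 + s0^2) / 2)`; binary:
#' `(p1 - p0) / sqrt((p1 (1 - p1) + p0 (1 - p0)) / 2)`. Weighted variants
#' use weighted means and variances. Zero pooled variance with unequal
#' means is reported as `Inf` (flagged downstream); with equal means as 0.
#'
#' @param x Covariate vector (numeric or logical; factors are expanded by
#'   [balance_table()]).
#' @param treated Logical indicator of the brand group.
#' @param weights Optional nonnegative weights (default: unweighted).
#' @param binary Treat `x` as binary (proportion scale)? Default guesses
#'   from the values.
#' @return The standardized difference (signed).
#' @export
standardized_difference <- function(x, treated, weights = NULL,
                                    binary = NULL) {
  treated <- as.logical(treated)
  if (is.logical(x)) x <- as.numeric(x)
  if (is.null(weights)) weights <- rep(1, length(x))
  if (is.null(binary)) binary <- all(x %in% c(0, 1))
  wmean <- function(v, w) sum(w * v) / sum(w)
  wvar <- function(v, w) {
    m <- wmean(v, w)
    sum(w * (v - m)^2) / (sum(w) - 1)
  }
  m1 <- wmean(x[treated], weights[treated])
  m0 <- wmean(x[!treated], weights[!treated])
  pooled <- if (binary) {
    (m1 * (1 - m1) + m0 * (1 - m0)) / 2
  } else {
    (wvar(x[treated], weights[treated]) + wvar(x[!treated], weights[!treated])) / 2
  }
  if (pooled <= 0) {
    return(if (isTRUE(all.equal(m1, m0))) 0 else Inf)
  }
  (m1 - m0) / sqrt(pooled)
}

#' Covariate balance before and after weighting
#'
#' One row per covariate (one per level for categorical covariates) with
#' the unweighted and weighted standardized differences and the
#' conventional `|d| <= 0.10` negligible-imbalance flag. Continuous age is
#' reported both as a continuous difference and by decade class.
#'
#' @param data Cohort rows used in the propensity model.
#' @param weights Stabilized weights aligned with `data`.
#' @param covariates Character vector of covariate columns; defaults to the
#'   propensity model set.
#' @return A data.frame of class `balance_report`.
#' @export
balance_table <- function(data, weights,
                          covariates = c("age", "sex", "cmu", "polypharmacy",
                                         "charlson", "fracture_history",
                                         "year", "frequency", "specialty")) {
  data <- as.data.frame(data)
  treated <- data$group == "brand"
  rows <- list()
  add <- function(name, x, binary) {
    rows[[length(rows) + 1L]] <<- data.frame(
      covariate = name,
      d_unweighted = standardized_difference(x, treated, binary = binary),
      d_weighted = standardized_difference(x, treated, weights, binary = binary)
    )
  }
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      add(cv, x, binary = FALSE)
      if (cv == "age") {
        br <- cut(x, c(-Inf, 59, 69, 79, Inf),
                  labels = c("50-59", "60-69", "70-79", ">=80"))
        for (lv in levels(br)) add(paste0("age:", lv), br == lv, binary = TRUE)
      }
    } else if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))) {
      add(cv, as.numeric(x), binary = TRUE)
    } else {
      x <- as.factor(x)
      for (lv in levels(x)) add(paste0(cv, ":", lv), x == lv, binary = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  out$negligible <- abs(out$d_weighted) <= 0.10
  class(out) <- c("balance_report", "data.frame")
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Covariate balance (standardized differences)\n")
  y <- x
  y$d_unweighted <- round(y$d_unweighted, 3)
  y$d_weighted <- round(y$d_weighted, 3)
  print.data.frame(y, row.names = FALSE)
  cat("max |d| pre:", round(max(abs(x$d_unweighted)), 3),
      " post:", round(max(abs(x$d_weighted)), 3), "\n")
  invisible(x)
}

#' Estimate stabilized IPTW weights for a cohort
#'
#' Convenience wrapper: fits the propensity model, forms stabilized
#' weights with the empirical brand share as the marginal prevalence, and
#' assembles the balance report.
#'
#' @param cohort Analysis cohort table.
#' @param spec A [propensity_spec()].
#' @return A list of class `weighted_cohort`: `data` (rows used, with
#'   `pscore` and `sw`), `balance`, `marginal`, `n_excluded_missing`.
#' @export
estimate_weights <- function(cohort, spec = propensity_spec()) {
  pf <- fit_propensity(cohort, spec)
  dat <- pf$data
  dat$sw <- stabilized_weight(dat$pscore, dat$brand == 1L, pf$marginal)
  bal <- balance_table(dat, dat$sw)
  structure(list(data = dat, balance = bal, marginal = pf$marginal,
                 n_excluded_missing = pf$n_excluded_missing,
                 propensity_fit = pf$fit),
            class = "weighted_cohort")
}

#' @export
print.weighted_cohort <- function(x, ...) {
  cat("Weighted cohort:", nrow(x$data), "patients (",
      x$n_excluded_missing, "excluded for missing specialty )\n")
  cat("marginal brand share:", round(x$marginal, 3),
      "; mean stabilized weight:", round(mean(x$data$sw), 3), "\n")
  cat("max post-weighting |d|:",
      round(max(abs(x$balance$d_weighted)), 3), "\n")
  invisible(x)
}
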