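#' Build survival records for the discontinuation analysis
#'
#' One record per analysis patient: time in (0, 365], event status
#' (censored / discontinued / died) and the brand indicator, joined with
#' the stabilized weight.
#'
#' @param episodes A `treatment_episodes` table.
#' @param weighted A `weighted_cohort` from [estimate_weights()] (or a
#'   data.frame with `patient_id` and `sw`).
#' @return A data.frame with `patient_id`, `time`, `event` (factor with
#'   levels censored, discontinued, died), `brand`, `sw`.
#' @export
survival_records <- function(episodes, weighted) {
  ep <- as.data.frame(episodes)
  w <- if (inherits(weighted, "weighted_cohort")) weighted$data else
    as.data.frame(weighted)
  rec <- merge(ep[, c("patient_id", "group", "status", "censor_day")],
               w[, c("patient_id", "sw")], by = "patient_id")
  rec$time <- as.numeric(rec$censor_day)
  if (any(rec$time <= 0)) stop("nonpositive follow-up time", call. = FALSE)
  rec$event <- factor(ifelse(rec$status == "discontinued", "discontinued",
                             ifelse(rec$status == "died", "died", "censored")),
                      levels = c("censored", "discontinued", "died"))
  rec$brand <- as.integer(rec$group == "brand")
  rec[, c("patient_id", "time", "event", "brand", "sw")]
}

new_effect_estimate <- function(measure, est, se, n_used, n_events,
                                n_excluded = 0L, fit = NULL) {
  z <- stats::qnorm(0.975)
  structure(list(measure = measure, estimate = est,
                 robust_se = se,
                 conf_low = exp(log(est) - z * se),
                 conf_high = exp(log(est) + z * se),
                 n_used = n_used, n_events = n_events,
                 n_excluded = n_excluded, fit = fit),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s (brand vs generic) = %.3f [%.3f; %.3f]  (robust SE of log %s = %.4f, n = %d)\n",
              x$measure, x$estimate, x$conf_low, x$conf_high, x$measure,
              x$robust_se, x$n_used))
  invisible(x)
}

#' Weighted Fine-Gray model for discontinuation with death competing
#'
#' Estimates the subdistribution hazard ratio of treatment discontinuation
#' (brand vs generic, generic = reference) over the first year, accounting
#' for the competing risk of death. The subdistribution risk sets are built
#' by the Fine-Gray expansion (patients with a prior competing event remain
#' in later risk sets with time-decaying censoring weights from an
#' unweighted Kaplan-Meier of the censoring distribution); the stabilized
#' IPTW weight multiplies each patient's risk-set contribution. Ties use
#' the Breslow approximation and the variance is a robust sandwich
#' clustered on patient, treating the weights as fixed.
#'
#' @param records Output of [survival_records()].
#' @return An `effect_estimate` (measure `"HR"`).
#' @export
fit_fine_gray <- function(records) {
  if (sum(records$event == "discontinued") == 0L) {
    stop("no discontinuation events: subdistribution hazard is not estimable",
         call. = FALSE)
  }
  if (any(records$sw <= 0)) stop("weights must be positive", call. = FALSE)
  records$.id <- seq_len(nrow(records))
  fg <- survival::finegray(survival::Surv(time, event) ~ brand + sw + .id,
                           data = records, etype = "discontinued")
  fit <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ brand,
    data = fg, weights = fg$fgwt * fg$sw, id = fg$.id,
    ties = "breslow", robust = TRUE)
  if (is.na(stats::coef(fit)["brand"])) {
    stop("Fine-Gray model did not converge", call. = FALSE)
  }
  se <- sqrt(diag(fit$var))[1]
  new_effect_estimate("HR", unname(exp(stats::coef(fit)["brand"])), se,
                      n_used = nrow(records),
                      n_events = sum(records$event == "discontinued"),
                      fit = fit)
}

#' Weighted log-binomial model for good implementation
#'
#' Binomial regression with a log link of the good-implementation indicator
#' (CMA7 at or above the threshold) on the brand indicator, with stabilized
#' IPTW weights; the exponentiated coefficient is the risk ratio of good
#' implementation, brand vs generic. Variance is the HC0 sandwich treating
#' weights as fixed. Fitting uses the quasi-likelihood form of the binomial
#' log-link family (identical point estimates, tolerant of non-integer
#' weighted responses).
#'
#' @param data Data frame with logical/0-1 `good`, `brand` indicator and
#'   weights `sw` (eligible patients only).
#' @return An `effect_estimate` (measure `"RR"`).
#' @export
fit_log_binomial <- function(data) {
  data <- as.data.frame(data)
  data$good <- as.numeric(data$good)
  if (length(unique(data$good)) < 2L) {
    stop("degenerate outcome: good-implementation indicator is constant",
         call. = FALSE)
  }
  p0 <- stats::weighted.mean(data$good, data$sw)
  fit <- stats::glm(good ~ brand, data = data,
                    family = stats::quasibinomial(link = "log"),
                    weights = sw, start = c(log(p0), 0))
  if (!fit$converged) {
    stop("log-binomial model did not converge", call. = FALSE)
  }
  if (any(stats::fitted(fit) >= 1)) {
    stop("log-binomial fit reached a fitted probability >= 1", call. = FALSE)
  }
  vc <- sandwich::vcovHC(fit, type = "HC0")
  se <- sqrt(diag(vc))["brand"]
  new_effect_estimate("RR", unname(exp(stats::coef(fit)["brand"])),
                      unname(se),
                      n_used = nrow(data),
                      n_events = sum(data$good == 1),
                      fit = fit)
}

#' Fit the discontinuation model from pipeline pieces
#'
#' Thin wrapper assembling [survival_records()] and [fit_fine_gray()].
#'
#' @inheritParams survival_records
#' @return An `effect_estimate` (measure `"HR"`).
#' @export
fit_discontinuation_model <- function(episodes, weighted) {
  fit_fine_gray(survival_records(episodes, weighted))
}

#' Fit the implementation model from pipeline pieces
#'
#' Restricts to implementation-eligible patients (persistence of at least
#' six months), joins stabilized weights, and fits the weighted
#' log-binomial risk-ratio model.
#'
#' @inheritParams survival_records
#' @return An `effect_estimate` (measure `"RR"`).
#' @export
fit_implementation_model <- function(episodes, weighted) {
  ep <- as.data.frame(episodes)
  ep <- ep[ep$eligible & !is.na(ep$cma7), ]
  w <- if (inherits(weighted, "weighted_cohort")) weighted$data else
    as.data.frame(weighted)
  dat <- merge(ep[, c("patient_id", "group", "good")],
               w[, c("patient_id", "sw")], by = "patient_id")
  dat$brand <- as.integer(dat$group == "brand")
  fit_log_binomial(dat)
}

#' Persistence curve (diagnostic)
#'
#' Step function of the proportion of patients still on first-line
#' treatment at each day of follow-up: a patient contributes to the
#' at-treatment proportion through `end_day` (discontinuation, death, or
#' administrative censoring).
#'
#' @param episodes A `treatment_episodes` table.
#' @param by_group Split by treatment group?
#' @return A data.frame with `day` (0..follow-up) and `persistent`
#'   proportion (per group when `by_group`).
#' @export
persistence_curve <- function(episodes, by_group = TRUE) {
  ep <- as.data.table(episodes)
  fu <- attr(episodes, "followup_days") %||% 365L
  days <- 0:fu
  one <- function(end_day, status) {
    # discontinued/died exit at end_day; persistent patients never exit
    exits <- end_day[status != "persistent"]
    vapply(days, function(t) 1 - sum(exits <= t) / length(end_day), numeric(1))
  }
  if (by_group) {
    out <- ep[, .(day = days, persistent = one(end_day, status)), by = group]
  } else {
    out <- data.table(day = days,
                      persistent = one(ep$end_day, ep$status))
  }
  as.data.frame(out)
}
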