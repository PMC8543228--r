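# Per-study compositional Cox regression.
#
# The linear predictor is gamma' z + beta' v, where z are the ilr balance
# coordinates of each subject's daily composition and v any further
# covariates.  Fitting is ordinary partial-likelihood maximisation
# (Efron tie handling); what is compositional is the construction and
# interpretation of the predictors, not the estimator.

#' Landmark exclusion of early deaths
#'
#' Removes subjects who died within the first `cutoff` years of follow-up
#' to limit reverse-causation bias (illness causing both inactivity and
#' early death).  Subjects censored before the cutoff are retained unless
#' `drop_all_early = TRUE`.  Follow-up clocks are not reset.
#'
#' @param x A [cohort()].
#' @param cutoff Landmark in years (default 2).
#' @param drop_all_early If `TRUE`, drop every subject with follow-up
#'   shorter than the cutoff, censored or not.
#' @return The filtered `cohort`; the number of removed subjects is
#'   reported via `message()`.
#' @export
landmark_filter <- function(x, cutoff = 2, drop_all_early = FALSE) {
  stopifnot(inherits(x, "cohort"), cutoff >= 0)
  d <- x$data
  drop <- if (drop_all_early) d$followup < cutoff
          else d$event == 1 & d$followup < cutoff
  if (sum(d$event[!drop]) == 0)
    stop("landmark cutoff removes every event in study '", x$study, "'")
  if (any(drop))
    message(sum(drop), " subject(s) removed by ", cutoff,
            "-year landmark in '", x$study, "'")
  x$data <- d[!drop, , drop = FALSE]
  x
}

#' Fit the compositional Cox model for one study
#'
#' Transforms each subject's composition to ilr coordinates and fits a
#' Cox proportional-hazards model with those coordinates plus the
#' cohort's covariates as predictors.  Ties use the Efron approximation;
#' Newton iterations stop at a relative partial-log-likelihood change of
#' 1e-9 (at most 100 iterations).
#'
#' @param x A [cohort()] with strictly positive compositions (impute
#'   zeros first).
#' @param covariates Character vector of covariate columns to adjust for;
#'   defaults to all non-core columns of the cohort.
#' @return A `study_fit`: ilr coefficients `gamma` with covariance
#'   `vcov_gamma`, covariate coefficients `beta`, sample sizes, study
#'   metadata, and the underlying `coxph` object in `$fit`.
#' @export
fit_compositional_cox <- function(x, covariates = x$covariates) {
  stopifnot(inherits(x, "cohort"))
  if (sum(x$data$event) < 2)
    stop("at least 2 events are required to fit study '", x$study, "'")
  comp <- compositions(x)
  if (any(comp <= 0))
    stop("compositions contain zeros; run impute_zeros() first")
  z <- ilr_forward(comp)
  df <- cbind(as.data.frame(z),
              x$data[c("followup", "event", covariates)])
  fml <- stats::as.formula(paste(
    "survival::Surv(followup, event) ~",
    paste(c(colnames(z), covariates), collapse = " + ")))
  fit <- survival::coxph(
    fml, data = df, ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100),
    x = TRUE)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    warning("degenerate predictors (no variation or collinearity) in: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (any(abs(cf) > 15, na.rm = TRUE))
    warning("possible monotone likelihood / separation; flagged: ",
            paste(names(cf)[abs(cf) > 15 & !is.na(cf)], collapse = ", "))
  zc <- intersect(colnames(z), names(cf))
  V <- stats::vcov(fit)
  structure(
    list(study = x$study, device = x$device,
         measures_sleep = x$measures_sleep,
         n = nrow(x$data), n_events = sum(x$data$event),
         gamma = cf[zc], beta = cf[setdiff(names(cf), zc)],
         vcov_gamma = V[zc, zc, drop = FALSE],
         vcov = V, fit = fit),
    class = "study_fit")
}

#' @export
print.study_fit <- function(x, ...) {
  cat(sprintf("<study_fit '%s': n=%d, events=%d, %s, sleep %smeasured>\n",
              x$study, x$n, x$n_events, x$device,
              if (x$measures_sleep) "" else "not "))
  print(round(c(x$gamma, x$beta), 4))
  invisible(x)
}

#' Predicted survival probability
#'
#' Evaluates S(t) = exp(-H0(t) exp(gamma' z + beta' v)) using the
#' Breslow-type baseline cumulative hazard of the fitted study.
#'
#' @param fit A `study_fit` from [fit_compositional_cox()].
#' @param z Named ilr coordinates of the subject's composition.
#' @param v Named covariate values (on the scale used at fit time);
#'   centred at zero when omitted.
#' @param t Time(s) in years, `t >= 0`.
#' @return Survival probabilities, one per element of `t`.
#' @export
predict_survival <- function(fit, z, v = NULL, t) {
  stopifnot(inherits(fit, "study_fit"), all(t >= 0))
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  if (any(t > max(bh$time)))
    warning("t beyond observed follow-up; extrapolating the last ",
            "baseline hazard value")
  H0 <- stats::approx(c(0, bh$time), c(0, bh$hazard), xout = t,
                      method = "constant", rule = 2, f = 0)$y
  lp <- sum(fit$gamma * z[names(fit$gamma)]) +
    if (length(fit$beta) && !is.null(v))
      sum(fit$beta * v[names(fit$beta)]) else 0
  exp(-H0 * exp(lp))
}

#' Proportional-hazards diagnostics
#'
#' Score tests on scaled Schoenfeld residuals, per coefficient and
#' globally, for the proportional-hazards assumption of a fitted study.
#'
#' @param fit A `study_fit`.
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return Data frame with columns `term`, `chisq`, `df`, `p`; the last
#'   row is the global test.
#' @export
test_proportional_hazards <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "study_fit"))
  if (fit$n_events < 2) stop("PH test undefined with fewer than 2 events")
  zp <- survival::cox.zph(fit$fit, transform = transform)
  tab <- as.data.frame(zp$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}

#' Kaplan-Meier summary by risk-score tertile
#'
#' Companion to the formal PH test: survival-curve inspection across
#' low/medium/high linear-predictor groups.
#'
#' @param fit A `study_fit`.
#' @param x The cohort the fit came from.
#' @return A `survfit` object (plot or summarise it as usual).
#' @export
km_by_risk_group <- function(fit, x) {
  stopifnot(inherits(fit, "study_fit"), inherits(x, "cohort"))
  lp <- fit$fit$linear.predictors
  grp <- cut(lp, stats::quantile(lp, c(0, 1 / 3, 2 / 3, 1)),
             include.lowest = TRUE, labels = c("low", "mid", "high"))
  survival::survfit(survival::Surv(x$data$followup, x$data$event) ~ grp)
}

# ---- federation exchange files ---------------------------------------

#' Write a study fit as a federation exchange file
#'
#' Serialises only what the pooling stage needs -- coefficients, their
#' covariance, sample sizes and metadata -- never subject-level data.
#' Numbers are written at full precision so a write/read round trip is
#' value-exact.
#'
#' @param fit A `study_fit` (or a masked fit from
#'   [mask_missing_sleep()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_study_fit <- function(fit, path) {
  stopifnot(inherits(fit, "study_fit"))
  obj <- list(
    study = fit$study, device = fit$device,
    measures_sleep = fit$measures_sleep,
    n = fit$n, n_events = fit$n_events,
    gamma = as.list(.num_out(fit$gamma)),
    beta = as.list(.num_out(fit$beta)),
    gamma_names = names(fit$gamma),
    vcov_gamma = .num_out(as.vector(t(fit$vcov_gamma))),
    software_version = as.character(utils::packageVersion("codasurv")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a federation exchange file
#' @param path JSON path written by [write_study_fit()].
#' @return A `study_fit` (without the subject-level `$fit` component).
#' @export
read_study_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(o$gamma_names)
  V <- matrix(.num_in(o$vcov_gamma), p, p, byrow = TRUE,
              dimnames = list(o$gamma_names, o$gamma_names))
  structure(
    list(study = o$study, device = o$device,
         measures_sleep = o$measures_sleep, n = o$n,
         n_events = o$n_events,
         gamma = .num_in(unlist(o$gamma))[o$gamma_names],
         beta = if (length(o$beta)) .num_in(unlist(o$beta))
                else numeric(0),
         vcov_gamma = V, vcov = NULL, fit = NULL),
    class = "study_fit")
}

# coefficients travel as decimal strings with 17 significant digits so a
# write/read round trip is value-exact
.num_out <- function(x) {
  out <- sprintf("%.17g", x)
  names(out) <- names(x)
  out
}

.num_in <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}
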