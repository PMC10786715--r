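#' Encode EHR records as delayed-entry counting-process rows
#'
#' Maps raw per-subject records (entry age, diagnosis or censoring age,
#' event flag, problem-list flag) to `(start, stop, event]` rows:
#'
#' * normal event (`diagnosis >= entry + instant_window`):
#'   `(entry, diagnosis, 1)`;
#' * instant event (diagnosis within `instant_window` years of entry): the
#'   onset is assumed to predate the first visit, encoded `(0, entry, 1)`;
#' * problem-list event with no date: `(0, entry, 1)`;
#' * censored: `(entry, censor_age, 0)`.
#'
#' Rows whose stop does not exceed their start are dropped and reported;
#' every input subject appears exactly once in the output or the drop
#' report. Negative ages are an error.
#'
#' @param records data.frame with columns donor, entry_age, event_age,
#'   event (0/1), problem_list (logical; optional).
#' @param instant_window years (default 1).
#' @return list: `records` (donor, start, stop, event, reason), `dropped`
#'   (donor, why).
#' @export
encode_survival <- function(records, instant_window = 1) {
  req <- c("donor", "entry_age", "event_age", "event")
  stopifnot(all(req %in% names(records)))
  if (!"problem_list" %in% names(records)) records$problem_list <- FALSE
  ages <- c(records$entry_age, records$event_age)
  if (any(ages < 0, na.rm = TRUE)) stop_config("encode_survival: negative ages")

  n <- nrow(records)
  start <- stop_ <- numeric(n)
  event <- integer(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    e <- records$entry_age[i]
    a <- records$event_age[i]
    if (records$event[i] == 1L && (isTRUE(records$problem_list[i]) || is.na(a))) {
      start[i] <- 0; stop_[i] <- e; event[i] <- 1L
      reason[i] <- "problem_list_interval"
    } else if (records$event[i] == 1L && a < e + instant_window) {
      start[i] <- 0; stop_[i] <- e; event[i] <- 1L
      reason[i] <- "instant_event"
    } else if (records$event[i] == 1L) {
      start[i] <- e; stop_[i] <- a; event[i] <- 1L
      reason[i] <- "normal"
    } else {
      start[i] <- e; stop_[i] <- a; event[i] <- 0L
      reason[i] <- "censored"
    }
  }
  out <- data.frame(donor = records$donor, start = start, stop = stop_,
                    event = event, reason = reason, stringsAsFactors = FALSE)
  bad <- !(out$stop > out$start) | is.na(out$stop)
  dropped <- data.frame(donor = out$donor[bad],
                        why = rep("stop <= start", sum(bad)),
                        stringsAsFactors = FALSE)
  list(records = out[!bad, , drop = FALSE], dropped = dropped)
}

#' Cox proportional-hazards model with delayed entry
#'
#' Fits the counting-process partial likelihood (risk set at t: subjects
#' with `start < t <= stop`) with Efron tie handling, via
#' [survival::coxph()]. Standard errors come from the inverse observed
#' information.
#'
#' @param records data.frame with start, stop, event.
#' @param covariates data.frame of model covariates aligned with `records`
#'   rows (e.g. sex, PC1, PC2, scaled score).
#' @return list: `table` (term, loghr, se, z, p), `fit` (the coxph object),
#'   `loglik` (null and fitted partial log-likelihood).
#' @export
cox_delayed_entry <- function(records, covariates) {
  stopifnot(all(c("start", "stop", "event") %in% names(records)))
  if (sum(records$event) < 2L)
    stop_config("cox_delayed_entry: need >= 2 events")
  d <- cbind(records[, c("start", "stop", "event")], covariates)
  fit <- survival::coxph(
    survival::Surv(start, stop, event) ~ .,
    data = d[, c("start", "stop", "event", names(covariates))],
    ties = "efron")
  conv <- if (!is.null(fit$info) && "convergence" %in% names(fit$info))
    fit$info[["convergence"]] else 0
  if (any(!is.finite(fit$coefficients)) || conv != 0)
    stop_config("cox_delayed_entry: fit did not converge")
  co <- summary(fit)$coefficients
  monotone <- any(abs(fit$coefficients) > 15)
  if (monotone)
    warning("cox_delayed_entry: monotone likelihood suspected (|loghr| > 15)")
  list(table = data.frame(term = rownames(co), loghr = co[, "coef"],
                          se = co[, "se(coef)"], z = co[, "z"],
                          p = pmax(co[, "Pr(>|z|)"], P_FLOOR),
                          row.names = NULL, stringsAsFactors = FALSE),
       fit = fit, loglik = fit$loglik)
}

#' Kaplan-Meier curves stratified by score quartiles
#'
#' Quartile cut points at the 25/50/75% score quantiles (ties assigned to
#' the lower stratum); the product-limit estimator is left-truncation aware
#' (risk set at t counts subjects with `start < t <= stop`). Identical
#' scores collapse to a single stratum with a warning.
#'
#' @param records data.frame with start, stop, event.
#' @param scores numeric vector aligned with `records` rows.
#' @return list: `fit` (a [survival::survfit()] object), `quartile` (factor
#'   per row), `cuts`.
#' @export
km_quartiles <- function(records, scores) {
  stopifnot(nrow(records) == length(scores))
  if (nrow(records) < 8L) stop_config("km_quartiles: need >= 8 subjects")
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), na.rm = TRUE)
  if (length(unique(qs)) < 3L || all(scores == scores[1])) {
    warning("km_quartiles: degenerate score distribution; fewer than 4 strata")
  }
  brk <- unique(c(-Inf, qs, Inf))
  quartile <- cut(scores, breaks = brk, labels = paste0("Q", seq_len(length(brk) - 1L)),
                  right = TRUE)
  d <- cbind(records[, c("start", "stop", "event")], quartile = quartile)
  fit <- survival::survfit(survival::Surv(start, stop, event) ~ quartile,
                           data = d)
  list(fit = fit, quartile = quartile, cuts = qs)
}

#' Chronic kidney disease stage from eGFR
#'
#' Bands (ml/min/1.73 m^2), inclusive at the lower edge: 45-59 stage 3a,
#' 30-44 stage 3b, 15-29 stage 4, below 15 stage 5; 60 and above is not
#' staged (`"none"`).
#'
#' @param egfr numeric vector, non-negative.
#' @return character vector of stage labels.
#' @export
ckd_stage_from_egfr <- function(egfr) {
  if (any(egfr < 0, na.rm = TRUE)) stop_config("eGFR must be non-negative")
  out <- rep(NA_character_, length(egfr))
  ok <- !is.na(egfr)
  out[ok] <- ifelse(egfr[ok] >= 60, "none",
             ifelse(egfr[ok] >= 45, "3a",
             ifelse(egfr[ok] >= 30, "3b",
             ifelse(egfr[ok] >= 15, "4", "5"))))
  out
}
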