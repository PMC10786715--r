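#' Simulate EHR-style outcomes with delayed entry
#'
#' For each outcome listed in `outcome_effects`, a true onset age is drawn
#' from an exponential hazard `base_hazard * exp(eta)` where `eta` is the
#' linear predictor over the referenced donor latents. Entry age (first
#' visit) is drawn independently of the latents, and administrative censoring
#' follows a bounded observation window. The emitted records mimic what an
#' EHR exposes:
#'
#' * onset after entry: the diagnosis age is recorded as-is;
#' * onset before entry: the diagnosis surfaces shortly after the first
#'   visit (so it lands inside the downstream "instant event" window);
#' * a configured fraction of observed events are exposed as undated
#'   problem-list entries (`problem_list = TRUE`, `event_age = NA`);
#' * onset after the censoring age: a censored record.
#'
#' Continuous labs (eGFR, HbA1C) are drawn around the configured means with
#' a contribution of the tone latent to induce realistic trait-lab
#' correlation.
#'
#' @param latents output of [simulate_donor_latents()].
#' @param config a [simulation_config()].
#' @return list with `records` (donor, outcome, entry_age, event_age, event,
#'   problem_list, onset_age_true) and `labs` (donor plus one column per lab).
#' @export
simulate_outcomes <- function(latents, config) {
  stopifnot(inherits(config, "sim_config"))
  oe <- config$outcome_effects
  n <- nrow(latents)
  set.seed(child_seed(config$seed, "outcomes"))
  entry <- stats::runif(n, 25, 65)
  censor <- pmin(entry + stats::runif(n, 5, 30), 90)

  records <- list()
  for (out_name in unique(oe$outcome)) {
    rows <- oe[oe$outcome == out_name, , drop = FALSE]
    eta <- rep(0, n)
    for (r in seq_len(nrow(rows))) {
      lat <- rows$latent[r]
      if (!lat %in% names(latents))
        stop_config("outcome effect references unknown latent '%s'", lat)
      if (rows$log_hr[r] != 0) eta <- eta + rows$log_hr[r] * latents[[lat]]
    }
    onset <- stats::rexp(n, rate = config$base_hazard * exp(eta))
    obs_event <- onset <= censor
    # onsets before entry surface in the EHR just after the first visit
    recorded <- ifelse(onset < entry, entry + stats::runif(n, 0, 0.5), onset)
    plist <- obs_event & (stats::runif(n) < config$problem_list_rate)
    records[[out_name]] <- data.frame(
      donor = latents$donor,
      outcome = out_name,
      entry_age = entry,
      event_age = ifelse(obs_event, ifelse(plist, NA_real_, recorded), censor),
      event = as.integer(obs_event),
      problem_list = plist,
      onset_age_true = onset,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  labs <- data.frame(donor = latents$donor, stringsAsFactors = FALSE)
  for (lab in names(config$lab_means)) {
    scale <- if (lab == "eGFR") c(sd = 15, tone = -4) else c(sd = 0.6, tone = 0.15)
    labs[[lab]] <- config$lab_means[[lab]] +
      scale["tone"] * latents$tone + stats::rnorm(n, 0, scale["sd"])
  }
  list(records = records, labs = labs)
}
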