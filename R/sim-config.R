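#' Default gate-anchored mixture templates
#'
#' One row per (channel, gate) component of the event-cloud mixture used by
#' the generator. Means and diagonal spreads are in instrument units on the
#' three optical axes (FSC, SSC, SFL); `weight` is the baseline mixture weight
#' of the component within its channel. Components are placed so that any two
#' gates in the same channel are separated by at least eight spreads on at
#' least one axis, which lets axis-aligned box gates recover mixture
#' proportions with negligible misclassification.
#'
#' The gate set mirrors the naming used on hematology-analyzer channels
#' (WDF white-cell differential, WNR white count and nucleated RBC, RET
#' reticulocyte, PLTF fluorescent platelet): neutrophil subpopulations
#' NE1-NE4 (NE2 being the perturbation-evoked high-SSC/high-SFL
#' subpopulation), monocytes, lymphocytes, eosinophils, basophils, mature and
#' reticulated red cells, platelets and immature platelet fraction, plus
#' debris/ghost components.
#'
#' @return data.frame with columns gate, channel, fsc, ssc, sfl, s_fsc,
#'   s_ssc, s_sfl, weight.
#' @export
default_gate_templates <- function() {
  tpl <- rbind(
    # channel, gate, fsc, ssc, sfl, weight
    data.frame(channel = "WDF", gate = c("NE1", "NE2", "NE3", "NE4", "MO", "MO2",
                                         "LY", "EO1", "EO2", "DEBRIS"),
               fsc = c(60000, 60000, 90000, 60000, 100000, 120000, 40000, 70000, 90000, 10000),
               ssc = c(60000, 90000, 60000, 60000, 40000, 40000, 30000, 120000, 140000, 10000),
               sfl = c(40000, 90000, 60000, 60000, 100000, 120000, 80000, 60000, 90000, 10000),
               weight = c(0.18, 0.02, 0.10, 0.25, 0.08, 0.02, 0.22, 0.03, 0.02, 0.08)),
    data.frame(channel = "WNR", gate = c("WBC", "WBC1", "WBC2", "BASO", "UK1", "NRBC", "GHOST"),
               fsc = c(80000, 50000, 110000, 80000, 30000, 30000, 10000),
               ssc = c(50000, 50000, 50000, 90000, 80000, 20000, 10000),
               sfl = c(70000, 50000, 90000, 110000, 30000, 90000, 40000),
               weight = c(0.35, 0.18, 0.10, 0.04, 0.05, 0.03, 0.25)),
    data.frame(channel = "RET", gate = c("RBC1", "RBC2", "RET1", "RET2", "GHOST"),
               fsc = c(90000, 120000, 90000, 90000, 20000),
               ssc = c(30000, 30000, 30000, 30000, 10000),
               sfl = c(15000, 15000, 60000, 100000, 35000),
               weight = c(0.50, 0.25, 0.12, 0.05, 0.08)),
    data.frame(channel = "PLTF", gate = c("PLT", "IPF", "DEBRIS"),
               fsc = c(30000, 50000, 8000),
               ssc = c(20000, 30000, 8000),
               sfl = c(50000, 90000, 8000),
               weight = c(0.70, 0.10, 0.20))
  )
  tpl$s_fsc <- 1500
  tpl$s_ssc <- 1500
  tpl$s_sfl <- 1500
  tpl[, c("gate", "channel", "fsc", "ssc", "sfl", "s_fsc", "s_ssc", "s_sfl", "weight")]
}

default_condition_effects <- function(conditions) {
  non_base <- setdiff(conditions, "baseline")
  if (!length(non_base)) return(data.frame(condition = character(), channel = character(),
                                           gate = character(), logfc = numeric()))
  do.call(rbind, lapply(non_base, function(cc) data.frame(
    condition = cc,
    channel = c("WDF", "PLTF", "WNR"),
    gate = c("NE2", "IPF", "BASO"),
    logfc = c(1.0, 0.5, 0.3)
  )))
}

default_causal_effects <- function(n_variants) {
  idx <- unique(pmin(n_variants, c(10L, max(1L, round(n_variants * 0.2)), max(1L, round(n_variants * 0.6)))))
  data.frame(
    variant = idx,
    condition = "*",
    gate = c("NE2", "RET1", "PLT")[seq_along(idx)],
    effect = c(1.5, 1.2, 1.2)[seq_along(idx)]
  )
}

default_outcome_effects <- function() {
  data.frame(
    latent = c("tone", "NE2", "tone", "tone"),
    outcome = c("T2D", "T2D", "CKD", "CTRL"),
    log_hr = c(0.3, 0.3, 0.3, 0)
  )
}

#' Build and validate a simulation configuration
#'
#' Bundles every parameter of the synthetic cohort generator: genotypes with
#' AR(1) LD blocks under Hardy-Weinberg equilibrium, gate-anchored cytometry
#' event mixtures per perturbation condition, donor latent traits (including
#' an "inflammatory tone" latent that couples disease risk to gate weights),
#' and EHR-style delayed-entry outcomes.
#'
#' @param n_donors,n_variants cohort and panel size.
#' @param ld_block_size variants per LD block.
#' @param ld_rho AR(1) correlation of adjacent latent variant liabilities,
#'   in `[0, 1)`.
#' @param maf_range interval strictly inside `(0, 0.5]` from which per-variant
#'   minor allele frequencies are drawn uniformly.
#' @param conditions character vector of condition identifiers; "baseline"
#'   receives no condition effect.
#' @param gate_templates data.frame as [default_gate_templates()].
#' @param condition_effects data.frame (condition, channel, gate, logfc):
#'   log-fold changes applied to baseline mixture weights per condition.
#' @param causal_effects data.frame (variant, condition, gate, effect):
#'   per-allele shifts of the named gate's donor latent, in latent s.d. units
#'   (`condition = "*"` applies under every condition).
#' @param outcome_effects data.frame (latent, outcome, log_hr) linking donor
#'   latent traits to outcome hazards.
#' @param events_per_sample events per donor x condition x channel.
#' @param latent_scale multiplier from donor latent to log mixture weight.
#' @param tone_loadings named numeric: per-gate loading of the inflammatory
#'   tone latent on the gate's donor latent.
#' @param missing_rate genotype missingness rate in `[0, 1)`.
#' @param instrument_max exclusive upper bound of the optical range
#'   (default `2^18`, an 18-bit scale).
#' @param base_hazard per-year baseline hazard of each simulated outcome.
#' @param problem_list_rate fraction of observed events exposed as undated
#'   problem-list entries.
#' @param lab_means named numeric means for continuous labs.
#' @param seed integer global seed; all child streams derive from it.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_donors = 200L,
                              n_variants = 500L,
                              ld_block_size = 10L,
                              ld_rho = 0.4,
                              maf_range = c(0.1, 0.5),
                              conditions = c("baseline", "Pam3CSK4_19h", "LPS_18h"),
                              gate_templates = default_gate_templates(),
                              condition_effects = default_condition_effects(conditions),
                              causal_effects = default_causal_effects(n_variants),
                              outcome_effects = default_outcome_effects(),
                              events_per_sample = 1000L,
                              latent_scale = 0.35,
                              tone_loadings = c(NE2 = 0.4, WBC = 0.3, PLT = 0.3),
                              missing_rate = 0,
                              instrument_max = 2^18,
                              base_hazard = 0.004,
                              problem_list_rate = 0.1,
                              lab_means = c(eGFR = 75, HbA1C = 5.6),
                              seed = 1L) {
  if (n_donors < 2L || n_variants < 1L)
    stop_config("need n_donors >= 2 and n_variants >= 1")
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop_config("ld_rho must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must be an interval inside (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must lie in [0, 1)")
  if (events_per_sample < 1L) stop_config("events_per_sample must be positive")
  stopifnot(all(c("gate", "channel", "fsc", "ssc", "sfl",
                  "s_fsc", "s_ssc", "s_sfl", "weight") %in% names(gate_templates)))
  if (any(gate_templates[, c("s_fsc", "s_ssc", "s_sfl")] <= 0))
    stop_config("gate template spreads must be strictly positive")
  if (anyDuplicated(gate_templates[, c("channel", "gate")]))
    stop_config("gate names must be unique within a channel")
  wsum <- tapply(gate_templates$weight, gate_templates$channel, sum)
  if (any(abs(wsum - 1) > 1e-9))
    stop_config("baseline mixture weights must sum to 1 per channel (got %s)",
                paste(sprintf("%s=%.6f", names(wsum), wsum), collapse = ", "))
  if (nrow(outcome_effects) && any(!is.finite(outcome_effects$log_hr)))
    stop_config("outcome log hazard ratios must be finite")
  if (nrow(causal_effects) &&
      (any(causal_effects$variant < 1L) || any(causal_effects$variant > n_variants)))
    stop_config("causal_effects reference variants outside 1..n_variants")

  structure(list(
    n_donors = as.integer(n_donors), n_variants = as.integer(n_variants),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    maf_range = maf_range, conditions = conditions,
    gate_templates = gate_templates, condition_effects = condition_effects,
    causal_effects = causal_effects, outcome_effects = outcome_effects,
    events_per_sample = as.integer(events_per_sample),
    latent_scale = latent_scale, tone_loadings = tone_loadings,
    missing_rate = missing_rate, instrument_max = instrument_max,
    base_hazard = base_hazard, problem_list_rate = problem_list_rate,
    lab_means = lab_means, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d donors, %d variants (LD blocks of %d, rho=%.2f), %d conditions, %d gates, %d events/sample, seed %d\n",
              x$n_donors, x$n_variants, x$ld_block_size, x$ld_rho,
              length(x$conditions), nrow(x$gate_templates),
              x$events_per_sample, x$seed))
  invisible(x)
}
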