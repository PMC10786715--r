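#' Simulate donor latent traits
#'
#' Every donor receives an "inflammatory tone" latent (standard normal) plus
#' one latent per gate targeted by a causal effect or a tone loading. A gate
#' latent is `sum(effect * dosage) + loading * tone + N(0,1)` with missing
#' dosages replaced by twice the target allele frequency; condition-specific
#' causal effects produce latents keyed `"<gate>@<condition>"`.
#'
#' @param config a [simulation_config()].
#' @param geno the matching `genotype_matrix`.
#' @return data.frame with a `donor` column, `tone`, and one column per
#'   latent gate trait.
#' @export
simulate_donor_latents <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_donors
  set.seed(child_seed(config$seed, "latents"))
  tone <- stats::rnorm(n)

  ce <- config$causal_effects
  keys <- character(0)
  if (nrow(ce)) {
    keys <- ifelse(ce$condition == "*", ce$gate, paste0(ce$gate, "@", ce$condition))
  }
  keys <- union(keys, names(config$tone_loadings))
  out <- data.frame(donor = geno$donors, tone = tone, stringsAsFactors = FALSE)
  for (key in keys) {
    gate <- sub("@.*$", "", key)
    z <- stats::rnorm(n)
    if (nrow(ce)) {
      rows <- which(ifelse(ce$condition == "*", ce$gate, paste0(ce$gate, "@", ce$condition)) == key)
      for (r in rows) {
        d <- geno$dosage[, ce$variant[r]]
        d[is.na(d)] <- 2 * geno$variants$maf_target[ce$variant[r]]
        z <- z + ce$effect[r] * d
      }
    }
    loading <- config$tone_loadings[gate]
    if (!is.na(loading)) z <- z + loading * tone
    out[[key]] <- z
  }
  out
}

#' Per-donor mixture weights for one condition
#'
#' Applies, in order: the condition's log-fold changes to the template
#' baseline weights, then the donor's latent modulation
#' `exp(latent_scale * z)` for gates with a latent, then renormalisation
#' within each channel.
#'
#' @param config a [simulation_config()].
#' @param latents output of [simulate_donor_latents()].
#' @param donor donor id or index.
#' @param condition condition identifier.
#' @return `donor_state`: list with `donor`, `condition`, and `weights`, a
#'   named list channel -> named weight vector (summing to 1).
#' @export
donor_state <- function(config, latents, donor, condition) {
  if (is.numeric(donor)) donor <- latents$donor[donor]
  i <- match(donor, latents$donor)
  if (is.na(i)) stop_config("unknown donor '%s'", donor)
  tpl <- config$gate_templates
  w <- tpl$weight
  ce <- config$condition_effects
  if (NROW(ce)) {
    hit <- match(paste(condition, tpl$channel, tpl$gate),
                 paste(ce$condition, ce$channel, ce$gate))
    lfc <- ifelse(is.na(hit), 0, ce$logfc[hit])
    w <- w * exp(lfc)
  }
  for (j in seq_len(nrow(tpl))) {
    key_cond <- paste0(tpl$gate[j], "@", condition)
    key <- if (key_cond %in% names(latents)) key_cond
           else if (tpl$gate[j] %in% names(latents)) tpl$gate[j] else NA
    if (!is.na(key)) w[j] <- w[j] * exp(config$latent_scale * latents[[key]][i])
  }
  weights <- split(stats::setNames(w, tpl$gate), tpl$channel)
  weights <- lapply(weights, function(wc) wc / sum(wc))
  list(donor = donor, condition = condition, weights = weights)
}

new_event_table <- function(donor, condition, channel, events) {
  events <- as.matrix(events)
  if (ncol(events) != 3L) stop_config("event table needs 3 columns (FSC, SSC, SFL)")
  colnames(events) <- c("FSC", "SSC", "SFL")
  if (nrow(events) && (any(!is.finite(events)) || any(events < 0)))
    stop_config("event values must be finite and non-negative")
  structure(list(donor = donor, condition = condition, channel = channel,
                 events = events),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %s / %s / %s, %d events\n",
              x$donor, x$condition, x$channel, nrow(x$events)))
  invisible(x)
}

#' Simulate cytometry events for one donor under one condition
#'
#' Draws `events_per_sample` events per channel from the gate-anchored
#' Gaussian mixture defined by the donor state's weights and the template
#' component means/spreads, then clips every optical value to the instrument
#' range `[0, instrument_max)`. Negative adjusted weights are clipped to zero
#' before renormalisation; a channel whose weights are all zero is an error.
#'
#' @param state a [donor_state()] (or any list with `donor`, `condition`,
#'   `weights` in the same layout).
#' @param condition condition identifier (defaults to the state's).
#' @param config a [simulation_config()].
#' @return named list of `event_table`, one per channel.
#' @export
simulate_events <- function(state, condition = state$condition, config) {
  tpl <- config$gate_templates
  n_ev <- config$events_per_sample
  out <- list()
  for (ch in unique(tpl$channel)) {
    wc <- state$weights[[ch]]
    wc[wc < 0] <- 0
    if (sum(wc) <= 0) stop_config("all mixture weights zero for channel %s", ch)
    wc <- wc / sum(wc)
    tch <- tpl[tpl$channel == ch, ]
    tch <- tch[match(names(wc), tch$gate), ]
    set.seed(child_seed(config$seed,
                        paste("events", state$donor, condition, ch, sep = "/")))
    comp <- sample.int(length(wc), n_ev, replace = TRUE, prob = wc)
    mu <- as.matrix(tch[, c("fsc", "ssc", "sfl")])[comp, , drop = FALSE]
    sd <- as.matrix(tch[, c("s_fsc", "s_ssc", "s_sfl")])[comp, , drop = FALSE]
    ev <- mu + matrix(stats::rnorm(3 * n_ev), n_ev, 3) * sd
    ev <- pmin(pmax(ev, 0), config$instrument_max - 1e-9)
    out[[ch]] <- new_event_table(state$donor, condition, ch, ev)
  }
  out
}

#' Simulate donor covariates
#'
#' Age at draw, sex, race, draw-to-analysis time (hours), study month,
#' genotyping chip and batch, matching the covariate set adjusted for in the
#' association scan.
#'
#' @param config a [simulation_config()].
#' @return data.frame keyed by `donor`.
#' @export
simulate_covariates <- function(config) {
  n <- config$n_donors
  set.seed(child_seed(config$seed, "covariates"))
  data.frame(
    donor = sprintf("donor_%04d", seq_len(n)),
    age = round(stats::runif(n, 20, 70), 1),
    sex = sample(c(0L, 1L), n, replace = TRUE),
    race = sample(c("A", "B", "C", "D"), n, replace = TRUE,
                  prob = c(0.6, 0.2, 0.1, 0.1)),
    draw_time = round(stats::runif(n, 0.5, 36), 2),
    study_month = sample.int(24L, n, replace = TRUE),
    chip = sample(c("chip1", "chip2"), n, replace = TRUE),
    batch = sample.int(5L, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
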