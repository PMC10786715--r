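test_that("simulated genotypes match configured allele frequencies and are HWE-consistent", {
  cfg <- simulation_config(n_donors = 10000L, n_variants = 30L,
                           maf_range = c(0.3, 0.3) + c(-1e-9, 1e-9),
                           ld_rho = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% c(0, 1, 2)))
  maf <- colMeans(g$dosage) / 2
  expect_true(all(abs(maf - 0.3) < 0.02))
  # single-variant genotype frequencies follow HWE proportions
  het <- colMeans(g$dosage == 1)
  expect_true(all(abs(het - 2 * 0.3 * 0.7) < 0.03))
  expect_true(all(diff(g$variants$pos) > 0))
})

test_that("ld_rho = 0 gives uncorrelated variants; correlation increases with ld_rho", {
  cfg0 <- simulation_config(n_donors = 5000L, n_variants = 20L, ld_rho = 0,
                            seed = 4)
  g0 <- simulate_genotypes(cfg0)
  cors0 <- diag(stats::cor(g0$dosage[, -20], g0$dosage[, -1]))
  expect_true(all(abs(cors0) < 0.05))

  cfg8 <- simulation_config(n_donors = 5000L, n_variants = 20L, ld_rho = 0.8,
                            ld_block_size = 20L, seed = 4)
  g8 <- simulate_genotypes(cfg8)
  cors8 <- diag(stats::cor(g8$dosage[, -20], g8$dosage[, -1]))
  expect_gt(mean(cors8), mean(abs(cors0)) + 0.2)
})

test_that("identical seed and config reproduce identical outputs", {
  cfg <- tiny_sim_config(seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  lat <- simulate_donor_latents(cfg, g1)
  st <- donor_state(cfg, lat, 1, "baseline")
  e1 <- simulate_events(st, "baseline", cfg)
  e2 <- simulate_events(st, "baseline", cfg)
  expect_identical(e1, e2)
  o1 <- simulate_outcomes(lat, cfg)
  o2 <- simulate_outcomes(lat, cfg)
  expect_identical(o1, o2)
})

test_that("configuration validation rejects invalid parameters", {
  expect_error(simulation_config(ld_rho = 1), "ld_rho")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(n_donors = 1), "n_donors")
  tpl <- default_gate_templates()
  tpl$weight[1] <- tpl$weight[1] + 0.5
  expect_error(simulation_config(gate_templates = tpl), "sum to 1")
  oe <- default_outcome_effects()
  oe$log_hr[1] <- Inf
  expect_error(simulation_config(outcome_effects = oe), "finite")
})

test_that("a degenerate single-gate mixture concentrates all events at that component", {
  tpl <- default_gate_templates()
  tpl <- tpl[tpl$channel == "WDF", ]
  tpl$weight <- ifelse(tpl$gate == "NE2", 1, 0)
  # bypass config weight validation via explicit state weights
  cfg <- simulation_config(gate_templates = within(tpl, weight <- rep(1 / nrow(tpl), nrow(tpl))),
                           events_per_sample = 4000L, conditions = "baseline",
                           causal_effects = data.frame(), seed = 2)
  st <- list(donor = "d1", condition = "baseline",
             weights = list(WDF = stats::setNames(as.numeric(tpl$gate == "NE2"),
                                                  tpl$gate)))
  ev <- simulate_events(st, "baseline", cfg)$WDF
  mu <- tpl[tpl$gate == "NE2", c("fsc", "ssc", "sfl")]
  se <- 1500 / sqrt(4000)
  expect_lt(abs(mean(ev$events[, "FSC"]) - mu$fsc), 3 * se)
  expect_lt(abs(mean(ev$events[, "SSC"]) - mu$ssc), 3 * se)
  expect_lt(abs(mean(ev$events[, "SFL"]) - mu$sfl), 3 * se)
})

test_that("negative weights are clipped and all-zero weights error", {
  tpl_all <- default_gate_templates()
  tpl <- tpl_all[tpl_all$channel == "WDF", ]
  cfg <- simulation_config(gate_templates = tpl, conditions = "baseline",
                           causal_effects = data.frame(),
                           events_per_sample = 300L, seed = 5)
  wdf_gates <- tpl$gate
  w <- stats::setNames(rep(-1, length(wdf_gates)), wdf_gates)
  st <- list(donor = "d", condition = "baseline", weights = list(WDF = w))
  expect_error(simulate_events(st, "baseline", cfg), "all mixture weights zero")
  w["NE1"] <- 1
  st$weights$WDF <- w
  ev <- simulate_events(st, "baseline", cfg)$WDF
  lab <- assign_gates(ev, gates_from_templates(tpl))
  expect_true(all(lab %in% c("NE1", "ungated")))
})

test_that("a causal variant raises the NE2 fraction of high-dosage donors", {
  cfg <- simulation_config(
    n_donors = 300L, n_variants = 20L, conditions = "baseline",
    causal_effects = data.frame(variant = 3L, condition = "*", gate = "NE2",
                                effect = 1.5),
    tone_loadings = c(NE2 = 0), events_per_sample = 500L, seed = 21)
  g <- simulate_genotypes(cfg)
  lat <- simulate_donor_latents(cfg, g)
  gates <- gates_from_templates(cfg$gate_templates)
  frac <- vapply(seq_len(cfg$n_donors), function(i) {
    st <- donor_state(cfg, lat, i, "baseline")
    ev <- simulate_events(st, "baseline", cfg)$WDF
    lab <- assign_gates(ev, gates)
    sum(lab == "NE2") / sum(lab %in% c("NE1", "NE2", "NE3", "NE4"))
  }, numeric(1))
  d <- g$dosage[, 3]
  expect_gt(mean(frac[d == 2]), mean(frac[d == 0]))
})

test_that("null outcome effects decouple event times from latents", {
  cfg <- simulation_config(
    n_donors = 3000L, n_variants = 5L, events_per_sample = 10L,
    outcome_effects = data.frame(latent = "tone", outcome = "NULLDX",
                                 log_hr = 0),
    seed = 13)
  g <- simulate_genotypes(cfg)
  lat <- simulate_donor_latents(cfg, g)
  oc <- simulate_outcomes(lat, cfg)
  r <- stats::cor(oc$records$onset_age_true, lat$tone)
  expect_lt(abs(r), 0.05)
})

test_that("onsets beyond the censoring age are emitted censored", {
  cfg <- tiny_sim_config(seed = 3)
  g <- simulate_genotypes(cfg)
  lat <- simulate_donor_latents(cfg, g)
  oc <- simulate_outcomes(lat, cfg)
  rec <- oc$records
  late <- rec$onset_age_true > rec$event_age + 1e-9 & rec$event == 0
  expect_true(all(rec$event[rec$onset_age_true > 90] == 0))
  expect_true(all(rec$event_age[late] <= 90 + 1e-9))
  # every record is either an observed event or censored at the recorded age
  expect_true(all(rec$event %in% c(0L, 1L)))
})

test_that("VCF round trip preserves dosages and variant metadata", {
  cfg <- tiny_sim_config(missing_rate = 0.05, seed = 17)
  g <- simulate_genotypes(cfg)
  path <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, path)
  back <- read_genotypes_vcf(path)
  expect_equal(unname(back$dosage), unname(g$dosage), tolerance = 1e-6)
  expect_equal(back$variants$pos, g$variants$pos)
  expect_equal(back$variants$id, g$variants$id)
})
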