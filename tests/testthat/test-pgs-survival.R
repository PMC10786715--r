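test_that("PGS construction clumps, thresholds and orients weights", {
  set.seed(51)
  n <- 300
  v <- stats::rbinom(n, 2, 0.4)
  noisy <- function(x, flips) {
    i <- sample(n, flips); x[i] <- pmin(pmax(x[i] + sample(c(-1, 1), flips, TRUE), 0), 2); x
  }
  geno <- make_geno(cbind(v, noisy(v, 15), stats::rbinom(n, 2, 0.4)),
                    pos = c(10000L, 60000L, 80000L))
  ss <- data.frame(trait = "tr", variant = c("v001", "v002", "v003"),
                   chrom = "1", pos = c(10000, 60000, 80000),
                   beta = c(0.4, 0.35, 0.2), p = c(0.01, 0.02, 0.2),
                   stringsAsFactors = FALSE)
  w <- build_pgs(ss, geno)
  # v002 clumps into v001 (r2 ~ 0.9, 50 kb); v003 fails the 0.1 threshold
  expect_equal(w$variant, "v001")
  expect_equal(w$weight, 0.4)
  expect_equal(w$effect_allele, "G")

  ss1 <- ss[1, ]; ss1$p <- 0.05
  w1 <- build_pgs(ss1, geno)
  expect_equal(nrow(w1), 1)
  ss2 <- ss[1, ]; ss2$p <- 0.2
  expect_warning(w2 <- build_pgs(ss2, geno), "no variants")
  expect_equal(nrow(w2), 0)
})

test_that("scoring equals the brute-force dot product and applies the imputation rule", {
  set.seed(52)
  n <- 100; m <- 50
  g <- matrix(stats::rbinom(n * m, 2, 0.3), n, m)
  g[sample(length(g), 200)] <- NA
  geno <- make_geno(g)
  w <- data.frame(variant = colnames(geno$dosage), effect_allele = "G",
                  weight = stats::rnorm(m), stringsAsFactors = FALSE)
  g <- geno$dosage
  sc <- score_genotypes(geno, w)
  gi <- g
  for (j in seq_len(m)) {
    af <- mean(gi[, j], na.rm = TRUE) / 2
    gi[is.na(gi[, j]), j] <- 2 * af
  }
  expect_lt(max(abs(sc$score - as.numeric(gi %*% w$weight))), 1e-12)

  # single weight on {0,1,2} dosages
  g1 <- make_geno(matrix(c(0, 1, 2), 3, 1))
  w1 <- data.frame(variant = "v001", effect_allele = "G", weight = 0.5)
  expect_equal(score_genotypes(g1, w1)$score, c(0, 0.5, 1.0))

  # effect allele equal to the reference flips the dosage
  wr <- data.frame(variant = "v001", effect_allele = "A", weight = 0.5)
  expect_equal(score_genotypes(g1, wr)$score, c(1.0, 0.5, 0))

  # an all-missing variant contributes 2 * frequency * weight everywhere
  g2 <- matrix(c(0, 1, 2, NA, NA, NA), 3, 2)
  geno2 <- make_geno(g2)
  geno2$variants$maf_target <- c(0.25, 0.25)
  w2 <- data.frame(variant = c("v001", "v002"), effect_allele = "G",
                   weight = c(0, 1), stringsAsFactors = FALSE)
  expect_equal(score_genotypes(geno2, w2)$score, rep(2 * 0.25, 3))

  expect_error(score_genotypes(g1, data.frame(variant = "zzz",
                                              effect_allele = "G",
                                              weight = 1)), "no overlapping")
})

test_that("survival encoding implements the instant-event and problem-list rules", {
  rec <- data.frame(
    donor = c("a", "b", "c", "d", "e"),
    entry_age = c(40, 40, 40, 40, 40),
    event_age = c(40.5, 55, 70, NA, 39),
    event = c(1L, 1L, 0L, 1L, 0L),
    problem_list = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  enc <- encode_survival(rec)
  r <- enc$records
  expect_equal(r[r$donor == "a", c("start", "stop", "event")],
               data.frame(start = 0, stop = 40, event = 1L,
                          row.names = which(r$donor == "a")))
  expect_equal(r$reason[r$donor == "a"], "instant_event")
  expect_equal(unlist(r[r$donor == "b", c("start", "stop", "event")]),
               c(start = 40, stop = 55, event = 1))
  expect_equal(r$reason[r$donor == "b"], "normal")
  expect_equal(unlist(r[r$donor == "c", c("start", "stop", "event")]),
               c(start = 40, stop = 70, event = 0))
  expect_equal(r[r$donor == "d", "reason"], "problem_list_interval")
  expect_equal(unlist(r[r$donor == "d", c("start", "stop")]),
               c(start = 0, stop = 40))
  # censored before entry: dropped but reported
  expect_false("e" %in% r$donor)
  expect_equal(enc$dropped$donor, "e")
  # conservation: each subject in exactly one place
  expect_equal(sort(c(r$donor, enc$dropped$donor)), sort(rec$donor))

  expect_error(encode_survival(transform(rec, entry_age = -1)), "negative")
})

test_that("delayed-entry Cox equals standard Cox when nothing is truncated", {
  set.seed(53)
  n <- 300
  z <- stats::rnorm(n)
  t <- stats::rexp(n, 0.1 * exp(0.4 * z))
  cens <- stats::rexp(n, 0.05)
  rec <- data.frame(start = 0, stop = pmin(t, cens),
                    event = as.integer(t <= cens))
  f1 <- cox_delayed_entry(rec, data.frame(z = z))
  f2 <- survival::coxph(survival::Surv(rec$stop, rec$event) ~ z,
                        ties = "efron")
  expect_lt(abs(f1$table$loghr - unname(stats::coef(f2))), 1e-6)
  expect_lt(abs(f1$table$se - sqrt(stats::vcov(f2)[1, 1])), 1e-6)
})

test_that("Cox estimates are invariant to reordering and scale equivariant; likelihood ascends", {
  set.seed(54)
  n <- 400
  z <- stats::rnorm(n)
  entry <- stats::runif(n, 0, 3)
  t <- entry + stats::rexp(n, 0.2 * exp(0.3 * z))
  rec <- data.frame(start = entry, stop = t,
                    event = stats::rbinom(n, 1, 0.8))
  f <- cox_delayed_entry(rec, data.frame(z = z))
  perm <- sample(n)
  fp <- cox_delayed_entry(rec[perm, ], data.frame(z = z[perm]))
  expect_equal(f$table$loghr, fp$table$loghr, tolerance = 1e-9)

  fs <- cox_delayed_entry(rec, data.frame(z = 10 * z))
  expect_equal(fs$table$loghr, f$table$loghr / 10, tolerance = 1e-9)

  expect_gte(f$loglik[2], f$loglik[1])   # fitted beats the null
})

test_that("quartile Kaplan-Meier strata order by hazard in a separated simulation", {
  set.seed(55)
  n <- 2000
  score <- stats::rnorm(n)
  t <- stats::rexp(n, 0.05 * exp(1.5 * score))
  rec <- data.frame(start = 0, stop = t, event = 1L)
  km <- km_quartiles(rec, score)
  s <- summary(km$fit, times = stats::median(t))
  surv_by_q <- s$surv[order(s$strata)]
  expect_equal(length(surv_by_q), 4)
  expect_true(all(diff(surv_by_q) < 0))   # higher score quartile, lower survival

  expect_warning(km_quartiles(rec[1:50, ], rep(1, 50)), "degenerate")
})

test_that("random-effects pooling degenerates and interpolates correctly", {
  m0 <- meta_random_effects(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(m0$pooled, 0.2, tolerance = 1e-9)
  expect_equal(m0$tau2, 0)
  expect_lte(m0$pooled_se, 0.1 + 1e-9)

  m1 <- meta_random_effects(0.3, 0.15)
  expect_equal(m1$pooled, 0.3)
  expect_equal(m1$tau2, 0)

  m2 <- meta_random_effects(c(0.1, 0.9), c(0.02, 0.02))
  expect_gt(m2$tau2, 0)
  expect_gt(m2$pooled, 0.1)
  expect_lt(m2$pooled, 0.9)

  grid <- data.frame(score = "s", endpoint = c("e1", "e1", "e2", "e2"),
                     cohort = c("A", "B", "A", "B"),
                     loghr = c(0.2, 0.25, -0.1, -0.05),
                     se = c(0.1, 0.1, 0.1, 0.1))
  mt <- suppressWarnings(meta_table(grid))
  expect_equal(nrow(mt), 2)
  expect_true(all(c("tau2", "q") %in% names(mt)))
})

test_that("CKD staging follows the eGFR bands with inclusive lower edges", {
  expect_equal(ckd_stage_from_egfr(c(90, 60, 59.9, 50, 45, 44.9, 30, 29.9, 15, 14.9, 10, 0)),
               c("none", "none", "3a", "3a", "3a", "3b", "3b", "4", "4", "5", "5", "5"))
  expect_error(ckd_stage_from_egfr(-1), "non-negative")
  expect_true(is.na(ckd_stage_from_egfr(NA)))
})
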