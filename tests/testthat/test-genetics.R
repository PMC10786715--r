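test_that("HWE exact test matches exhaustive enumeration for small samples", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  expect_equal(hwe_exact_test(0, 2, 0), hwe_enumeration_oracle(0, 2, 0))

  for (n_AA in 0:4) for (n_Aa in 0:4) for (n_aa in 0:4) {
    if (n_AA + n_Aa + n_aa < 1 || n_AA + n_Aa + n_aa > 10) next
    expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                 hwe_enumeration_oracle(n_AA, n_Aa, n_aa),
                 tolerance = 1e-12,
                 label = sprintf("(%d,%d,%d)", n_AA, n_Aa, n_aa))
  }
})

test_that("strong homozygote excess yields an extreme HWE p-value", {
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  # and equilibrium-looking counts do not
  expect_gt(hwe_exact_test(49, 42, 9), 0.05)
})

test_that("KING kinship hits pedigree expectations", {
  set.seed(31)
  p <- stats::runif(10000, 0.1, 0.5)
  geno_of <- function(h1, h2) h1 + h2
  h <- function() stats::rbinom(10000, 1, p)
  a <- geno_of(h(), h())
  expect_equal(king_kinship(a, a), 0.5)

  b <- geno_of(h(), h())
  expect_lt(abs(king_kinship(a, b)), 0.05)

  # parent-offspring: the child inherits one parental allele
  pa1 <- h(); pa2 <- h()
  parent <- geno_of(pa1, pa2)
  pick <- stats::rbinom(10000, 1, 0.5)
  child <- geno_of(ifelse(pick == 1, pa1, pa2), h())
  phi <- king_kinship(parent, child)
  expect_lt(abs(phi - 0.25), 0.05)

  expect_warning(
    expect_warning(king_kinship(c(0, 2, 0), c(2, 0, 2)), "jointly observed"),
    "no heterozygous")
})

test_that("variant QC excludes by missingness, MAF and MAC with reasons", {
  set.seed(8)
  n <- 200
  clean <- matrix(stats::rbinom(n * 30, 2, 0.3), n, 30)
  miss <- stats::rbinom(n, 2, 0.3); miss[1:30] <- NA     # 15% missing
  rare <- stats::rbinom(n, 2, 0.04)                      # MAF ~0.04
  g <- make_geno(cbind(clean, miss, rare))
  res <- variant_qc(g, scan_config(), prune_related = FALSE)
  expect_equal(res$report$reason[res$report$id == "v031"], "missingness")
  expect_equal(res$report$reason[res$report$id == "v032"], "maf")
  expect_false(any(c("v031", "v032") %in% colnames(res$geno$dosage)))
  # every excluded unit appears exactly once
  expect_false(anyDuplicated(res$report$id) > 0)

  clean_res <- variant_qc(make_geno(clean), scan_config(),
                          prune_related = FALSE)
  expect_equal(nrow(clean_res$report), 0)
})

test_that("kinship pruning removes one member of a duplicated pair", {
  set.seed(9)
  g <- matrix(stats::rbinom(50 * 300, 2, 0.3), 50, 300)
  g[2, ] <- g[1, ]                      # duplicate pair
  g[2, 1:30] <- NA                      # donor 2 has higher missingness
  geno <- make_geno(g)
  res <- variant_qc(geno, scan_config(miss_ceiling = 0.5), prune_related = TRUE)
  kin <- res$report[res$report$reason == "kinship", ]
  expect_equal(kin$id, "d002")
  expect_false("d002" %in% res$geno$donors)
})

test_that("association scan equals the per-variant least-squares oracle", {
  set.seed(15)
  n <- 50; m <- 20
  g <- make_geno(matrix(stats::rbinom(n * m, 2, 0.4), n, m))
  g$dosage[3, 7] <- NA                   # exercise the row-omission path
  y <- stats::rnorm(n)
  cov <- data.frame(age = stats::rnorm(n), sex = stats::rbinom(n, 1, 0.5))
  res <- association_scan(y, g, cov)
  for (j in seq_len(m)) {
    d <- data.frame(y = y, dose = g$dosage[, j],
                    age = scale(cov$age), sex = scale(cov$sex))
    fit <- summary(stats::lm(y ~ dose + age + sex, data = d))
    co <- fit$coefficients["dose", ]
    expect_lt(abs(res$beta[j] - co["Estimate"]), 1e-8)
    expect_lt(abs(res$se[j] - co["Std. Error"]), 1e-8)
    expect_lt(abs(res$p[j] - co["Pr(>|t|)"]), 1e-8)
  }
})

test_that("a noiseless trait recovers its construction exactly", {
  set.seed(16)
  g <- make_geno(matrix(stats::rbinom(200 * 3, 2, 0.5), 200, 3))
  y <- 0.5 * g$dosage[, 2]
  res <- association_scan(y, g, covariates = NULL)
  expect_equal(res$beta[2], 0.5, tolerance = 1e-10)
  expect_gte(res$p[2], 1e-320)   # underflow guard keeps p positive
})

test_that("null scans are calibrated and collinear covariates are dropped", {
  set.seed(17)
  n <- 400; m <- 800
  g <- make_geno(matrix(stats::rbinom(n * m, 2, 0.3), n, m))
  y <- stats::rnorm(n)
  res <- association_scan(y, g, covariates = NULL)
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m) + 0.005)

  cov <- data.frame(a = stats::rnorm(n))
  cov$b <- 2 * cov$a
  expect_warning(association_scan(y, g, cov), "collinear")
})

test_that("clumping matches the exhaustive oracle across random instances", {
  cfg <- scan_config()
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120; m <- 40
    block <- matrix(stats::rbinom(n * 8, 2, 0.3), n, 8)
    g <- cbind(block[, rep(1:8, 3)] , matrix(stats::rbinom(n * 16, 2, 0.3), n, 16))
    g <- g + matrix(stats::rbinom(length(g), 1, 0.08), n, m) *
      sample(c(-1, 1), length(g), TRUE)
    g <- pmin(pmax(g, 0), 2)
    geno <- make_geno(g, pos = sort(sample.int(5e5, m)))
    res <- rbind(
      data.frame(trait = "t1", variant = geno$variants$id,
                 chrom = "1", pos = geno$variants$pos,
                 p = 10^-stats::runif(m, 0, 12), stringsAsFactors = FALSE),
      data.frame(trait = "t2", variant = geno$variants$id,
                 chrom = "1", pos = geno$variants$pos,
                 p = 10^-stats::runif(m, 0, 12), stringsAsFactors = FALSE))
    mine <- clump(res, geno, cfg)
    oracle <- clump_oracle(res, geno$dosage, geno$variants)
    expect_equal(length(mine), length(oracle))
    mine_members <- lapply(mine, function(r) sort(r$members))
    oracle_members <- lapply(oracle, `[[`, "members")
    expect_setequal(vapply(mine_members, paste, "", collapse = ","),
                    vapply(oracle_members, paste, "", collapse = ","))
    expect_setequal(vapply(mine, `[[`, "", "lead"),
                    vapply(oracle, `[[`, "", "lead"))
  }
})

test_that("regions with single-trait support are discarded and distance splits regions", {
  set.seed(21)
  n <- 100
  v1 <- stats::rbinom(n, 2, 0.4)
  geno <- make_geno(cbind(v1, v1, stats::rbinom(n, 2, 0.4)),
                    pos = c(1000L, 2000L, 400000L))
  res <- data.frame(trait = c("t1", "t1", "t1"),
                    variant = c("v001", "v002", "v003"), chrom = "1",
                    pos = c(1000, 2000, 400000),
                    p = c(1e-10, 1e-9, 1e-12), stringsAsFactors = FALSE)
  expect_length(clump(res, geno, scan_config()), 0)

  res$trait <- c("t1", "t2", "t3")
  regions <- clump(res, geno, scan_config())
  # v003 sits 398 kb away at r2 ~ 0: its region has one trait and is dropped
  expect_length(regions, 1)
  expect_setequal(regions[[1]]$members, c("v001", "v002"))
  expect_equal(regions[[1]]$lead, "v001")
  expect_setequal(regions[[1]]$supporting_traits, c("t1", "t2"))
})

test_that("perfect-LD triplets on two traits clump to one region led by the smallest p", {
  set.seed(22)
  v <- stats::rbinom(150, 2, 0.5)
  geno <- make_geno(cbind(v, v, v), pos = c(1e4L, 2e4L, 3e4L))
  res <- data.frame(trait = c("tA", "tB", "tA"),
                    variant = c("v001", "v002", "v003"), chrom = "1",
                    pos = c(1e4, 2e4, 3e4), p = c(1e-10, 1e-9, 1e-8),
                    stringsAsFactors = FALSE)
  regions <- clump(res, geno, scan_config())
  expect_length(regions, 1)
  expect_equal(regions[[1]]$lead, "v001")
  expect_setequal(regions[[1]]$members, c("v001", "v002", "v003"))
})

test_that("genotype PCs separate simulated subpopulations", {
  set.seed(23)
  n <- 120; m <- 300
  p1 <- stats::runif(m, 0.1, 0.9)
  shift <- stats::rnorm(m, 0, 0.18)
  p2 <- pmin(pmax(p1 + shift, 0.02), 0.98)
  g <- rbind(matrix(stats::rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
             matrix(stats::rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m))
  pcs <- genotype_pcs(make_geno(g), k = 2)
  grp <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(stats::cor(pcs[, 1], grp)), 0.5)
})
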