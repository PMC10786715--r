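make_table <- function(events, channel = "WDF", donor = "d1",
                       condition = "baseline") {
  perturbscreen:::new_event_table(donor, condition, channel, events)
}

test_that("CSV event tables round trip, including the empty case", {
  path <- tempfile(fileext = ".csv")
  ev <- matrix(c(100, 50, 80, 1, 2, 3, 9, 8, 7, 0, 0, 0, 5, 5, 5),
               ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("FSC", "SSC", "SFL")))
  write_events(make_table(ev), path, "csv")
  tab <- read_events(path, "csv", donor = "d1", condition = "baseline",
                     channel = "WDF")
  expect_equal(nrow(tab$events), 5)
  expect_equal(unname(tab$events), unname(ev))

  writeLines("FSC,SSC,SFL", path)
  empty <- read_events(path, "csv", donor = "d", condition = "c", channel = "WDF")
  expect_equal(nrow(empty$events), 0)
})

test_that("FCS files written by the generator read back at float32 precision", {
  cfg <- tiny_sim_config(seed = 8)
  g <- simulate_genotypes(cfg)
  lat <- simulate_donor_latents(cfg, g)
  ev <- simulate_events(donor_state(cfg, lat, 2, "baseline"), "baseline", cfg)$RET
  path <- tempfile(fileext = ".fcs")
  write_events(ev, path, "fcs")
  back <- read_events(path, "fcs", donor = ev$donor, condition = ev$condition,
                      channel = ev$channel)
  # float32 keeps ~7 significant digits; values are O(1e5)
  expect_lt(max(abs(back$events - ev$events)), 0.05)
  expect_identical(colnames(back$events), c("FSC", "SSC", "SFL"))
})

test_that("truncated FCS and unknown channel names raise informative errors", {
  path <- tempfile(fileext = ".fcs")
  ev <- make_table(matrix(1:30, 10, 3, dimnames = list(NULL, c("FSC", "SSC", "SFL"))))
  write_events(ev, path, "fcs")
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:80], path)
  expect_error(read_events(path, "fcs", donor = "d", condition = "c",
                           channel = "WDF"), "truncated")

  csv <- tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), csv)
  expect_error(read_events(csv, "csv", donor = "d", condition = "c",
                           channel = "WDF"), "a, b, c")
})

test_that("gate assignment follows bounds convention and priority ranks", {
  ev <- make_table(matrix(c(100, 50, 80), 1, 3,
                          dimnames = list(NULL, c("FSC", "SSC", "SFL"))))
  g1 <- gate_definition("A", "WDF", ssc = c(0, 100), sfl = c(0, 100),
                        priority = 1)
  expect_equal(as.character(assign_gates(ev, list(g1))), "A")

  # lower bound inclusive, upper exclusive
  edge_lo <- make_table(matrix(c(0, 0, 0), 1, 3))
  edge_hi <- make_table(matrix(c(100, 100, 100), 1, 3))
  g2 <- gate_definition("B", "WDF", fsc = c(0, 100), ssc = c(0, 100),
                        sfl = c(0, 100), priority = 1)
  expect_equal(as.character(assign_gates(edge_lo, list(g2))), "B")
  expect_equal(as.character(assign_gates(edge_hi, list(g2))), "ungated")

  # overlapping gates: lower rank wins
  gA <- gate_definition("A", "WDF", ssc = c(0, 100), priority = 1)
  gB <- gate_definition("B", "WDF", ssc = c(0, 100), priority = 2)
  expect_equal(as.character(assign_gates(ev, list(gB, gA))), "A")
  # empty gate list: everything ungated
  expect_equal(as.character(assign_gates(ev, list())), "ungated")
})

test_that("robust statistics match closed-form values and Gaussian consistency", {
  s <- robust_stats(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$robust_sd, 1.4826)
  expect_equal(s$robust_cv, 74.13)

  s2 <- robust_stats(c(5, 5, 5, 5))
  expect_equal(unlist(s2), c(median = 5, robust_sd = 0, robust_cv = 0))

  s3 <- robust_stats(numeric(0))
  expect_true(all(is.na(unlist(s3))))

  set.seed(42)
  s4 <- robust_stats(stats::rnorm(10000, 10, 2))
  expect_lt(abs(s4$robust_sd - 2) / 2, 0.02)

  expect_true(is.na(robust_stats(c(-1, 0, 1))$robust_cv))
})

test_that("featurize emits the expected schema and percentage bookkeeping", {
  set.seed(1)
  evs <- rbind(cbind(stats::rnorm(60, 100, 1), stats::rnorm(60, 100, 1),
                     stats::rnorm(60, 100, 1)),
               cbind(stats::rnorm(40, 500, 1), stats::rnorm(40, 500, 1),
                     stats::rnorm(40, 500, 1)))
  tab <- make_table(evs)
  gates <- list(gate_definition("G1", "WDF", fsc = c(0, 300), priority = 1),
                gate_definition("G2", "WDF", fsc = c(300, 1000), priority = 2))
  ratios <- list(ratio_definition("G1/G2", "WDF", "G1", "G2"))
  out <- featurize(list(tab), gates, ratios)
  expect_equal(nrow(out), 2 * 11 + 1)        # 11 stats per gate + 1 ratio
  pct <- out$value[grepl("_Pct$", out$parameter)]
  expect_equal(sum(pct), 100)
  expect_equal(out$value[out$parameter == "WDF_baseline_G1/G2"], 60 / 40)

  # all events in one gate
  out1 <- featurize(list(tab), gates[1], ratios = list())
  expect_equal(out1$value[out1$parameter == "WDF_baseline_G1_Pct"], 60)
})

test_that("gate counts plus ungated account for every event and order does not matter", {
  cfg <- tiny_sim_config(seed = 10)
  g <- simulate_genotypes(cfg)
  lat <- simulate_donor_latents(cfg, g)
  tabs <- simulate_events(donor_state(cfg, lat, 5, "baseline"), "baseline", cfg)
  gates <- gates_from_templates(cfg$gate_templates)
  for (tab in tabs) {
    lab <- assign_gates(tab, gates)
    expect_equal(length(lab), nrow(tab$events))
    expect_equal(sum(table(lab)), nrow(tab$events))
  }
  f1 <- featurize(tabs, gates)
  perm <- tabs
  for (i in seq_along(perm)) {
    set.seed(i)
    perm[[i]]$events <- perm[[i]]$events[sample(nrow(perm[[i]]$events)), ]
  }
  f2 <- featurize(perm, gates)
  expect_equal(f1, f2)
})

test_that("low-count gates keep Count and Pct but mask distributional statistics", {
  ev <- make_table(matrix(stats::rnorm(15, 50, 1), 5, 3,
                          dimnames = list(NULL, c("FSC", "SSC", "SFL"))))
  gates <- list(gate_definition("G", "WDF", fsc = c(0, 100), priority = 1))
  out <- featurize(list(ev), gates, ratios = list(), min_count = 10)
  val <- function(p) out$value[out$parameter == paste0("WDF_baseline_G_", p)]
  expect_equal(val("Count"), 5)
  expect_equal(val("Pct"), 100)
  expect_true(is.na(val("Med_SSC")))
})

test_that("duplicate donor-condition inputs are rejected", {
  ev <- make_table(matrix(1:3, 1, 3))
  ev2 <- make_table(matrix(1:3, 1, 3), donor = "d2")
  gates <- list(gate_definition("G", "WDF", fsc = c(0, 100), priority = 1))
  expect_error(featurize(list(ev, ev2), gates), "single donor")
  expect_error(featurize(list(ev, ev), gates), "duplicate channel")
})

test_that("derive_ratio handles zero numerators, zero denominators and unknown gates", {
  counts <- c(NE2 = 50, NE4 = 200)
  expect_equal(derive_ratio(counts, "NE2", "NE4"), 0.25)
  expect_equal(derive_ratio(c(NE2 = 0, NE4 = 10), "NE2", "NE4"), 0)
  expect_true(is.na(derive_ratio(c(NE2 = 5, NE4 = 0), "NE2", "NE4")))
  expect_error(derive_ratio(counts, "NEX", "NE4"), "unknown gate")
  # multi-gate denominators sum counts
  counts4 <- c(NE1 = 10, NE2 = 30, NE3 = 20, NE4 = 40)
  expect_equal(derive_ratio(counts4, "NE2", c("NE1", "NE2", "NE3", "NE4")), 0.3)
})
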