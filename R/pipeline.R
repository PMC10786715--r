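#' Assemble and validate a pipeline configuration
#'
#' Collects the per-module parameter blocks plus stage toggles and the
#' global seed. Any block may be overridden by the corresponding argument;
#' `sim` accepts either a [simulation_config()] or a list of arguments for
#' it. A configuration can also be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param sim simulation block.
#' @param qc list: mad_k, ica_k, variance_threshold.
#' @param scan list of [scan_config()] arguments plus `n_pcs`.
#' @param pgs list: p1, r2, kb, score_p, max_scores.
#' @param survival list: instant_window, application_n (donors per
#'   application cohort), application_cohorts.
#' @param stages named logical vector toggling pipeline stages.
#' @param seed global seed (fans out per stage via [child_seed()]).
#' @export
pipeline_config <- function(sim = list(), qc = list(), scan = list(),
                            pgs = list(), survival = list(),
                            stages = NULL, seed = 1L) {
  defaults <- list(
    qc = list(mad_k = 4, ica_k = 2.5, variance_threshold = 0.9),
    scan = list(n_pcs = 10L),
    pgs = list(p1 = 0.5, r2 = 0.5, kb = 100, score_p = 0.1, max_scores = 3L),
    survival = list(instant_window = 1, application_n = 300L,
                    application_cohorts = c("cohortB", "cohortC"))
  )
  stage_names <- c("simulate", "gate", "qc", "scan", "clump", "clinical",
                   "pgs", "survive", "meta", "ica")
  st <- stats::setNames(rep(TRUE, length(stage_names)), stage_names)
  if (!is.null(stages)) st[names(stages)] <- unlist(stages)

  if (!inherits(sim, "sim_config"))
    sim <- do.call(simulation_config, utils::modifyList(list(seed = seed), sim))
  cfg <- list(
    sim = sim,
    qc = utils::modifyList(defaults$qc, qc),
    scan = utils::modifyList(defaults$scan, scan),
    pgs = utils::modifyList(defaults$pgs, pgs),
    survival = utils::modifyList(defaults$survival, survival),
    stages = st, seed = as.integer(seed))
  scan_args <- cfg$scan[setdiff(names(cfg$scan), "n_pcs")]
  cfg$scan_config <- do.call(scan_config, scan_args)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: %s", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y),
                                       names(formals(pipeline_config)))])
}

#' Demo configuration: 200 donors, 500 variants, 3 conditions
#'
#' The scale used by the packaged end-to-end example.
#' @param seed global seed.
#' @param events_per_sample events per donor x condition x channel.
#' @export
demo_pipeline_config <- function(seed = 1L, events_per_sample = 400L) {
  pipeline_config(
    sim = list(n_donors = 200L, n_variants = 500L,
               events_per_sample = events_per_sample),
    seed = seed)
}

log_line <- function(state, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(msg, "\n", sep = "", file = state$log_path, append = TRUE)
  invisible(msg)
}

register_output <- function(state, stage, path) {
  state$outputs[[stage]] <- c(state$outputs[[stage]], path)
  state
}

#' Run the full pipeline
#'
#' Executes, in fixed order: simulate, gate, qc, scan, clump, clinical,
#' pgs, survive, meta, ica. Each stage writes its tabular outputs and a log
#' into `out_dir`, and the run ends with a `manifest.json` recording the
#' MD5 checksum of every output so any modified intermediate is detectable.
#' Re-running with an identical configuration reproduces byte-identical
#' outputs. A disabled stage whose outputs a later stage needs aborts with
#' a dependency error naming both stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, the state list with all in-memory intermediates.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(dir = out_dir, outputs = list(),
                log_path = file.path(out_dir, "run.log"))
  cat("", file = state$log_path)  # truncate
  on_stage <- function(name) isTRUE(config$stages[[name]])
  need <- function(done, stage, needs) {
    if (!done) stop_config("stage '%s' requires stage '%s' to have run",
                           stage, needs)
  }

  if (on_stage("simulate")) state <- stage_simulate(state, config)
  if (on_stage("gate")) {
    need(!is.null(state$events_index), "gate", "simulate")
    state <- stage_gate(state, config)
  }
  if (on_stage("qc")) {
    need(!is.null(state$pheno_raw), "qc", "gate")
    state <- stage_qc(state, config)
  }
  if (on_stage("scan")) {
    need(!is.null(state$pheno_qc), "scan", "qc")
    state <- stage_scan(state, config)
  }
  if (on_stage("clump")) {
    need(!is.null(state$scan_results), "clump", "scan")
    state <- stage_clump(state, config)
  }
  if (on_stage("clinical")) {
    need(!is.null(state$pheno_qc), "clinical", "qc")
    state <- stage_clinical(state, config)
  }
  if (on_stage("pgs")) {
    need(!is.null(state$scan_results), "pgs", "scan")
    state <- stage_pgs(state, config)
  }
  if (on_stage("survive")) {
    need(!is.null(state$pgs_scores), "survive", "pgs")
    state <- stage_survive(state, config)
  }
  if (on_stage("meta")) {
    need(!is.null(state$survival_grid), "meta", "survive")
    state <- stage_meta(state, config)
  }
  if (on_stage("ica")) {
    need(!is.null(state$meta_results), "ica", "meta")
    state <- stage_ica(state, config)
  }

  manifest <- list(
    seed = config$seed,
    stages_run = names(which(config$stages)),
    outputs = lapply(state$outputs, function(paths) {
      md5 <- tools::md5sum(paths)
      rel <- ifelse(startsWith(names(md5), paste0(out_dir, "/")),
                    substring(names(md5), nchar(out_dir) + 2L), names(md5))
      stats::setNames(as.list(unname(md5)), rel)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(state, "pipeline complete: %d stages, %d output files",
           sum(config$stages), length(unlist(state$outputs)))
  invisible(state)
}

stage_simulate <- function(state, config) {
  sim <- config$sim
  log_line(state, "simulate: %d donors, %d variants, %d conditions, seed %d",
           sim$n_donors, sim$n_variants, length(sim$conditions), sim$seed)
  geno <- simulate_genotypes(sim)
  covar <- simulate_covariates(sim)
  latents <- simulate_donor_latents(sim, geno)
  outc <- simulate_outcomes(latents, sim)

  ev_dir <- file.path(state$dir, "events")
  dir.create(ev_dir, showWarnings = FALSE)
  index <- list()
  for (donor in latents$donor) {
    for (cond in sim$conditions) {
      stt <- donor_state(sim, latents, donor, cond)
      tabs <- simulate_events(stt, cond, sim)
      for (ch in names(tabs)) {
        path <- file.path(ev_dir, sprintf("%s_%s_%s.csv", donor, cond, ch))
        write_events(tabs[[ch]], path, format = "csv")
        index[[length(index) + 1L]] <- data.frame(
          donor = donor, condition = cond, channel = ch, path = path,
          stringsAsFactors = FALSE)
      }
    }
  }
  index <- do.call(rbind, index)

  paths <- file.path(state$dir, c("genotypes.vcf", "covariates.tsv",
                                  "latents.tsv", "outcomes.tsv", "labs.tsv",
                                  "events_index.tsv"))
  write_genotypes_vcf(geno, paths[1])
  write_tsv(covar, paths[2])
  write_tsv(latents, paths[3])
  write_tsv(outc$records, paths[4])
  write_tsv(outc$labs, paths[5])
  idx_rel <- index
  idx_rel$path <- basename(index$path)
  write_tsv(idx_rel, paths[6])
  state$geno <- geno; state$covariates <- covar; state$latents <- latents
  state$outcomes <- outc; state$events_index <- index
  register_output(state, "simulate", c(paths, index$path))
}

stage_gate <- function(state, config) {
  sim <- config$sim
  gates <- gates_from_templates(sim$gate_templates,
                                instrument_max = sim$instrument_max)
  idx <- state$events_index
  long <- list()
  for (key in unique(paste(idx$donor, idx$condition, sep = "\r"))) {
    rows <- idx[paste(idx$donor, idx$condition, sep = "\r") == key, ]
    tabs <- lapply(seq_len(nrow(rows)), function(i) {
      read_events(rows$path[i], format = "csv", donor = rows$donor[i],
                  condition = rows$condition[i], channel = rows$channel[i])
    })
    long[[length(long) + 1L]] <- featurize(tabs, gates)
  }
  long <- do.call(rbind, long)
  pheno <- phenotype_matrix(long)
  meta <- unique(long[, c("parameter", "condition")])
  meta$channel <- sub("_.*$", "", meta$parameter)
  log_line(state, "gate: %d donors x %d parameters", nrow(pheno), ncol(pheno))

  p1 <- file.path(state$dir, "phenotypes_long.tsv")
  p2 <- file.path(state$dir, "phenotypes_wide.tsv")
  p3 <- file.path(state$dir, "parameter_meta.tsv")
  write_tsv(long, p1)
  write_tsv(data.frame(donor = rownames(pheno), pheno, check.names = FALSE), p2)
  write_tsv(meta, p3)
  state$pheno_raw <- pheno
  state$param_meta <- meta
  register_output(state, "gate", c(p1, p2, p3))
}

stage_qc <- function(state, config) {
  qc <- apply_phenotype_qc(state$pheno_raw, state$param_meta,
                           mad_k = config$qc$mad_k, ica_k = config$qc$ica_k,
                           seed = child_seed(config$seed, "qc"))
  log_line(state,
           "qc: mad_k=%g masked %d cells; ica_k=%g removed %d donors",
           config$qc$mad_k, sum(qc$cell_mask), config$qc$ica_k,
           length(unique(qc$removed_donors$donor)))
  blocks <- list()
  for (cond in unique(state$param_meta$condition)) {
    cols <- state$param_meta$parameter[state$param_meta$condition == cond]
    blocks[[cond]] <- qc$matrix[, intersect(colnames(qc$matrix), cols),
                                drop = FALSE]
  }
  indep <- suppressWarnings(
    estimate_independent_traits(blocks, config$qc$variance_threshold))
  log_line(state, "qc: independent traits per block [%s], overall %d",
           paste(sprintf("%s=%d", names(indep$per_block), indep$per_block),
                 collapse = ", "), indep$overall)

  p1 <- file.path(state$dir, "phenotypes_qc.tsv")
  p2 <- file.path(state$dir, "qc_report.tsv")
  p3 <- file.path(state$dir, "qc_removed_donors.tsv")
  p4 <- file.path(state$dir, "independent_traits.tsv")
  write_tsv(data.frame(donor = rownames(qc$matrix), qc$matrix,
                       check.names = FALSE), p1)
  write_tsv(qc$report, p2)
  write_tsv(qc$removed_donors, p3)
  write_tsv(data.frame(block = names(indep$per_block),
                       components = as.integer(indep$per_block),
                       overall = indep$overall), p4)
  state$pheno_qc <- qc$matrix
  state$qc_result <- qc
  state$independent_traits <- indep
  register_output(state, "qc", c(p1, p2, p3, p4))
}

stage_scan <- function(state, config) {
  vqc <- variant_qc(state$geno, config$scan_config)
  geno_f <- vqc$geno
  donors <- intersect(rownames(state$pheno_qc), geno_f$donors)
  keep <- match(donors, geno_f$donors)
  geno_s <- structure(list(dosage = geno_f$dosage[keep, , drop = FALSE],
                           variants = geno_f$variants, donors = donors),
                      class = "genotype_matrix")
  # cap the PC count for small cohorts so the model keeps residual df
  n_pcs <- min(config$scan$n_pcs, max(2L, length(donors) %/% 20L))
  pcs <- genotype_pcs(geno_s, k = n_pcs)
  cov <- state$covariates[match(donors, state$covariates$donor), ]
  covariates <- data.frame(age = cov$age, sex = cov$sex,
                           draw_time = cov$draw_time,
                           study_month = cov$study_month,
                           chip = factor(cov$chip), batch = factor(cov$batch))
  covariates <- cbind(covariates, as.data.frame(pcs))
  p_model <- ncol(stats::model.matrix(~ ., covariates))

  traits <- state$pheno_qc[donors, , drop = FALSE]
  traits <- traits[, colSums(!is.na(traits)) >= p_model + 3L, drop = FALSE]
  if (!ncol(traits))
    stop_config("scan: no traits with enough non-missing donors (need >= %d)",
                p_model + 3L)
  log_line(state, "scan: %d traits x %d variants on %d donors (%d excluded by variant QC)",
           ncol(traits), ncol(geno_s$dosage), length(donors), nrow(vqc$report))
  res <- suppressWarnings(association_scan_multi(traits, geno_s, covariates))

  p1 <- file.path(state$dir, "scan_sumstats.tsv")
  p2 <- file.path(state$dir, "variant_qc_report.tsv")
  write_tsv(res, p1)
  write_tsv(vqc$report, p2)
  state$scan_results <- res
  state$geno_filtered <- geno_s
  state$scan_covariates <- covariates
  register_output(state, "scan", c(p1, p2))
}

stage_clump <- function(state, config) {
  regions <- clump(state$scan_results, state$geno_filtered,
                   config$scan_config)
  log_line(state, "clump: %d regions (r2>%.2f, <%g kb, >=%d traits, p<%g)",
           length(regions), config$scan_config$clump_r2,
           config$scan_config$clump_kb, config$scan_config$min_traits,
           config$scan_config$sig_threshold)
  tab <- clump_table(regions)
  p1 <- file.path(state$dir, "clumped_regions.tsv")
  write_tsv(tab, p1)
  state$clump_regions <- regions
  register_output(state, "clump", p1)
}

stage_clinical <- function(state, config) {
  top <- if (length(state$clump_regions %||% list())) {
    select_top_traits(state$scan_results, state$clump_regions, k = 3)
  } else character(0)
  if (length(top) < 3L) {
    # fall back to the strongest-scanned traits so the stage remains testable
    agg <- stats::aggregate(p ~ trait, data = state$scan_results, FUN = min)
    top <- unique(c(top, agg$trait[order(agg$p)]))[seq_len(min(6L, nrow(agg)))]
  }
  donors <- rownames(state$pheno_qc)
  rec <- state$outcomes$records
  outcomes <- sort(unique(rec$outcome))
  binary <- vapply(outcomes, function(o) {
    r <- rec[rec$outcome == o, ]
    r$event[match(donors, r$donor)]
  }, numeric(length(donors)))
  rownames(binary) <- donors
  labs <- as.matrix(state$outcomes$labs[match(donors, state$outcomes$labs$donor),
                                        -1, drop = FALSE])
  rownames(labs) <- donors
  cov <- state$covariates[match(donors, state$covariates$donor), ]
  covariates <- data.frame(age = cov$age, race = factor(cov$race),
                           sex = cov$sex, draw_time = cov$draw_time)
  traits <- state$pheno_qc[, intersect(top, colnames(state$pheno_qc)),
                           drop = FALSE]
  asm <- suppressWarnings(assoc_score_matrix(traits, binary, labs, covariates))
  log_line(state, "clinical: %d traits x %d endpoints, pi0=%.3f",
           nrow(asm$stat), ncol(asm$stat), asm$pi0)

  paths <- file.path(state$dir, c("clinical_assoc.tsv", "clinical_ica.tsv"))
  write_tsv(asm$long, paths[1])
  if (nrow(asm$stat) >= 3L && ncol(asm$stat) >= 3L) {
    proj <- ica_project(asm$stat, seed = child_seed(config$seed, "clinical_ica"))
    write_tsv(data.frame(endpoint = rownames(proj$coordinates),
                         proj$coordinates), paths[2])
    state$clinical_ica <- proj
  } else paths <- paths[1]
  state$clinical_assoc <- asm
  register_output(state, "clinical", paths)
}

stage_pgs <- function(state, config) {
  top <- unique(state$clinical_assoc$long$trait %||%
                  unique(state$scan_results$trait))
  top <- utils::head(top, config$pgs$max_scores)
  weights <- list()
  for (tr in top) {
    ss <- state$scan_results[state$scan_results$trait == tr, ]
    w <- suppressWarnings(build_pgs(ss, state$geno_filtered,
                                    p1 = config$pgs$p1, r2 = config$pgs$r2,
                                    kb = config$pgs$kb,
                                    score_p = config$pgs$score_p))
    if (nrow(w)) weights[[tr]] <- w
  }
  log_line(state, "pgs: %d scores built (p1=%g, r2=%g, kb=%g, score_p=%g)",
           length(weights), config$pgs$p1, config$pgs$r2, config$pgs$kb,
           config$pgs$score_p)

  # application cohorts simulated from the same generative model
  app <- list()
  for (cname in config$survival$application_cohorts) {
    sim_app <- config$sim
    sim_app$n_donors <- as.integer(config$survival$application_n)
    sim_app$seed <- child_seed(config$seed, paste0("application_", cname))
    geno_a <- simulate_genotypes(sim_app)
    geno_a$donors <- paste0(cname, "_", geno_a$donors)
    rownames(geno_a$dosage) <- geno_a$donors
    lat_a <- simulate_donor_latents(sim_app, geno_a)
    lat_a$donor <- geno_a$donors
    out_a <- simulate_outcomes(lat_a, sim_app)
    cov_a <- simulate_covariates(sim_app)
    cov_a$donor <- geno_a$donors
    scores <- lapply(weights, function(w) score_genotypes(geno_a, w))
    app[[cname]] <- list(geno = geno_a, latents = lat_a, outcomes = out_a,
                         covariates = cov_a, scores = scores,
                         pcs = genotype_pcs(geno_a, k = 2))
  }

  wtab <- do.call(rbind, weights)
  p1 <- file.path(state$dir, "pgs_weights.tsv")
  write_tsv(wtab %||% data.frame(variant = character(),
                                 effect_allele = character(),
                                 weight = numeric(), trait = character()), p1)
  state$pgs_weights <- weights
  state$pgs_scores <- app
  register_output(state, "pgs", p1)
}

stage_survive <- function(state, config) {
  grid <- list()
  for (cname in names(state$pgs_scores)) {
    a <- state$pgs_scores[[cname]]
    rec_all <- a$outcomes$records
    for (outc in unique(rec_all$outcome)) {
      rec <- rec_all[rec_all$outcome == outc, ]
      enc <- encode_survival(rec, config$survival$instant_window)
      m <- match(enc$records$donor, a$covariates$donor)
      base_cov <- data.frame(sex = a$covariates$sex[m],
                             PC1 = a$pcs[enc$records$donor, 1],
                             PC2 = a$pcs[enc$records$donor, 2])
      for (tr in names(a$scores)) {
        sc <- a$scores[[tr]]
        covs <- cbind(base_cov,
                      score = sc$score_scaled[match(enc$records$donor,
                                                    sc$donor)])
        fit <- tryCatch(cox_delayed_entry(enc$records, covs),
                        error = function(e) NULL)
        if (is.null(fit)) next
        row <- fit$table[fit$table$term == "score", ]
        grid[[length(grid) + 1L]] <- data.frame(
          score = tr, endpoint = outc, cohort = cname,
          loghr = row$loghr, se = row$se, z = row$z, p = row$p,
          n = nrow(enc$records), events = sum(enc$records$event),
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, grid)
  log_line(state, "survive: %d cohort x score x endpoint models", NROW(grid))
  p1 <- file.path(state$dir, "survival_assoc.tsv")
  write_tsv(grid, p1)
  state$survival_grid <- grid
  register_output(state, "survive", p1)
}

stage_meta <- function(state, config) {
  mt <- meta_table(state$survival_grid)
  log_line(state, "meta: %d pooled models, %d with tau2 > 0",
           nrow(mt), sum(mt$tau2 > 0))
  forest <- mt
  forest$ci_lo <- forest$pooled_loghr - 1.96 * forest$pooled_se
  forest$ci_hi <- forest$pooled_loghr + 1.96 * forest$pooled_se
  p1 <- file.path(state$dir, "meta_results.tsv")
  write_tsv(forest, p1)
  state$meta_results <- mt
  register_output(state, "meta", p1)
}

stage_ica <- function(state, config) {
  mt <- state$meta_results
  scores <- unique(mt$score)
  endpoints <- unique(mt$endpoint)
  z <- matrix(NA_real_, length(scores), length(endpoints),
              dimnames = list(scores, endpoints))
  z[cbind(match(mt$score, scores), match(mt$endpoint, endpoints))] <- mt$z
  if (length(scores) < 3L || length(endpoints) < 3L) {
    log_line(state, "ica: skipped (need >= 3 scores and >= 3 endpoints)")
    return(state)
  }
  proj <- ica_project(z, seed = child_seed(config$seed, "meta_ica"))
  log_line(state, "ica: projected %d endpoints x %d scores onto 2 components",
           length(endpoints), length(scores))
  p1 <- file.path(state$dir, "meta_ica.tsv")
  write_tsv(data.frame(endpoint = rownames(proj$coordinates),
                       proj$coordinates), p1)
  state$meta_ica <- proj
  register_output(state, "ica", p1)
}
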