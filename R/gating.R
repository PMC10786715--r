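#' Define an axis-aligned gate
#'
#' A gate is a box on any subset of the three optical axes; bounds are lower
#' inclusive, upper exclusive, so gates with shared edges tile the plane
#' without double counting. When boxes overlap the gate with the lower
#' priority rank wins.
#'
#' @param gate gate name.
#' @param channel channel the gate belongs to (WDF/WNR/RET/PLTF).
#' @param fsc,ssc,sfl `c(lower, upper)` bounds, or `NULL` for unbounded.
#' @param priority integer rank; lower wins on overlap.
#' @return a `gate_definition`.
#' @export
gate_definition <- function(gate, channel, fsc = NULL, ssc = NULL, sfl = NULL,
                            priority = 1L) {
  for (b in list(fsc, ssc, sfl)) {
    if (!is.null(b) && (length(b) != 2L || !(b[1] < b[2])))
      stop_config("gate '%s': bounds must satisfy lower < upper", gate)
  }
  structure(list(gate = gate, channel = channel,
                 bounds = list(FSC = fsc, SSC = ssc, SFL = sfl),
                 priority = as.integer(priority)),
            class = "gate_definition")
}

#' Derive box gates from mixture templates
#'
#' Places a box of half-width `k_spread` spreads around each template
#' component mean on all three axes, clipped to the instrument range.
#' Priority follows template row order.
#'
#' @param templates data.frame as [default_gate_templates()].
#' @param k_spread box half-width in component spreads (default 4).
#' @param instrument_max upper end of the optical range.
#' @return list of `gate_definition`.
#' @export
gates_from_templates <- function(templates = default_gate_templates(),
                                 k_spread = 4, instrument_max = 2^18) {
  out <- vector("list", nrow(templates))
  rank_in_channel <- stats::ave(seq_len(nrow(templates)), templates$channel,
                                FUN = seq_along)
  for (i in seq_len(nrow(templates))) {
    t <- templates[i, ]
    box <- function(mu, s) c(max(0, mu - k_spread * s),
                             min(instrument_max, mu + k_spread * s))
    out[[i]] <- gate_definition(t$gate, t$channel,
                                fsc = box(t$fsc, t$s_fsc),
                                ssc = box(t$ssc, t$s_ssc),
                                sfl = box(t$sfl, t$s_sfl),
                                priority = rank_in_channel[i])
  }
  out
}

#' Assign events to gates
#'
#' Each event is assigned to the highest-priority (lowest rank) gate whose
#' bounds contain it, with lower-inclusive / upper-exclusive intervals;
#' events contained by no gate are labelled `"ungated"`. Gates for channels
#' other than the table's are ignored.
#'
#' @param table an `event_table`.
#' @param gates list of `gate_definition`.
#' @return factor of length `nrow(table$events)` with gate names plus
#'   `"ungated"`.
#' @export
assign_gates <- function(table, gates) {
  stopifnot(inherits(table, "event_table"))
  gates <- Filter(function(g) g$channel == table$channel, gates)
  n <- nrow(table$events)
  labels <- rep("ungated", n)
  if (length(gates)) {
    pr <- vapply(gates, `[[`, 1L, "priority")
    if (anyDuplicated(pr))
      stop_config("priority ranks must be unique within channel %s", table$channel)
    # apply in decreasing rank so higher-priority gates overwrite on overlap
    for (g in gates[order(pr, decreasing = TRUE)]) {
      inside <- rep(TRUE, n)
      for (ax in c("FSC", "SSC", "SFL")) {
        b <- g$bounds[[ax]]
        if (!is.null(b))
          inside <- inside & table$events[, ax] >= b[1] & table$events[, ax] < b[2]
      }
      labels[inside] <- g$gate
    }
  }
  factor(labels, levels = c(vapply(gates, `[[`, "", "gate"), "ungated"))
}

#' Robust location and scale statistics
#'
#' Median, robust s.d. (Gaussian-consistent `1.4826 * MAD`) and robust
#' coefficient of variation (`100 * robust_sd / median`; missing when the
#' median is zero). An empty vector yields all-missing statistics.
#'
#' @param values numeric vector (must be finite).
#' @return named list `(median, robust_sd, robust_cv)`.
#' @export
robust_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    return(list(median = NA_real_, robust_sd = NA_real_, robust_cv = NA_real_))
  if (any(!is.finite(values))) stop_config("robust_stats: values must be finite")
  med <- stats::median(values)
  rsd <- 1.4826 * stats::median(abs(values - med))
  rcv <- if (med == 0) NA_real_ else 100 * rsd / med
  list(median = med, robust_sd = rsd, robust_cv = rcv)
}

#' Define a count ratio between gate sets
#'
#' @param name ratio name as it appears in parameter names (e.g. "NE2/NE4").
#' @param channel channel whose gate counts feed the ratio.
#' @param numerator,denominator character vectors of gate names; counts are
#'   summed within each side.
#' @export
ratio_definition <- function(name, channel, numerator, denominator) {
  structure(list(name = name, channel = channel, numerator = numerator,
                 denominator = denominator),
            class = "ratio_definition")
}

#' Default ratio set
#'
#' `NE2/NE4` is the evoked high-SSC/high-SFL neutrophil subpopulation over
#' the total neutrophil count (NE1+NE2+NE3+NE4); `RET1/RBC1` and `IPF/PLT`
#' are reticulocyte and immature-platelet fractions.
#' @export
default_ratios <- function() {
  list(
    ratio_definition("NE2/NE4", "WDF", "NE2", c("NE1", "NE2", "NE3", "NE4")),
    ratio_definition("RET1/RBC1", "RET", "RET1", "RBC1"),
    ratio_definition("IPF/PLT", "PLTF", "IPF", "PLT")
  )
}

#' Compute a count ratio
#'
#' Sum of numerator counts over sum of denominator counts; missing when the
#' denominator is zero.
#'
#' @param counts named numeric vector of gate counts.
#' @param numerator,denominator gate names (summed).
#' @export
derive_ratio <- function(counts, numerator, denominator) {
  missing_gates <- setdiff(c(numerator, denominator), names(counts))
  if (length(missing_gates))
    stop_config("unknown gate(s): %s", paste(missing_gates, collapse = ", "))
  den <- sum(counts[denominator])
  if (den == 0) return(NA_real_)
  sum(counts[numerator]) / den
}

STAT_NAMES <- c("Count", "Pct",
                "Med_FSC", "Med_SSC", "Med_SFL",
                "SD_FSC", "SD_SSC", "SD_SFL",
                "CV_FSC", "CV_SSC", "CV_SFL")

#' Featurize one donor x condition
#'
#' For every gate in the table's channel: event count, percentage of the
#' channel's total events, and the robust statistics (median, robust s.d.,
#' robust CV) on each optical axis; gates with fewer than `min_count`
#' members keep Count and Pct but report the distributional statistics as
#' missing. Configured ratios are appended. Parameter names follow
#' `<CHANNEL>_<Condition>_<Gate>_<Stat>` (ratios:
#' `<CHANNEL>_<Condition>_<RatioName>`).
#'
#' @param tables list of `event_table` for one donor and condition (one per
#'   channel; missing channels yield missing parameters downstream).
#' @param gates list of `gate_definition`.
#' @param ratios list of `ratio_definition`.
#' @param min_count reporting floor for distributional statistics.
#' @return long data.frame (donor, condition, parameter, value).
#' @export
featurize <- function(tables, gates, ratios = default_ratios(), min_count = 10L) {
  keys <- unique(vapply(tables, function(t) paste(t$donor, t$condition), ""))
  if (length(keys) != 1L)
    stop_config("featurize expects tables from a single donor x condition, got: %s",
                paste(keys, collapse = "; "))
  channels <- vapply(tables, `[[`, "", "channel")
  if (anyDuplicated(channels))
    stop_config("duplicate channel tables for %s", keys)
  donor <- tables[[1]]$donor
  condition <- tables[[1]]$condition

  rows <- list()
  for (tab in tables) {
    labels <- assign_gates(tab, gates)
    gate_names <- setdiff(levels(labels), "ungated")
    n_total <- nrow(tab$events)
    counts <- stats::setNames(
      as.numeric(table(factor(labels, levels = gate_names))), gate_names)
    for (g in gate_names) {
      member <- tab$events[labels == g, , drop = FALSE]
      cnt <- counts[[g]]
      vals <- c(Count = cnt,
                Pct = if (n_total > 0) 100 * cnt / n_total else NA_real_)
      vals[STAT_NAMES[-(1:2)]] <- NA_real_
      if (cnt >= min_count) {
        for (ax in c("FSC", "SSC", "SFL")) {
          st <- robust_stats(member[, ax])
          vals[paste0("Med_", ax)] <- st$median
          vals[paste0("SD_", ax)] <- st$robust_sd
          vals[paste0("CV_", ax)] <- st$robust_cv
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor = donor, condition = condition,
        parameter = paste(tab$channel, condition, g, names(vals), sep = "_"),
        value = unname(vals), stringsAsFactors = FALSE)
    }
    for (rd in ratios) {
      if (!identical(rd$channel, tab$channel)) next
      if (!all(c(rd$numerator, rd$denominator) %in% gate_names)) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor = donor, condition = condition,
        parameter = paste(tab$channel, condition, rd$name, sep = "_"),
        value = derive_ratio(counts, rd$numerator, rd$denominator),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Featurize a cohort into a wide phenotype matrix
#'
#' @param long data.frame rbind-ed from [featurize()] calls across donors
#'   and conditions.
#' @return numeric matrix donors x parameters (dimnames set), parameters in
#'   first-appearance order.
#' @export
phenotype_matrix <- function(long) {
  donors <- unique(long$donor)
  params <- unique(long$parameter)
  m <- matrix(NA_real_, length(donors), length(params),
              dimnames = list(donors, params))
  m[cbind(match(long$donor, donors), match(long$parameter, params))] <- long$value
  m
}
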