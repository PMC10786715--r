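# Shared helpers: deterministic seed derivation, TSV IO, small validators.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed and a stage tag
#'
#' A single pipeline seed fans out to per-stage (and per-donor) child seeds
#' through a Lehmer-style hash, so each stage's stream is reproducible
#' independently of the order in which stages run. All arithmetic stays below
#' 2^53 and the result is a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param tag character tag naming the consumer (e.g. "genotypes",
#'   "events/donor_007/baseline").
#' @return integer in `[1, 2147483646]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(tag))) h <- (h * 31 + c) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% (m - 1) + 1)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA", data.table = FALSE)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# two-sided p from t, floored to avoid underflow to 0 (observed scans reach
# p ~ 1e-100; the floor keeps -log10(p) finite)
P_FLOOR <- 1e-320

p_from_t <- function(t, df) {
  pmax(2 * stats::pt(-abs(t), df = df), P_FLOOR)
}

p_from_z <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), P_FLOOR)
}
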