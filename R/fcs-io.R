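# Minimal FCS 3.1 reader/writer (list mode, 32-bit floats, little-endian).
# Only the keywords needed for round-tripping three-parameter event tables
# are written; the reader checks them and refuses anything it cannot parse.

FCS_DELIM <- "/"

#' Write an event table to disk
#'
#' `format = "csv"` writes a plain header + FSC/SSC/SFL columns.
#' `format = "fcs"` writes a minimal FCS 3.1 file: list mode, `$DATATYPE F`
#' (IEEE 32-bit floats), byte order `1,2,3,4`.
#'
#' @param table an `event_table`.
#' @param path output path.
#' @param format "csv" or "fcs".
#' @export
write_events <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "event_table"))
  if (format == "csv") {
    data.table::fwrite(as.data.frame(table$events), path)
    return(invisible(path))
  }
  ev <- table$events
  n <- nrow(ev)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = "3",
    "$P1N" = "FSC", "$P2N" = "SSC", "$P3N" = "SFL",
    "$P1B" = "32", "$P2B" = "32", "$P3B" = "32",
    "$P1E" = "0,0", "$P2E" = "0,0", "$P3E" = "0,0",
    "$P1R" = "262144", "$P2R" = "262144", "$P3R" = "262144"
  )
  build_text <- function(kw) {
    paste0(FCS_DELIM,
           paste0(names(kw), FCS_DELIM, unname(kw), FCS_DELIM, collapse = ""))
  }
  # fixed-width offsets so the TEXT length is stable across the two passes
  fmt_off <- function(x) sprintf("%010d", x)
  kw["$BEGINDATA"] <- fmt_off(0)
  kw["$ENDDATA"] <- fmt_off(0)
  text_len <- nchar(build_text(kw), type = "bytes")
  header_len <- 58L
  data_begin <- header_len + text_len
  data_end <- data_begin + 4L * 3L * n - 1L
  kw["$BEGINDATA"] <- fmt_off(data_begin)
  kw["$ENDDATA"] <- fmt_off(data_end)
  text <- build_text(kw)
  stopifnot(nchar(text, type = "bytes") == text_len)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    header_len, header_len + text_len - 1L,
                    data_begin, data_end, 0L, 0L)
  stopifnot(nchar(header, type = "bytes") == header_len)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(ev)), con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs_events <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!startsWith(header, "FCS3"))
    stop_config("not an FCS 3.x file: %s", path)
  offs <- as.integer(substring(header, 10 + 8 * (0:5) + 1, 10 + 8 * (1:6)))
  text_begin <- offs[1]; text_end <- offs[2]
  data_begin <- offs[3]; data_end <- offs[4]
  if (any(is.na(c(text_begin, text_end, data_begin, data_end))) ||
      data_end >= sz || text_end >= sz)
    stop_config("truncated FCS file: %s", path)
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substring(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  if (!identical(kw[["$DATATYPE"]], "F") || !identical(kw[["$MODE"]], "L"))
    stop_config("unsupported FCS layout (need list mode, float data)")
  if (!identical(kw[["$BYTEORD"]], "1,2,3,4"))
    stop_config("unsupported FCS byte order %s", kw[["$BYTEORD"]])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  names_par <- vapply(seq_len(n_par), function(i) kw[[sprintf("$P%dN", i)]],
                      character(1))
  seek(con, data_begin)
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4L,
                  endian = "little")
  if (length(vals) < n_par * n_tot)
    stop_config("truncated FCS data segment: %s", path)
  m <- matrix(vals, ncol = n_par, byrow = TRUE)
  colnames(m) <- names_par
  m
}

#' Read an event table from CSV or FCS
#'
#' @param path file path.
#' @param format "auto" (by extension), "csv" or "fcs".
#' @param donor,condition,channel identifiers attached to the table; when
#'   `NULL` they are parsed from a `<donor>_<condition>_<channel>` filename.
#' @param channel_map optional named vector renaming file columns to
#'   FSC/SSC/SFL.
#' @return an `event_table`.
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        donor = NULL, condition = NULL, channel = NULL,
                        channel_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("no such file: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (is.null(donor) || is.null(condition) || is.null(channel)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    bits <- strsplit(stem, "_")[[1]]
    if (length(bits) >= 3) {
      if (is.null(channel)) channel <- bits[length(bits)]
      if (is.null(donor)) donor <- paste(bits[1:2], collapse = "_")
      if (is.null(condition))
        condition <- paste(bits[3:(length(bits) - 1)], collapse = "_")
    }
  }
  m <- if (format == "csv") {
    d <- data.table::fread(path, data.table = FALSE)
    as.matrix(d)
  } else {
    read_fcs_events(path)
  }
  if (!is.null(channel_map)) {
    hit <- match(colnames(m), names(channel_map))
    colnames(m)[!is.na(hit)] <- channel_map[hit[!is.na(hit)]]
  }
  want <- c("FSC", "SSC", "SFL")
  if (!all(want %in% colnames(m)))
    stop_config("cannot resolve channels FSC/SSC/SFL; file has: %s",
                paste(colnames(m), collapse = ", "))
  m <- m[, want, drop = FALSE]
  if (!nrow(m)) m <- matrix(numeric(0), 0, 3, dimnames = list(NULL, want))
  new_event_table(donor %||% "unknown", condition %||% "unknown",
                  channel %||% "unknown", m)
}
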