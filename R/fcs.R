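# Minimal FCS support. Covers list-mode files (the overwhelmingly common
# case): FCS 2.0/3.0/3.1, $MODE L, $DATATYPE F/D/I, little- or big-endian.
# CSV is the package's canonical interchange format; FCS reading is
# best-effort over these dialects and FCS writing exists to produce
# round-trip fixtures.

fcs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fcs_error")))
}

parse_fcs_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substr(txt, 2L, nchar(txt)), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1L, length(parts), by = 2L)]
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(trimws(vals)), toupper(trimws(keys)))
}

#' Read an FCS file
#'
#' Parses FCS 2.0/3.0/3.1 list-mode files and returns all events with the
#' channel names from the `$PnN` keywords, in file order and untransformed.
#'
#' @param path path to the FCS file.
#' @param sample_id sample identifier; defaults to the file name.
#' @param subject_id optional subject identifier.
#' @return A [flow_sample].
#' @section Errors: distinct condition classes are signalled for a missing
#'   file (`fcs_file_missing`), an unparsable header (`fcs_header_error`),
#'   a truncated or inconsistent data segment (`fcs_truncated`) and a file
#'   with zero events (`fcs_empty`).
#' @export
read_fcs <- function(path, sample_id = basename(path), subject_id = NULL) {
  if (!file.exists(path)) {
    fcs_error(sprintf("FCS file not found: %s", path), "fcs_file_missing")
  }
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 58L) {
    fcs_error(sprintf("file too short to hold an FCS header: %s", path),
              "fcs_header_error")
  }
  version <- rawToChar(bytes[1:6])
  if (!startsWith(version, "FCS")) {
    fcs_error(sprintf("not an FCS file (header '%s'): %s", version, path),
              "fcs_header_error")
  }
  offs <- suppressWarnings(as.integer(vapply(0:3, function(i) {
    rawToChar(bytes[(11L + 8L * i):(18L + 8L * i)])
  }, character(1))))
  if (anyNA(offs[1:2]) || offs[1] <= 0L || offs[2] <= offs[1]) {
    fcs_error(sprintf("unparsable FCS header offsets: %s", path),
              "fcs_header_error")
  }
  kw <- parse_fcs_text(bytes[(offs[1] + 1L):min(offs[2] + 1L, length(bytes))])

  tot <- as.integer(kw[["$TOT"]])
  par <- as.integer(kw[["$PAR"]])
  if (is.na(par) || par < 1L) {
    fcs_error(sprintf("missing or invalid $PAR keyword: %s", path),
              "fcs_header_error")
  }
  if (is.na(tot) || tot == 0L) {
    fcs_error(sprintf("FCS file has zero events: %s", path), "fcs_empty")
  }
  mode <- toupper(kw[["$MODE"]] %||% "L")
  if (mode != "L") {
    fcs_error(sprintf("unsupported $MODE '%s' (only list mode): %s",
                      mode, path), "fcs_header_error")
  }
  dbeg <- offs[3]; dend <- offs[4]
  if (is.na(dbeg) || dbeg <= 0L) dbeg <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(dend) || dend <= 0L) dend <- as.integer(kw[["$ENDDATA"]])
  if (is.na(dbeg) || is.na(dend) || dbeg <= 0L || dend < dbeg) {
    fcs_error(sprintf("unparsable data segment offsets: %s", path),
              "fcs_header_error")
  }

  dtype <- toupper(kw[["$DATATYPE"]] %||% "F")
  bits <- suppressWarnings(as.integer(kw[["$P1B"]] %||% "32"))
  size <- switch(dtype,
                 F = 4L, D = 8L,
                 I = max(1L, bits %/% 8L),
                 fcs_error(sprintf("unsupported $DATATYPE '%s': %s",
                                   dtype, path), "fcs_header_error"))
  byteord <- kw[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  nvals <- tot * par
  avail <- min(dend, length(bytes) - 1L) - dbeg + 1L
  if (avail < nvals * size) {
    fcs_error(sprintf(
      "truncated data segment: need %d bytes, found %d: %s",
      nvals * size, max(avail, 0L), path), "fcs_truncated")
  }
  seg <- bytes[(dbeg + 1L):(dbeg + nvals * size)]
  what <- if (dtype == "I") "integer" else "double"
  vals <- readBin(seg, what = what, n = nvals, size = size, endian = endian,
                  signed = TRUE)
  mat <- matrix(as.numeric(vals), nrow = tot, ncol = par, byrow = TRUE)

  nm <- vapply(seq_len(par), function(j) {
    kw[[sprintf("$P%dN", j)]] %||% kw[[sprintf("$P%dS", j)]] %||%
      sprintf("P%d", j)
  }, character(1))
  flow_sample(mat, marker_names = nm, sample_id = sample_id,
              subject_id = subject_id)
}

#' Write a flow sample as an FCS 3.0 file
#'
#' Emits a single-dataset list-mode FCS 3.0 file with 32-bit float data,
#' little-endian byte order and the sample's marker names as `$PnN`.
#' Intended for fixtures and interoperability checks, not as a general
#' FCS exporter.
#'
#' @param sample a [flow_sample].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(sample, path) {
  stopifnot(inherits(sample, "flow_sample"))
  x <- sample$values
  n <- nrow(x); m <- ncol(x)
  d <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0", "$NEXTDATA", "0",
          "$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(m), "$TOT", as.character(n),
          "$BEGINDATA", "%BEGIN%%", "$ENDDATA", "%%END%%%")
  for (j in seq_len(m)) {
    kv <- c(kv, sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dN", j), sample$marker_names[j],
            sprintf("$P%dR", j),
            as.character(max(1024, 2^ceiling(log2(max(abs(x[, j]), 1) + 1)))))
  }
  # fixed-width data offsets so TEXT length does not depend on their values
  text_body <- paste0(d, paste(kv, collapse = d), d)
  text_begin <- 58L
  text_end <- text_begin + nchar(text_body) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * m - 1L
  text_body <- sub("%BEGIN%%", formatC(data_begin, width = 8, flag = "0"),
                   text_body, fixed = TRUE)
  text_body <- sub("%%END%%%", formatC(data_end, width = 8, flag = "0"),
                   text_body, fixed = TRUE)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_body, con, eos = NULL)
  writeBin(as.vector(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
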