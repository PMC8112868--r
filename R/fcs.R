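#' Read an FCS 3.0/3.1 file
#'
#' Minimal, dependency-free reader for pre-gated list-mode cytometry exports.
#' Supports `$DATATYPE` F (float32), D (float64) and I with uniform
#' `$PnB` of 16 or 32 bits (promoted to double), both byte orders, single
#' dataset only. `$PnE` log-amplification keywords are deliberately ignored
#' (values are returned exactly as stored): all supported inputs are
#' pre-scaled cytometer exports.
#'
#' @param path path to the FCS file.
#' @return a `RawSample`: list with `data` (events x parameters matrix),
#'   `channel_ids` (`$PnN`), `channel_labels` (`$PnS`, defaulting to `$PnN`),
#'   `keywords` (named character) and `source_path`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) {
    cs_stop(sprintf("FCS file not found: %s", path), "io_error")
  }
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    cs_stop(sprintf("unsupported FCS version '%s' (need FCS3.0/3.1)", version),
            "format_error")
  }
  off <- function(i) {
    s <- substr(header, 11 + (i - 1) * 8, 10 + i * 8)
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) 0 else v
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)

  seek(con, text_start)
  text_raw <- readBin(con, "raw", n = text_end - text_start + 1)
  kw <- parse_fcs_text(rawToChar(text_raw))

  get_kw <- function(key, required = TRUE) {
    v <- kw[[key]]
    if (is.null(v) && required) {
      cs_stop(sprintf("required FCS keyword %s missing", key), "format_error")
    }
    v
  }
  mode <- get_kw("$MODE")
  if (toupper(mode) != "L") {
    cs_stop(sprintf("unsupported $MODE '%s': only list mode (L) is supported",
                    mode), "format_error")
  }
  nextdata <- get_kw("$NEXTDATA", required = FALSE)
  if (!is.null(nextdata) && as.numeric(nextdata) != 0) {
    cs_stop(paste0("multi-dataset FCS files are not supported ($NEXTDATA != 0);",
                   " export each dataset to its own file"), "format_error")
  }
  dtype <- toupper(get_kw("$DATATYPE"))
  if (!dtype %in% c("F", "D", "I")) {
    cs_stop(sprintf("unsupported $DATATYPE '%s' (supported: F, D, I)", dtype),
            "format_error")
  }
  byteord <- get_kw("$BYTEORD")
  endian <- if (grepl("^1", byteord)) "little" else "big"
  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))

  pnb <- vapply(seq_len(n_par), function(i) {
    as.integer(get_kw(sprintf("$P%dB", i)))
  }, 1L)
  if (dtype == "F" && any(pnb != 32L)) {
    cs_stop("$DATATYPE F requires $PnB = 32 for all parameters", "format_error")
  }
  if (dtype == "D" && any(pnb != 64L)) {
    cs_stop("$DATATYPE D requires $PnB = 64 for all parameters", "format_error")
  }
  if (dtype == "I") {
    if (length(unique(pnb)) != 1L || !pnb[1] %in% c(16L, 32L)) {
      cs_stop(paste0("$DATATYPE I supported only with uniform $PnB of 16 or 32",
                     sprintf(" (got: %s)", paste(unique(pnb), collapse = ","))),
              "format_error")
    }
  }
  if (data_start == 0) {
    data_start <- as.numeric(get_kw("$BEGINDATA"))
    data_end <- as.numeric(get_kw("$ENDDATA"))
  }
  n_values <- n_par * n_tot
  bytes_per <- pnb[1] / 8
  need <- n_values * bytes_per
  if (data_start + need - 1 > sz) {
    cs_stop("truncated DATA segment: file shorter than $PAR * $TOT values",
            "io_error")
  }
  seek(con, data_start)
  values <- switch(dtype,
    F = readBin(con, "numeric", n = n_values, size = 4, endian = endian),
    D = readBin(con, "numeric", n = n_values, size = 8, endian = endian),
    I = {
      if (pnb[1] == 16L) {
        as.numeric(readBin(con, "integer", n = n_values, size = 2,
                           signed = FALSE, endian = endian))
      } else {
        v <- as.numeric(readBin(con, "integer", n = n_values, size = 4,
                                endian = endian))
        ifelse(v < 0, v + 2^32, v)  # recover unsigned 32-bit
      }
    })
  if (length(values) < n_values) {
    cs_stop("truncated DATA segment: fewer values than $PAR * $TOT", "io_error")
  }
  data <- matrix(values, nrow = n_tot, ncol = n_par, byrow = TRUE)
  channel_ids <- vapply(seq_len(n_par), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) sprintf("P%d", i) else v
  }, "")
  channel_labels <- vapply(seq_len(n_par), function(i) {
    v <- kw[[sprintf("$P%dS", i)]]
    if (is.null(v)) channel_ids[i] else v
  }, "")
  colnames(data) <- channel_ids
  structure(list(data = data, channel_ids = channel_ids,
                 channel_labels = channel_labels,
                 keywords = kw, source_path = path),
            class = "RawSample")
}

# parse a delimited FCS TEXT segment into a named list; doubled delimiters
# inside values are the FCS escape for a literal delimiter character
parse_fcs_text <- function(txt) {
  delim <- substr(txt, 1, 1)
  body <- substring(txt, 2)
  if (endsWith(body, delim)) body <- substr(body, 1, nchar(body) - 1)
  toks <- strsplit(body, delim, fixed = TRUE)[[1]]
  # merge empty tokens back as escaped delimiters
  merged <- character(0)
  i <- 1
  while (i <= length(toks)) {
    cur <- toks[i]
    while (i + 1 <= length(toks) && toks[i + 1] == "" && i + 2 <= length(toks)) {
      cur <- paste0(cur, delim, toks[i + 2])
      i <- i + 2
    }
    merged <- c(merged, cur)
    i <- i + 1
  }
  if (length(merged) %% 2 != 0) {
    cs_stop("malformed FCS TEXT segment: odd number of tokens", "format_error")
  }
  keys <- merged[seq(1, length(merged), by = 2)]
  vals <- merged[seq(2, length(merged), by = 2)]
  setNames(as.list(vals), toupper(trimws(keys)))
}

#' Write an FCS 3.1 file
#'
#' Writes a single-dataset, list-mode FCS 3.1 file with `$DATATYPE` F
#' (little-endian float32). Round-trips through [read_fcs()] exactly in shape
#' and to float32 precision in values.
#'
#' @param data numeric events x parameters matrix (finite values only).
#' @param channel_ids `$PnN` values, one per column; defaults to column names.
#' @param channel_labels `$PnS` values; defaults to `channel_ids`.
#' @param path output path.
#' @param extra_keywords optional named character vector merged into TEXT.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(data, channel_ids = colnames(data),
                      channel_labels = channel_ids, path,
                      extra_keywords = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) {
    cs_stop("write_fcs requires at least one event", "value_error")
  }
  if (!all(is.finite(data))) {
    cs_stop("write_fcs refuses non-finite values (NaN/Inf present)",
            "value_error")
  }
  p <- ncol(data)
  if (is.null(channel_ids)) channel_ids <- sprintf("P%d", seq_len(p))
  if (is.null(channel_labels)) channel_labels <- channel_ids
  delim <- "/"
  sane <- function(x) gsub(delim, "_", as.character(x), fixed = TRUE)
  channel_ids <- sane(channel_ids)
  channel_labels <- sane(channel_labels)

  kw <- c(
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(nrow(data)),
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf("%010d", 0), "$ENDDATA" = sprintf("%010d", 0)
  )
  for (i in seq_len(p)) {
    rng <- max(data[, i])
    kw[sprintf("$P%dN", i)] <- channel_ids[i]
    kw[sprintf("$P%dS", i)] <- channel_labels[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- sprintf("%.0f", ceiling(max(rng, 1)) + 1)
  }
  if (!is.null(extra_keywords)) kw[names(extra_keywords)] <- sane(extra_keywords)

  render_text <- function(kw) {
    paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }
  text <- render_text(kw)
  text_start <- 58L
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * length(data) - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_start)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- render_text(kw)  # placeholders were fixed-width: length unchanged

  hdr_num <- function(x) {
    if (x <= 99999999) sprintf("%8d", x) else sprintf("%8d", 0L)
  }
  header <- paste0("FCS3.1    ",
                   hdr_num(text_start), hdr_num(text_end),
                   hdr_num(data_start), hdr_num(data_end),
                   hdr_num(0L), hdr_num(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(data)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an IMC segmented-cell intensity table (CSV)
#'
#' One row per segmented cell, header row of channel names. Non-marker
#' columns (cell id, centroid coordinates, region/ROI labels and any
#' non-numeric column) are split into a cell-metadata side table.
#'
#' @param path CSV path.
#' @param meta_cols optional character vector of column names to treat as
#'   metadata in addition to the auto-detected ones.
#' @return a `RawSample` whose `data` holds the numeric marker matrix; the
#'   side table is attached as `cell_meta`.
#' @export
read_cell_table <- function(path, meta_cols = NULL) {
  if (!file.exists(path)) {
    cs_stop(sprintf("cell table not found: %s", path), "io_error")
  }
  df <- tryCatch(
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      cs_stop(sprintf("parse error reading cell table %s: %s",
                      path, conditionMessage(e)), "parse_error")
    })
  if (nrow(df) == 0L || ncol(df) == 0L) {
    cs_stop(sprintf("parse error: cell table %s is empty", path), "parse_error")
  }
  default_meta <- c("cellid", "cell_id", "id", "objectnumber", "object_id",
                    "x", "y", "x_position", "y_position", "centroid_x",
                    "centroid_y", "region", "roi", "area", "label")
  is_meta <- tolower(names(df)) %in% default_meta |
    names(df) %in% (meta_cols %||% character(0))
  marker_cols <- names(df)[!is_meta]
  for (cn in marker_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        cs_stop(sprintf(
          "parse error: non-numeric marker value at row %d, column '%s'",
          bad[1], cn), "parse_error")
      }
      df[[cn]] <- num
    }
  }
  data <- as.matrix(df[, marker_cols, drop = FALSE])
  meta <- df[, is_meta, drop = FALSE]
  structure(list(data = data, channel_ids = marker_cols,
                 channel_labels = marker_cols, keywords = list(),
                 cell_meta = meta, source_path = path),
            class = "RawSample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
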