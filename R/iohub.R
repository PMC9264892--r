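#' Read a spectral cohort from a wide CSV file
#'
#' The wide layout is one row per spectrum: metadata columns first
#' (`patient_id`, `class`, `bio_rep`, `tech_rep`), then one numeric column
#' per wavenumber with the wavenumber (cm^-1) as header. Column order in the
#' file is irrelevant; the axis is re-sorted high-to-low on ingest.
#'
#' @param path path to the CSV file.
#' @param meta_columns character vector of metadata column names expected in
#'   the file.
#' @return a [spectral_dataset()].
#' @export
read_wide_csv <- function(path,
                          meta_columns = c("patient_id", "class",
                                           "bio_rep", "tech_rep")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  miss <- setdiff(meta_columns, names(dt))
  if (length(miss))
    stop("format error: missing metadata column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  spec_cols <- setdiff(names(dt), meta_columns)
  wn <- suppressWarnings(as.numeric(spec_cols))
  if (anyNA(wn))
    stop("format error: non-numeric wavenumber header(s): ",
         paste(utils::head(spec_cols[is.na(wn)], 3L), collapse = ", "),
         call. = FALSE)
  for (j in spec_cols) {
    v <- dt[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv))
        stop("parse error: non-numeric intensity in column '", j,
             "', row ", which(is.na(conv))[1L], call. = FALSE)
      dt[[j]] <- conv
    }
  }
  ord <- order(wn, decreasing = TRUE)
  mat <- as.matrix(dt[, spec_cols[ord], drop = FALSE])
  spectral_dataset(mat, wn[ord], dt[, meta_columns, drop = FALSE])
}

#' Write a spectral cohort to a wide CSV file
#'
#' Deterministic column order: metadata first, then wavenumbers high-to-low.
#' Round-trips with [read_wide_csv()] to within write precision (about
#' 1e-15 relative on intensities).
#'
#' @param ds a [spectral_dataset()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_wide_csv <- function(ds, path) {
  validate_dataset(ds)
  out <- cbind(ds$meta,
               as.data.frame(ds$matrix, optional = TRUE))
  names(out) <- c(names(ds$meta), format_wavenumber(ds$axis))
  ok <- tryCatch({
    data.table::fwrite(out, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error writing '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

# deterministic, full-precision header formatting
format_wavenumber <- function(x) formatC(x, format = "g", digits = 12)

#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal reader for JCAMP-DX 4.24, the standard infrared exchange format:
#' `##XYDATA=(X++(Y..Y))` blocks in AFFN or ASDF-compressed (SQZ/DIF/DUP)
#' form, and `##XYPOINTS=(XY..XY)` blocks. `##XFACTOR`/`##YFACTOR` scaling
#' and the `##NPOINTS` count are honoured; in DIF form the per-line ordinate
#' check value is verified and dropped.
#'
#' @param path path to a JCAMP-DX file.
#' @return an object of class `spectrum`: list with `wavenumbers` (strictly
#'   decreasing, cm^-1), `intensities`, `title`, and empty cohort metadata
#'   fields (`patient_id`, `class`, `bio_rep`, `tech_rep`).
#' @export
read_jcampdx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^##[^=]*=", "", lines[hit[1L]]))
  }
  title <- ldr("TITLE")
  xfac <- suppressWarnings(as.numeric(ldr("XFACTOR")))
  yfac <- suppressWarnings(as.numeric(ldr("YFACTOR")))
  if (is.na(xfac)) xfac <- 1
  if (is.na(yfac)) yfac <- 1
  npoints <- suppressWarnings(as.numeric(ldr("NPOINTS")))

  start <- grep("^##(XYDATA|XYPOINTS)\\s*=", lines, ignore.case = TRUE)
  if (!length(start))
    stop("format error: no ##XYDATA or ##XYPOINTS block in '", path, "'",
         call. = FALSE)
  start <- start[1L]
  is_xy_pairs <- grepl("^##XYPOINTS", lines[start], ignore.case = TRUE)
  body_end <- start
  while (body_end < length(lines) && !grepl("^##", lines[body_end + 1L]))
    body_end <- body_end + 1L
  body <- lines[seq(start + 1L, body_end)]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    stop("format error: empty data block in '", path, "'", call. = FALSE)

  if (is_xy_pairs) {
    toks <- unlist(strsplit(paste(body, collapse = " "), "[,;[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- as.numeric(toks)
    if (anyNA(vals) || length(vals) %% 2L != 0L)
      stop("format error: malformed XYPOINTS block", call. = FALSE)
    x <- vals[seq(1L, length(vals), 2L)] * xfac
    y <- vals[seq(2L, length(vals), 2L)] * yfac
  } else {
    firstx <- suppressWarnings(as.numeric(ldr("FIRSTX")))
    lastx <- suppressWarnings(as.numeric(ldr("LASTX")))
    deltax <- suppressWarnings(as.numeric(ldr("DELTAX")))
    parsed <- parse_asdf_block(body)
    y <- parsed$y * yfac
    n <- length(y)
    if (!is.na(firstx) && !is.na(lastx) && n > 1L) {
      x <- seq(firstx, lastx, length.out = n)
    } else if (!is.na(deltax)) {
      x0 <- if (!is.na(firstx)) firstx else parsed$anchor_x[1L] * xfac
      x <- x0 + deltax * (seq_len(n) - 1L)
    } else {
      x <- anchor_interpolate(parsed$anchor_pos, parsed$anchor_x * xfac, n)
    }
  }
  if (!is.na(npoints) && length(y) != npoints)
    stop("integrity error: NPOINTS = ", npoints, " but ", length(y),
         " ordinates decoded", call. = FALSE)
  ord <- order(x, decreasing = TRUE)
  structure(list(wavenumbers = x[ord], intensities = y[ord],
                 title = if (is.na(title)) "" else title,
                 patient_id = "", class = "", bio_rep = NA_integer_,
                 tech_rep = NA_integer_),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f -> %.1f cm-1%s\n",
              length(x$wavenumbers), max(x$wavenumbers),
              min(x$wavenumbers),
              if (nzchar(x$title)) paste0(" | ", x$title) else ""))
  invisible(x)
}

# --- ASDF (X++(Y..Y)) decoding -------------------------------------------
# SQZ digits replace the leading digit of an ordinate, DIF digits encode a
# difference from the previous ordinate, DUP digits repeat the previous
# ordinate or difference. In DIF mode the first ordinate of a continuation
# line is a check value and is dropped.

.sqz <- c("@" = 0, A = 1, B = 2, C = 3, D = 4, E = 5, F = 6, G = 7, H = 8,
          I = 9, a = -1, b = -2, c = -3, d = -4, e = -5, f = -6, g = -7,
          h = -8, i = -9)
.dif <- c("%" = 0, J = 1, K = 2, L = 3, M = 4, N = 5, O = 6, P = 7, Q = 8,
          R = 9, j = -1, k = -2, l = -3, m = -4, n = -5, o = -6, p = -7,
          q = -8, r = -9)
.dup <- c(S = 1, T = 2, U = 3, V = 4, W = 5, X = 6, Y = 7, Z = 8, s = 9)

parse_asdf_block <- function(body) {
  ys <- numeric(0)
  anchor_pos <- integer(0)  # index into ys of the point whose abscissa
  anchor_x <- numeric(0)    # is printed at the start of each line
  prev_line_dif <- FALSE
  for (line in body) {
    toks <- tokenize_asdf(line)
    if (!length(toks$value))
      stop("format error: undecodable data line: ", line, call. = FALSE)
    x0 <- toks$value[1L]
    if (toks$mode[1L] != "affn")
      stop("format error: line must start with an AFFN abscissa: ", line,
           call. = FALSE)
    yline <- numeric(0)
    last_was_dif <- FALSE
    last_dif <- 0
    for (i in seq_along(toks$value)[-1L]) {
      v <- toks$value[i]
      mode <- toks$mode[i]
      if (mode == "dup") {
        if (!length(yline) && !length(ys))
          stop("format error: DUP with no preceding ordinate", call. = FALSE)
        for (rep in seq_len(v - 1L)) {
          if (last_was_dif) {
            yline <- c(yline, yline[length(yline)] + last_dif)
          } else {
            yline <- c(yline, yline[length(yline)])
          }
        }
      } else if (mode == "dif") {
        base <- if (length(yline)) yline[length(yline)] else ys[length(ys)]
        yline <- c(yline, base + v)
        last_was_dif <- TRUE
        last_dif <- v
      } else { # affn or sqz: absolute ordinate
        yline <- c(yline, v)
        last_was_dif <- FALSE
      }
    }
    if (prev_line_dif && length(ys)) {
      # first ordinate duplicates the previous line's last (Y-check value)
      if (length(yline) && abs(yline[1L] - ys[length(ys)]) > 1e-8 *
            max(1, abs(ys[length(ys)])))
        stop("integrity error: DIF check value mismatch at x = ", x0,
             call. = FALSE)
      yline <- yline[-1L]
      anchor_pos <- c(anchor_pos, length(ys))
    } else {
      anchor_pos <- c(anchor_pos, length(ys) + 1L)
    }
    anchor_x <- c(anchor_x, x0)
    ys <- c(ys, yline)
    prev_line_dif <- last_was_dif
  }
  list(y = ys, anchor_pos = anchor_pos, anchor_x = anchor_x)
}

# uniform abscissa grid inferred from per-line anchors
anchor_interpolate <- function(pos, x, n) {
  if (n == 1L) return(x[1L])
  keep <- !duplicated(pos)
  pos <- pos[keep]; x <- x[keep]
  if (length(pos) < 2L)
    stop("format error: cannot infer abscissa spacing (single data line ",
         "without FIRSTX/LASTX or DELTAX)", call. = FALSE)
  step <- (x[length(x)] - x[1L]) / (pos[length(pos)] - pos[1L])
  x[1L] + step * (seq_len(n) - pos[1L])
}

tokenize_asdf <- function(line) {
  line <- trimws(sub("\\$\\$.*$", "", line))
  chars <- strsplit(line, "")[[1L]]
  values <- numeric(0)
  modes <- character(0)
  buf <- ""
  buf_mode <- NA_character_
  buf_sign <- 1
  flush <- function() {
    if (is.na(buf_mode)) return()
    num <- if (nzchar(buf)) as.numeric(buf) else 0
    if (is.na(num)) stop("format error: bad numeral '", buf, "'",
                         call. = FALSE)
    values <<- c(values, buf_sign * num)
    modes <<- c(modes, buf_mode)
    buf <<- ""; buf_mode <<- NA_character_; buf_sign <<- 1
  }
  for (ch in chars) {
    if (grepl("[0-9.]", ch)) {
      if (is.na(buf_mode)) { buf_mode <- "affn"; buf <- ch }
      else buf <- paste0(buf, ch)
    } else if (ch %in% c("+", "-")) {
      flush()
      buf_mode <- "affn"; buf <- ""; buf_sign <- if (ch == "-") -1 else 1
    } else if (ch %in% names(.sqz)) {
      flush()
      d <- .sqz[[ch]]
      buf_mode <- "sqz"; buf_sign <- if (d < 0) -1 else 1
      buf <- as.character(abs(d))
    } else if (ch %in% names(.dif)) {
      flush()
      d <- .dif[[ch]]
      buf_mode <- "dif"; buf_sign <- if (d < 0) -1 else 1
      buf <- as.character(abs(d))
    } else if (ch %in% names(.dup)) {
      flush()
      buf_mode <- "dup"; buf <- as.character(.dup[[ch]])
    } else if (grepl("[[:space:],;]", ch)) {
      flush()
    } else if (ch == "?") {
      flush() # missing value marker: skipped
    } else {
      stop("format error: unexpected character '", ch, "' in data line",
           call. = FALSE)
    }
  }
  flush()
  list(value = values, mode = modes)
}
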