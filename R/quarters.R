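#' Calendar-quarter utilities
#'
#' Receipt quarters are represented throughout the package as strings of the
#' form `"2019Q2"`. These helpers parse, format and order them; extraction
#' windows (see [drug_query()]) are inclusive quarter ranges.
#'
#' @param x Character vector of quarter labels (`"YYYYQn"`, n in 1..4).
#' @return `quarter_index()` returns an integer vector that orders quarters
#'   chronologically (year * 4 + quarter - 1); `quarter_label()` inverts it.
#' @examples
#' quarter_index("2019Q2") < quarter_index("2025Q1")
#' quarter_label(quarter_index("2019Q2") + 1) # "2019Q3"
#' @export
quarter_index <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})Q([1-4])$", as.character(x)))
  bad <- lengths(m) != 3L & !is.na(x)
  if (any(bad)) {
    stop("malformed quarter label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected 'YYYYQn')", call. = FALSE)
  }
  vapply(m, function(g) {
    if (length(g) != 3L) return(NA_integer_)
    as.integer(g[2L]) * 4L + as.integer(g[3L]) - 1L
  }, integer(1))
}

#' @rdname quarter_index
#' @export
quarter_label <- function(x) {
  x <- as.integer(x)
  ifelse(is.na(x), NA_character_, sprintf("%04dQ%d", x %/% 4L, x %% 4L + 1L))
}

#' @rdname quarter_index
#' @param from,to Quarter labels bounding an inclusive sequence.
#' @export
quarter_seq <- function(from, to) {
  i <- quarter_index(from)
  j <- quarter_index(to)
  if (i > j) stop("quarter range start ", from, " is after end ", to, call. = FALSE)
  quarter_label(seq.int(i, j))
}

# Derive the quarter label from a FAERS receipt date (YYYYMMDD); NA when the
# date is missing or unparseable.
quarter_from_date <- function(dt) {
  dt <- as.character(dt)
  ok <- !is.na(dt) & grepl("^[0-9]{8}$", dt)
  out <- rep(NA_character_, length(dt))
  yr <- as.integer(substr(dt[ok], 1L, 4L))
  mo <- as.integer(substr(dt[ok], 5L, 6L))
  valid <- mo >= 1L & mo <= 12L
  out[ok][valid] <- sprintf("%04dQ%d", yr[valid], (mo[valid] - 1L) %/% 3L + 1L)
  out
}

# First day of a quarter as a FAERS-style YYYYMMDD string (used by the writer).
date_from_quarter <- function(q) {
  idx <- quarter_index(q)
  ifelse(is.na(idx), "",
         sprintf("%04d%02d01", idx %/% 4L, (idx %% 4L) * 3L + 1L))
}
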