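# FAERS date handling. Dates travel as YYYYMMDD integers; numeric order is
# calendar order, so comparisons never need Date objects. Partial dates
# (YYYY or YYYYMM) are padded to the first day/month and flagged via a
# precision string so they can be written back at their original precision.

# Parse a character vector of FAERS date fields.
# Returns list(date = integer YYYYMMDD (padded), prec = character in
# {"day","month","year","missing"}, bad = logical, TRUE where a non-empty
# field failed to parse).
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  date <- rep(NA_integer_, n)
  prec <- rep("missing", n)
  bad <- rep(FALSE, n)

  empty <- is.na(x) | x == ""
  digits <- !empty & grepl("^[0-9]+$", x)
  nc <- nchar(x)

  padded <- rep(NA_character_, n)
  i <- digits & nc == 4
  padded[i] <- paste0(x[i], "0101"); prec[i] <- "year"
  i <- digits & nc == 6
  padded[i] <- paste0(x[i], "01"); prec[i] <- "month"
  i <- digits & nc == 8
  padded[i] <- x[i]; prec[i] <- "day"

  ok <- !is.na(padded)
  if (any(ok)) {
    d <- as.Date(padded[ok], format = "%Y%m%d")
    valid <- !is.na(d)
    date[ok][valid] <- as.integer(padded[ok][valid])
    # calendar-invalid (e.g. 20200230): treat as missing, count as bad
    prec[ok][!valid] <- "missing"
    bad[ok][!valid] <- TRUE
  }
  bad[!empty & !ok] <- TRUE
  list(date = date, prec = prec, bad = bad)
}

# Render (date, prec) back to the FAERS field at its original precision.
format_faers_date <- function(date, prec) {
  s <- ifelse(is.na(date), "", sprintf("%08d", date))
  s[prec == "month"] <- substr(s[prec == "month"], 1L, 6L)
  s[prec == "year"] <- substr(s[prec == "year"], 1L, 4L)
  s[prec == "missing"] <- ""
  s
}
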