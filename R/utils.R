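
# Shared column-checking and small helpers.

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Certification status as an ordered-by-convention factor; non-FSC is the
# reference level so the status coefficient is the FSC effect.
status_factor <- function(certified) {
  factor(ifelse(certified, "FSC", "non-FSC"), levels = c("non-FSC", "FSC"))
}

as_posixct_utc <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  out <- tryCatch(
    suppressWarnings(as.POSIXct(x, tz = "UTC")),
    error = function(e) rep(as.POSIXct(NA), length(x))
  )
  if (anyNA(out) && !all(is.na(x))) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    abort(sprintf(
      "unparseable %s value(s): %s",
      what, paste(head(bad, 5), collapse = ", ")
    ))
  }
  out
}

# Stable config fingerprint used in reproducibility headers (no external
# digest dependency: md5 of the serialized object via a temp file).
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

# days between two POSIXct as numeric
days_between <- function(start, end) {
  as.numeric(difftime(end, start, units = "days"))
}
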