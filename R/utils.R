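# internal validation helpers -------------------------------------------

# stop with a message naming the offending field
check_range <- function(x, field, min = -Inf, max = Inf,
                        allow_equal = TRUE) {
  bad <- if (allow_equal) x < min | x > max else x <= min | x >= max
  if (any(bad & !is.na(x))) {
    abort(sprintf("`%s` out of range [%s, %s]: %s",
                  field, format(min), format(max),
                  paste(format(x[bad & !is.na(x)]), collapse = ", ")),
          class = "nitrosponge_validation_error")
  }
  invisible(x)
}

check_positive <- function(x, field, strict = TRUE) {
  bad <- if (strict) !is.na(x) & x <= 0 else !is.na(x) & x < 0
  if (any(bad)) {
    abort(sprintf("`%s` must be %s, got %s", field,
                  if (strict) "> 0" else ">= 0",
                  paste(format(x[bad]), collapse = ", ")),
          class = "nitrosponge_validation_error")
  }
  invisible(x)
}

check_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "nitrosponge_validation_error")
  }
  invisible(data)
}

# collapse a character vector of flags to a single ";"-separated string
flag_string <- function(...) {
  flags <- c(...)
  flags <- flags[nzchar(flags)]
  if (!length(flags)) "" else paste(unique(flags), collapse = ";")
}
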