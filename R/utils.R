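# internal helpers: argument checking and classed errors -----------------

stop_invalid <- function(msg) {
  abort(msg, class = "cyc_invalid_parameter")
}

stop_record <- function(msg) {
  abort(msg, class = "cyc_invalid_record")
}

stop_format <- function(msg) {
  abort(msg, class = "cyc_format_error")
}

stop_layout <- function(msg) {
  abort(msg, class = "cyc_layout_mismatch")
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single non-missing number", name))
  }
  if (strict_min && x <= min) {
    stop_invalid(sprintf("`%s` must be > %s", name, min))
  }
  if (!strict_min && x < min) {
    stop_invalid(sprintf("`%s` must be >= %s", name, min))
  }
  if (x > max) {
    stop_invalid(sprintf("`%s` must be <= %s", name, max))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

# column presence check for data-frame-first interfaces
check_columns <- function(x, cols, name) {
  if (!is.data.frame(x)) {
    stop_format(sprintf("`%s` must be a data frame", name))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    stop_format(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}
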