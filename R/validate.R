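# Internal argument checks. All user-facing errors carry a condition class so
# callers (and the CLI) can distinguish bad input from internal failures.

abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "popbenefit_invalid_input", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "popbenefit_degenerate", ...)
}

check_fraction <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_input(sprintf("`%s` must be numeric with no missing values.", name))
  }
  bad <- if (open) x <= 0 | x >= 1 else x < 0 | x > 1
  if (any(bad)) {
    abort_input(sprintf(
      "`%s` must lie in %s; got %s.",
      name, if (open) "(0, 1)" else "[0, 1]",
      paste(format(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_input(sprintf("`%s` must be numeric with no missing values.", name))
  }
  bad <- if (strict) x <= 0 else x < 0
  if (any(bad)) {
    abort_input(sprintf(
      "`%s` must be %s; got %s.",
      name, if (strict) "> 0" else ">= 0",
      paste(format(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

check_weights <- function(f1, f2) {
  check_positive(f1, "f1")
  check_positive(f2, "f2", strict = FALSE)
  invisible(NULL)
}

# recycle scalar-or-vector args against a common length, tidyverse-style
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != n
  if (any(bad)) {
    abort_input(sprintf(
      "Arguments must have length 1 or %d; offending: %s.",
      n, paste(names(args)[bad], collapse = ", ")
    ))
  }
  lapply(args, rep_len, n)
}
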