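# internal helpers shared across the package

# structured error so callers can distinguish failure modes by class
coex_stop <- function(class, msg, call. = FALSE) {
  cnd <- structure(
    class = c(class, "nigracoex_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

# delimiter from file extension; explicit `sep` wins
detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    coex_stop("nigracoex_bad_argument",
              sprintf("`%s` must be a single finite number", name))
  ok <- if (open) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    coex_stop("nigracoex_bad_argument",
              sprintf("`%s` = %g is outside its admissible range", name, x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
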