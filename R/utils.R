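# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message(sprintf(...))

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

warn2 <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

check_fraction <- function(x, what) {
  if (!is_fraction(x)) stop2("'%s' must be a single value in [0, 1]", what)
  x
}

# percentage rounded the way summary tables print it
pct <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, digits)
}
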