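#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., rosmod_invalid_category = ...) instead of grepping messages.
rosmod_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "rosmod_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# sample variance / sd always with the n-1 denominator
var1 <- function(x) stats::var(x)

round2 <- function(x, digits) {
  # round half away from zero, the convention of the field's stats software
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
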