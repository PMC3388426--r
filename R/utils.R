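# Internal helpers shared across the package.

# Half-up decimal rounding. base::round() rounds half to even, but published
# costing tables round half away from zero (e.g. 0.98752 -> 1 at 0 dp).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# "1,977.0"-style money formatting: thousands separators, fixed decimals.
fmt_money <- function(x, digits = 1) {
  formatC(round_half_up(x, digits),
          format = "f", digits = digits, big.mark = ",")
}

stop_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("humcap_domain_error", "humcap_error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("humcap_config_error", "humcap_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("humcap_io_error", "humcap_error")))
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`%s` must be a single finite number, not %s", name,
                paste(class(x), collapse = "/"))
  invisible(x)
}
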