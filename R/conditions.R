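# Classed error conditions so callers (and tests) can distinguish failure modes
# without parsing messages.

hs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("herbscreen_", class), "herbscreen_error"),
                      call = call))
}

hs_stop_invalid <- function(msg) hs_stop(msg, "invalid_argument", call = sys.call(-1))

hs_warn <- function(msg, class) {
  warning(warningCondition(msg,
                           class = c(paste0("herbscreen_", class), "herbscreen_warning")))
}

# scalar integer-ish check
is_count <- function(x, positive = TRUE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && (!positive || x >= 1)
}
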