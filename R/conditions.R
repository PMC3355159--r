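# Classed conditions so callers (and the CLI) can distinguish bad input
# from a capability refusal (enumeration cap, exhaustive-search bound).

stop_input <- function(fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c("canberra_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_cap <- function(fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c("canberra_cap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != trunc(x) || x < min)
    stop_input("`%s` must be a single integer >= %d (got %s)",
               name, min, paste(format(x), collapse = ","))
  as.integer(x)
}
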