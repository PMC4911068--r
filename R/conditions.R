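# Classed conditions so callers (and the CLI) can distinguish bad input
# from a model that is simply infeasible at the requested target.

abort_domain <- function(msg) {
  stop(structure(
    class = c("vocalrange_domain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_infeasible <- function(msg) {
  stop(structure(
    class = c("vocalrange_infeasible_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_scalar(x, name)
  if (x <= 0) abort_domain(sprintf("`%s` must be > 0 (got %g)", name, x))
  invisible(x)
}
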