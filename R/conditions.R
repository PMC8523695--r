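# Classed conditions so callers can distinguish domain violations from
# numerical evaluation failures.

tfk_stop <- function(msg, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "tfk_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

tfk_domain_error <- function(msg, ...) {
  tfk_stop(msg, "tfk_domain_error", call = sys.call(-1), ...)
}

tfk_eval_error <- function(msg, ...) {
  tfk_stop(msg, "tfk_eval_error", call = sys.call(-1), ...)
}

stopifnot_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    tfk_domain_error(sprintf("`%s` must be a finite numeric scalar", name))
  invisible(x)
}
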