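# Condition helpers: every user-facing failure mode gets a classed condition
# so callers (and the pipeline driver) can branch on error type.

hic_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "hicarch_error", "error")))
}

err_param       <- function(msg, ...) hic_error(msg, "hicarch_parameter_error", ...)
err_format      <- function(msg, ...) hic_error(msg, "hicarch_format_error", ...)
err_state       <- function(msg, ...) hic_error(msg, "hicarch_state_error", ...)
err_domain      <- function(msg, ...) hic_error(msg, "hicarch_domain_error", ...)
err_degenerate  <- function(msg, ...) hic_error(msg, "hicarch_degeneracy_error", ...)
err_convergence <- function(msg, ...) hic_error(msg, "hicarch_convergence_error", ...)
err_align       <- function(msg, ...) hic_error(msg, "hicarch_alignment_error", ...)
err_ambiguous   <- function(msg, ...) hic_error(msg, "hicarch_ambiguity_error", ...)
err_annotation  <- function(msg, ...) hic_error(msg, "hicarch_annotation_error", ...)
err_integration <- function(msg, ...) hic_error(msg, "hicarch_integration_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
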