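# Numerically stable logistic helpers used across the model and simulators.

#' Stable log(1 + exp(x))
#'
#' Evaluates without overflow for |x| up to the double range; for x > 0 the
#' identity x + log1p(exp(-x)) is used.
#'
#' @param x numeric vector.
#' @return numeric vector, same length as `x`.
#' @keywords internal
log1p_exp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

#' Inverse-logit and logit
#'
#' Thin wrappers over [stats::plogis()] / [stats::qlogis()], named for the
#' link function of the model.
#'
#' @param x,p numeric vectors (logit scale / probability scale).
#' @return numeric vector.
#' @export
inv_logit <- function(x) plogis(x)

#' @rdname inv_logit
#' @export
logit <- function(p) qlogis(p)

# Clip probabilities away from {0, 1} for likelihood evaluation only.
clip_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
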