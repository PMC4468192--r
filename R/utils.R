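inv_logit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

#' Derive a child RNG seed from a master seed
#'
#' Deterministic, cheap splitting of one user-facing seed into per-stage
#' seeds so that independent pipeline stages do not share RNG streams.
#' Kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed master integer seed
#' @param offset stage index (distinct per consumer)
#' @return an integer seed
#' @export
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 104729) %% 2147483647)
}

check_binary_labels <- function(y) {
  if (!all(y %in% c(0, 1))) stop_arg("labels must be 0/1")
  if (length(unique(y)) < 2L) {
    stop_arg("both classes must be present (models cannot converge on single-class data)")
  }
  invisible(TRUE)
}
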