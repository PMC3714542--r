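#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage (exploration, planning noise, navigation, ...) draws
#' its own stream from the master seed so sub-experiments can be re-run
#' independently. The derived seed is kept below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param label character tag of the consuming stage
#' @return an integer seed
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 1009) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(rowSums(v^2))

#' @keywords internal
point_dist <- function(a, b) sqrt(sum((a - b)^2))
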