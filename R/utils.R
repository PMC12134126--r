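## Internal helpers shared across modules.

config_error <- function(msg, ...) {
  abort(msg, class = "delatlas_config_error", ...)
}

arg_error <- function(msg, ...) {
  abort(msg, class = "delatlas_argument_error", ...)
}

parse_error <- function(msg, ...) {
  abort(msg, class = "delatlas_parse_error", ...)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used throughout the package to compare recovered spatial domains or gene
#' groups against planted truth, since cluster labels are arbitrary.
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) arg_error("`x` and `y` must have equal length.")
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  n <- length(x)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  total <- n * (n - 1) / 2
  expected <- sum_a * sum_b / total
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

## Derive a stream-specific 32-bit seed from a base seed, so that independent
## stages never consume the same RNG stream.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647L)
}
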