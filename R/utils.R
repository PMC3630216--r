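#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm pnorm rnorm runif rbinom chisq.test fisher.test
#' @importFrom stats glm binomial glm.control coef vcov pchisq model.matrix
#' @importFrom stats p.adjust complete.cases quantile integrate setNames
#' @importFrom utils read.delim write.table
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# All randomness flows through explicit integer seeds; the caller's global
# RNG state is left untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific sub-seed, kept inside 32-bit integer range.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  w <- exp(eta - m)
  w / rowSums(w)
}

# Polynomial rolling hash over a character scalar (modulus below 2^31 so
# arithmetic stays exact in doubles); used for config hashes in manifests.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
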