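#' @importFrom rlang abort warn %||% .data
#' @importFrom stats fft dnorm rnorm runif rpois quantile median convolve sd
NULL

rms_of <- function(x) sqrt(mean(x^2))

# deterministic 31-bit string hash for per-cell seed derivation
hash_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "|")
  codes <- utf8ToInt(key)
  s <- as.numeric(master %% 2147483647L)
  for (code in codes) {
    s <- (s * 31 + code) %% 2147483647
  }
  as.integer(s)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    rlang::abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
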