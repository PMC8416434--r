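#' @importFrom rlang abort warn .data
#' @importFrom tibble as_tibble tibble
#' @importFrom generics tidy glance
#' @importFrom stats fft rnorm rbinom sd var median plogis qlogis predict runif
#' @importFrom utils head modifyList
NULL

# FNV-1a hash of a raw vector, folded to a hex string. Used for config /
# artifact fingerprints so runs can assert reproducibility without an
# external hashing dependency.
fnv1a_hex <- function(raw_bytes) {
  stopifnot(is.raw(raw_bytes))
  h <- 2166136261
  for (b in as.integer(raw_bytes)) {
    # XOR into the low byte only; h itself can exceed the 32-bit signed
    # range bitwXor accepts
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # to stay inside double precision.
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

hash_object <- function(x) fnv1a_hex(serialize(x, NULL, version = 2))

# Deterministic sub-seed derivation: every source of randomness in the
# package draws its seed from a single master seed plus a character tag, so
# that stages can be re-run independently yet reproduce a full pipeline run.
derive_seed <- function(master, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 * 48271 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

qeeg_abort <- function(message, class, ...) {
  abort(message, class = c(class, "qeeg_error"), ...)
}

# Column-wise z-scoring with statistics taken from (and returned for) the
# training data only; constant columns are centred but left unscaled.
zscore_fit <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sig <- sqrt(pmax(colSums(x * x) - n * mu^2, 0) / (n - 1))
  sig[!is.finite(sig) | sig < 1e-12] <- 1
  list(center = mu, scale = sig)
}

zscore_apply <- function(x, stats) {
  x <- x - rep(stats$center, each = nrow(x))
  x / rep(stats$scale, each = nrow(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
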