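#' @keywords internal
"_PACKAGE"

# Numerically stable log-sum-exp over the rows of a matrix (or a vector).
logsumexp <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
  } else {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
}

# Sample standard deviation (denominator n - 1), kept explicit so every
# module shares one convention.
sample_sd <- function(x) stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Derive a stage seed from a global seed with a fixed offset, keeping the
# result inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647L)
}
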