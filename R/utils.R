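#' @keywords internal
"_PACKAGE"

# Shared internal helpers. Entity identifiers are case-normalized to upper
# case wherever lists from different namespaces (transcript, protein, TF,
# network) must be joinable.

norm_id <- function(x) toupper(trimws(as.character(x)))

# Derive a reproducible child seed from a base seed; kept below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 97L
}

geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
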