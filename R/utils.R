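#' @keywords internal
"_PACKAGE"

# Derive a deterministic 32-bit sub-seed from a master seed so each
# generator/stage consumes its own stream: adding a call to one generator
# never perturbs another.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 1

# graph density on n nodes / e edges; 0 or 1 node -> 0
graph_density <- function(n, e) {
  if (n < 2) return(0)
  2 * e / (n * (n - 1))
}
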