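#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# Deterministic seed derivation: mixes a base seed with small integer codes
# into [0, 2^31 - 2] so every sampled dataset / ensemble member gets its own
# reproducible stream. Plain modular arithmetic keeps it dependency-free and
# stable across platforms.
derive_seed <- function(base, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  acc <- as.numeric(base) %% m
  for (v in list(...)) {
    v <- if (is.character(v)) sum(utf8ToInt(v)) else as.numeric(v)
    if (is.na(v)) v <- 0
    acc <- (acc * 48271 + v + 1) %% m
  }
  as.integer(acc)
}

#' @export
generics::tidy

#' @export
generics::glance
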