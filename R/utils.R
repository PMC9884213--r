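# internal helpers: seeding, argument checks, small numerics

#' Derive a reproducible child seed from a top-level seed
#'
#' Module-level randomness (scan jitter, dataset shuffles, weight
#' initialization) is seeded from one top-level seed through named streams,
#' so phases can be rerun independently yet reproducibly.
#'
#' @param seed integer top-level seed.
#' @param stream character stream name, e.g. `"phase1"`, `"scan:3"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# run expr under a local RNG state seeded with `seed`
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_crownforge <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "crownforge_error")))
}
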