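# Stable 31-bit integer hash of strings/numbers, used to derive per-well RNG
# substreams from the master seed. Polynomial rolling hash over UTF-8 bytes;
# stays < 2^31 so it is always a valid set.seed() input.
stable_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                    character(1)), collapse = "::")
  bytes <- utf8ToInt(s)
  h <- 7
  m <- 2147483647
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

# evaluate expr under a locally-seeded RNG without disturbing the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must be a single value in [0, 1]", call. = FALSE)
  }
}
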