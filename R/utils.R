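# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# go through this so that a seed argument fully determines the output.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 31-bit sub-seed derived from an integer seed and a string
# tag, so independent random streams can be derived from one user seed.
derive_seed <- function(seed, tag) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 20 standard amino acids in the fixed one-hot order used everywhere.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 8-letter secondary-structure alphabet (DSSP order); the built-in
# geometric assigner only emits H, E and C ("-" is reported as C).
SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C")

stop_pf <- function(msg, class, ...) {
  stop(structure(class = c(class, "phosfusion_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
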