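#' Derive a reproducible substream seed from a master seed and identifiers
#'
#' All stochastic stages of the simulator draw from substreams keyed by the
#' master seed plus the identifier tuple of the object being generated
#' (animal, intercostal space, physiologic state, scan, plane, role). This
#' makes every output a pure function of (config, identifiers, seed) and
#' independent of generation order: rendering image 7 gives the same pixels
#' whether or not images 1..6 were rendered first.
#'
#' @param master_seed Integer master seed.
#' @param ... Identifier components (coerced to character) naming the
#'   substream, e.g. `"a03", 5, "arrest", 1, 12, "device"`.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "a01", 4, "arrest", 1, 3, "truth")
#' @export
substream_seed <- function(master_seed, ...) {
  tag <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  # FNV-1a over the tag bytes, folded into [0, 2^31 - 2]; done in doubles to
  # stay exact (all intermediates < 2^53)
  h <- 2166136261
  for (b in utf8ToInt(tag)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h <- (h + as.double(master_seed) %% 2147483647) %% 2147483647
  as.integer(h)
}

# xor of two non-negative doubles representing 32-bit words
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536) %% 65536, as.integer(b %/% 65536) %% 65536)
  as.double(hi) * 65536 + as.double(lo)
}

# Evaluate expr with a local RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
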