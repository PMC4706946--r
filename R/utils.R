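# Internal helpers shared across modules.

GENO_CLASSES <- c("AA", "AB", "BB")

#' Derive a reproducible substream seed from a global seed and a label
#'
#' All stochastic operations in the package consume a named substream derived
#' from one global integer seed, so that modules can be re-run or tested
#' independently without perturbing each other's draws.
#'
#' @param seed Global integer seed.
#' @param name Character label of the substream.
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  # 32-bit FNV-1a style mix of the label, folded with the seed
  h <- 2166136261 %% 2147483629
  for (b in utf8ToInt(name)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483629
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483629 + 1)
}

# Evaluate expr with a local RNG stream; restores the caller's RNG state.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Clip numeric vector into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Weighted mean/sd with a floor on the sd.
wmean <- function(x, w) sum(x * w) / sum(w)
wsd <- function(x, w, floor = 0) {
  if (length(x) < 2L) return(floor)
  m <- wmean(x, w)
  v <- sum(w * (x - m)^2) / sum(w) * length(x) / (length(x) - 1L)
  max(sqrt(v), floor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
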