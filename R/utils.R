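# Seed plumbing: one master seed expands into named substreams so that e.g.
# adding participants never perturbs the draws of earlier ones.

#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an arbitrary sequence of labels
#' (stage names, participant ids, run ids) into a new 32-bit seed.  The
#' derivation is deterministic and order-sensitive.
#'
#' @param seed Integer master seed.
#' @param ... Labels (numbers or strings) identifying the substream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate", 3)
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed) %% m
  for (k in list(...)) {
    kk <- if (is.character(k)) {
      v <- utf8ToInt(k)
      sum(v * seq_along(v))
    } else {
      as.double(k)
    }
    s <- (s * 69069 + (kk %% m) * 1234567 + 12345) %% m
  }
  as.integer(s)
}

# Evaluate code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Nearest design location with midpoint ties broken toward the centre.
nearest_button <- function(est, locations) {
  locations <- sort(locations)
  nb <- length(locations)
  edges <- (locations[-nb] + locations[-1]) / 2
  centre <- mean(locations)
  idx <- rep(1L, length(est))
  for (j in seq_along(edges)) {
    idx <- idx + (if (edges[j] < centre) est >= edges[j] else est > edges[j])
  }
  locations[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
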