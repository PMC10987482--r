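`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
refp_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "refplane_error")))
}

#' Deterministically combine seed components into one 32-bit seed
#' @noRd
mix_seed <- function(...) {
  parts <- c(...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

#' Evaluate an expression with a temporary RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Extract the pixel matrix from a tile or plain matrix
#' @noRd
tile_pixels <- function(tile) {
  if (inherits(tile, "bead_tile")) tile$pixels else tile
}

key_string <- function(experiment, exposure_ms, fov) {
  paste(experiment, exposure_ms, fov, sep = "|")
}
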