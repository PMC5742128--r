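# small shared utilities

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a sub-seed for a named pipeline stage from a master seed (kept well
# below .Machine$integer.max).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Unit helpers
#'
#' Convenience converters to SI base units (meters, seconds, amperes), for
#' configs written in the field's customary units.
#'
#' @param x numeric value(s).
#' @return value in SI units.
#' @name units
NULL

#' @rdname units
#' @export
um <- function(x) x * 1e-6
#' @rdname units
#' @export
mm <- function(x) x * 1e-3
#' @rdname units
#' @export
us <- function(x) x * 1e-6
#' @rdname units
#' @export
ms <- function(x) x * 1e-3
#' @rdname units
#' @export
mA <- function(x) x * 1e-3
#' @rdname units
#' @export
uA <- function(x) x * 1e-6

vnorm <- function(v) sqrt(sum(v^2))

polyline_length <- function(points) {
  if (nrow(points) < 2) return(0)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                    points[-nrow(points), , drop = FALSE])^2)))
}

# positions along a polyline at arc lengths s
polyline_point_at <- function(points, s) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  s <- pmin(pmax(s, 0), L)
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  t <- (s - cs[idx]) / pmax(seg[idx], 1e-300)
  points[idx, , drop = FALSE] +
    (points[idx + 1, , drop = FALSE] - points[idx, , drop = FALSE]) * t
}
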