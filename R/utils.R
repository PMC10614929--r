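# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "guvmem_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Bounding boxes are half-open [r0, r1) x [c0, c1) in 0-based pixel
# coordinates throughout the public interface.
bbox <- function(r0, r1, c0, c1) {
  stopifnot(r1 >= r0, c1 >= c0)
  c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
}

bbox_from_pixels <- function(px) {
  # px: n x 2 matrix of 0-based (row, col) pixel coordinates
  bbox(min(px[, 1L]), max(px[, 1L]) + 1L, min(px[, 2L]), max(px[, 2L]) + 1L)
}

bbox_overlaps <- function(a, b) {
  a[["r0"]] < b[["r1"]] && b[["r0"]] < a[["r1"]] &&
    a[["c0"]] < b[["c1"]] && b[["c0"]] < a[["c1"]]
}

bbox_inside <- function(b, height, width) {
  b[["r0"]] >= 0 && b[["c0"]] >= 0 && b[["r1"]] <= height && b[["c1"]] <= width
}

clip_bbox <- function(b, height, width) {
  bbox(max(b[["r0"]], 0), min(b[["r1"]], height),
       max(b[["c0"]], 0), min(b[["c1"]], width))
}
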