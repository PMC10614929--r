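# GUV recognition in the lipid channel. The study used a trained network
# for this step; a trained model is not reproducible from a text
# description, so the default detector is a deterministic gradient-vote
# circle transform, and import_detections() accepts boxes produced by any
# external detector through the JSON detection format.

# Separable Gaussian smoothing with replicate padding. Used instead of an
# FFT convolution so that detection is exactly translation-equivariant in
# the image interior.
gauss_blur_sep <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  P <- pad_replicate(img, r)
  H <- nrow(img); W <- ncol(img)
  tmp <- matrix(0, H, W + 2L * r)
  for (i in -r:r)
    tmp <- tmp + k[i + r + 1L] * P[(r + i) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in -r:r)
    out <- out + k[j + r + 1L] * tmp[, (r + j) + seq_len(W), drop = FALSE]
  out
}

#' Detect GUVs in a lipid channel by a gradient-vote circle transform
#'
#' The image is lightly smoothed, gradients are computed by central
#' differences, and every pixel whose gradient magnitude exceeds
#' `grad_frac` times the maximum casts votes at the two candidate circle
#' centers one radius away along its gradient line, for every integer
#' radius in `[r_min, r_max]`. Candidate circles are ranked by their
#' 3x3-pooled vote count divided by the circle circumference; overlapping
#' candidates (center distance below half the radius sum) are suppressed
#' keeping the higher-ranked one. The radius of each surviving circle is
#' refined as the gradient-weighted mean distance of its supporting edge
#' pixels, and the reported detection score is the vote ratio mapped to
#' `[0, 1]`. Regions are sorted by (row, col).
#'
#' @param lipid_channel numeric matrix, or an [mc_image()] (its `lipid`
#'   channel is used).
#' @param r_min,r_max radius search range in px (`r_min < r_max`).
#' @param min_score minimum detection score in `[0, 1]`.
#' @param edge_policy `"exclude"` (default) drops circles whose bounding
#'   box exits the frame; `"include"` keeps them.
#' @param grad_frac edge-pixel selection fraction of the maximum gradient
#'   magnitude.
#' @param smooth_sigma pre-smoothing sigma in px.
#' @return data.frame with columns `center_row`, `center_col` (0-based),
#'   `radius`, `score`, `r0`, `r1`, `c0`, `c1` (half-open bbox). A blank
#'   (constant) image yields zero rows.
#' @export
detect_guvs <- function(lipid_channel, r_min, r_max, min_score = 0.25,
                        edge_policy = c("exclude", "include"),
                        grad_frac = 0.3, smooth_sigma = 1.0) {
  edge_policy <- match.arg(edge_policy)
  if (inherits(lipid_channel, "mc_image"))
    lipid_channel <- get_channel(lipid_channel, "lipid")
  stopifnot(r_min < r_max, r_min > 0)
  img <- gauss_blur_sep(lipid_channel, smooth_sigma)
  H <- nrow(img); W <- ncol(img)
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  gr[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  gc[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  mmax <- max(mag)
  if (mmax == 0) return(empty_regions())
  sel <- which(mag > grad_frac * mmax)
  er <- ((sel - 1L) %% H)          # 0-based edge-pixel coordinates
  ec <- ((sel - 1L) %/% H)
  emag <- mag[sel]
  ur <- gr[sel] / emag
  uc <- gc[sel] / emag
  radii <- seq.int(ceiling(r_min), floor(r_max))
  cand <- list()
  for (r in radii) {
    cr <- c(round(er - r * ur), round(er + r * ur))
    cc <- c(round(ec - r * uc), round(ec + r * uc))
    ok <- cr >= 0 & cr < H & cc >= 0 & cc < W
    if (!any(ok)) next
    acc <- matrix(0L, H, W)
    tab <- table(cc[ok] * H + cr[ok])
    acc[as.integer(names(tab)) + 1L] <- as.integer(tab)
    ratio <- box_sum(acc, 3L) / (2 * pi * r)
    hits <- which(ratio >= 2 * min_score)
    if (length(hits) > 0L)
      cand[[length(cand) + 1L]] <- data.frame(
        center_row = (hits - 1L) %% H, center_col = (hits - 1L) %/% H,
        radius = r, ratio = ratio[hits])
  }
  if (length(cand) == 0L) return(empty_regions())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$ratio, cand$center_row, cand$center_col,
                     cand$radius), , drop = FALSE]
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    dup <- FALSE
    for (j in keep) {
      dd <- sqrt((cand$center_row[i] - cand$center_row[j])^2 +
                 (cand$center_col[i] - cand$center_col[j])^2)
      if (dd < 0.5 * (cand$radius[i] + cand$radius[j])) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- cand[keep, , drop = FALSE]
  # radius refinement: the annular intensity profile is symmetric about
  # the ring crest, so the background-subtracted intensity centroid of
  # pixel distances (with a 1/d circumference correction) recovers the
  # crest radius; iterate to decouple from the integer vote radius
  out$radius <- vapply(seq_len(nrow(out)), function(i) {
    refine_ring_radius(img, out$center_row[i], out$center_col[i],
                       out$radius[i])
  }, numeric(1L))
  out$score <- pmin(out$ratio / 2, 1)
  out$r0 <- out$center_row - out$radius
  out$r1 <- out$center_row + out$radius + 1
  out$c0 <- out$center_col - out$radius
  out$c1 <- out$center_col + out$radius + 1
  if (edge_policy == "exclude") {
    inside <- out$r0 >= 0 & out$c0 >= 0 & out$r1 <= H & out$c1 <= W
    out <- out[inside, , drop = FALSE]
  }
  out <- out[order(out$center_row, out$center_col),
             c("center_row", "center_col", "radius", "score",
               "r0", "r1", "c0", "c1"), drop = FALSE]
  rownames(out) <- NULL
  out
}

refine_ring_radius <- function(img, cr, cc, r0, half_width = 4,
                               n_iter = 4L) {
  H <- nrow(img); W <- ncol(img)
  ext <- ceiling(r0 + half_width + 2)
  ri <- max(1L, floor(cr + 1 - ext)):min(H, ceiling(cr + 1 + ext))
  ci <- max(1L, floor(cc + 1 - ext)):min(W, ceiling(cc + 1 + ext))
  sub <- img[ri, ci, drop = FALSE]
  d <- sqrt(outer((ri - 1 - cr)^2, (ci - 1 - cc)^2, "+"))
  w0 <- pmax(sub - min(sub), 0) / pmax(d, 1)
  r <- r0
  for (it in seq_len(n_iter)) {
    ann <- abs(d - r) <= half_width
    if (!any(ann)) return(r)
    r <- sum(d[ann] * w0[ann]) / sum(w0[ann])
  }
  r
}

empty_regions <- function() {
  data.frame(center_row = numeric(), center_col = numeric(),
             radius = numeric(), score = numeric(), r0 = numeric(),
             r1 = numeric(), c0 = numeric(), c1 = numeric())
}

#' Import externally produced GUV detections
#'
#' Validates a [detection_record()] against the image shape, applying the
#' same sorting and edge policy as [detect_guvs()]. Boxes fully outside
#' the frame are dropped with a warning; with `edge_policy = "include"`
#' partially outside boxes are clipped, with `"exclude"` they are dropped.
#'
#' @param record a [detection_record()].
#' @param image_shape integer `c(height, width)`.
#' @param edge_policy `"exclude"` (default) or `"include"`.
#' @return data.frame in the [detect_guvs()] format.
#' @export
import_detections <- function(record, image_shape,
                              edge_policy = c("exclude", "include")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(record, "detection_record"))
  H <- image_shape[1L]; W <- image_shape[2L]
  rg <- record$regions
  if (nrow(rg) == 0L) return(empty_regions())
  outside <- rg$r1 <= 0 | rg$r0 >= H | rg$c1 <= 0 | rg$c0 >= W
  if (any(outside)) {
    warnf("%d detection(s) fully outside the %d x %d frame dropped",
          sum(outside), H, W)
    rg <- rg[!outside, , drop = FALSE]
  }
  if (nrow(rg) == 0L) return(empty_regions())
  if (edge_policy == "exclude") {
    inside <- rg$r0 >= 0 & rg$c0 >= 0 & rg$r1 <= H & rg$c1 <= W
    rg <- rg[inside, , drop = FALSE]
  } else {
    rg$r0 <- pmax(rg$r0, 0); rg$r1 <- pmin(rg$r1, H)
    rg$c0 <- pmax(rg$c0, 0); rg$c1 <- pmin(rg$c1, W)
  }
  if (nrow(rg) == 0L) return(empty_regions())
  if (is.null(rg$score)) rg$score <- 1
  rg <- rg[order(rg$center_row, rg$center_col),
           c("center_row", "center_col", "radius", "score",
             "r0", "r1", "c0", "c1"), drop = FALSE]
  rownames(rg) <- NULL
  rg
}
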