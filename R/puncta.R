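# Per-GUV puncta calling. For each recognized GUV the protein-channel crop
# is processed independently: background estimate by minimum cross-entropy
# (Li) thresholding, background subtraction, non-local-means denoising,
# Gaussian blur, 8-bit rescale + global histogram equalization, Otsu
# foreground mask, then connected components larger than 5 px are counted
# as individual puncta.

#' Parameters of the puncta-calling pipeline
#'
#' The paper-fixed constant is the component size rule (components must be
#' larger than `min_component_px = 5` pixels, i.e. area >= 6). The filter
#' parameters are not dictated by the assay and are exposed here; results
#' on well-separated high-SNR spots are insensitive to +/-50% changes.
#'
#' @param nl_h NL-means filtering strength (intensity units).
#' @param nl_patch NL-means patch size in px (odd).
#' @param nl_search NL-means search window in px (odd).
#' @param blur_sigma Gaussian blur sigma in px (> 0).
#' @param min_component_px components must exceed this many pixels.
#' @param connectivity pixel connectivity, 4 or 8.
#' @param crop_pad padding around the GUV bounding box in px.
#' @param min_contrast minimum dynamic range (8-bit grey levels) the
#'   denoised crop must span to count as containing signal; below it the
#'   crop is treated as structure-free background. The default (8) sits
#'   well above the 2-3 levels that residual quantization noise spans and
#'   well below any spot with usable SNR.
#' @return object of class `pipeline_params`.
#' @export
pipeline_params <- function(nl_h = 10, nl_patch = 7, nl_search = 21,
                            blur_sigma = 1.0, min_component_px = 5L,
                            connectivity = 8L, crop_pad = 4L,
                            min_contrast = 8L) {
  stopifnot(nl_h > 0, nl_patch >= 1, nl_search >= 1, blur_sigma > 0,
            min_component_px >= 0, connectivity %in% c(4L, 8L),
            crop_pad >= 0, min_contrast >= 0)
  structure(list(nl_h = nl_h,
                 min_contrast = as.integer(min_contrast),
                 nl_patch = 2L * (as.integer(nl_patch) %/% 2L) + 1L,
                 nl_search = 2L * (as.integer(nl_search) %/% 2L) + 1L,
                 blur_sigma = blur_sigma,
                 min_component_px = as.integer(min_component_px),
                 connectivity = as.integer(connectivity),
                 crop_pad = as.integer(crop_pad)),
            class = "pipeline_params")
}

#' Minimum cross-entropy (Li) threshold
#'
#' Finds the background/foreground split minimizing the Li-Lee cross
#' entropy between the image and its two-level reconstruction, by
#' exhaustive search over the distinct intensity values present (pixels
#' `<= t` form the background class). Every level between the largest
#' background value and the smallest foreground value of the optimal
#' split minimizes the cross entropy equally; the midpoint of that
#' boundary is returned as the canonical threshold, so the value always
#' separates the two classes strictly. A constant crop returns that
#' constant. Used as the background estimate for subtraction.
#'
#' @param crop numeric matrix of nonnegative intensities.
#' @return threshold intensity (scalar).
#' @export
compute_li_threshold <- function(crop) {
  v <- as.numeric(crop)
  if (length(v) == 0L) stopf("empty crop")
  u <- sort(unique(v))
  if (length(u) == 1L) return(u)
  cnt <- tabulate(match(v, u), nbins = length(u))
  csum <- cumsum(cnt * u)
  cn <- cumsum(cnt)
  tot_s <- csum[length(u)]
  tot_n <- cn[length(u)]
  m_b <- csum / cn
  m_f <- (tot_s - csum) / (tot_n - cn)
  term <- function(s, m) ifelse(s > 0, s * log(m), 0)
  eta <- -(term(csum, m_b) + term(tot_s - csum, m_f))
  eta[length(u)] <- -term(tot_s, tot_s / tot_n)  # all-background split
  k <- which.min(eta)
  if (k == length(u)) return(u[k])
  (u[k] + u[k + 1L]) / 2
}

#' Otsu threshold on an 8-bit crop
#'
#' Exhaustive search over the 255 candidate levels for the level
#' minimizing the intra-class (within-group) intensity variance; ties are
#' broken toward the smallest level. The foreground mask is defined as
#' pixels strictly above the returned level. A constant crop has no
#' foreground and raises an error of class `guvmem_no_foreground`.
#'
#' @param crop8 integer matrix with values in 0..255.
#' @return threshold level (integer in 0..254).
#' @export
compute_otsu_threshold <- function(crop8) {
  v <- as.integer(crop8)
  if (length(v) == 0L) stopf("empty crop")
  if (any(v < 0L | v > 255L)) stopf("crop is not 8-bit")
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    stopf("constant crop: no foreground", class = "guvmem_no_foreground")
  n <- sum(h)
  lev <- 0:255
  cw <- cumsum(h)
  cs <- cumsum(h * lev)
  cs2 <- cumsum(h * lev^2)
  # candidates t = 0..254 with both classes nonempty
  t <- 0:254
  nb <- cw[t + 1L]; nf <- n - nb
  ok <- nb > 0L & nf > 0L
  sb <- cs[t + 1L]; sf <- cs[256L] - sb
  s2b <- cs2[t + 1L]; s2f <- cs2[256L] - s2b
  within <- (s2b - sb^2 / nb) + (s2f - sf^2 / nf)  # n * weighted variance
  within[!ok] <- Inf
  t[which.min(within)]
}

# --- NL-means denoising (integral-image vectorization) -------------------

pad_replicate <- function(x, p) {
  ri <- pmin(pmax(seq_len(nrow(x) + 2L * p) - p, 1L), nrow(x))
  ci <- pmin(pmax(seq_len(ncol(x) + 2L * p) - p, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

# Sum of x over a centered k x k window at every pixel, via 2-D cumsum on
# a padded copy (zero padding; callers pad with replicate first).
box_sum <- function(x, k) {
  r <- k %/% 2L
  xp <- matrix(0, nrow(x) + 2L * r + 1L, ncol(x) + 2L * r + 1L)
  xp[(r + 2L):(r + 1L + nrow(x)), (r + 2L):(r + 1L + ncol(x))] <- x
  S <- apply(xp, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  i <- seq_len(nrow(x)); j <- seq_len(ncol(x))
  S[i + 2L * r + 1L, j + 2L * r + 1L, drop = FALSE] -
    S[i, j + 2L * r + 1L, drop = FALSE] -
    S[i + 2L * r + 1L, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Non-local-means denoising
#'
#' Classic patchwise NL-means: each pixel is replaced by a weighted mean
#' of pixels in its search window, with weights
#' `exp(-d2 / h^2)` where `d2` is the mean squared difference between the
#' two surrounding patches. Boundaries are handled by replicate padding.
#'
#' @param img numeric matrix.
#' @param h filtering strength (intensity units).
#' @param patch odd patch size in px.
#' @param search odd search-window size in px.
#' @return denoised matrix of the same size.
#' @export
nl_means_denoise <- function(img, h = 10, patch = 7, search = 21) {
  stopifnot(h > 0, patch %% 2L == 1L, search %% 2L == 1L)
  pr <- patch %/% 2L
  sr <- search %/% 2L
  P <- pad_replicate(img, sr + pr)
  n_r <- nrow(img); n_c <- ncol(img)
  # the "reference" block inside the padded image, offset by (dy, dx)
  blk <- function(dy, dx)
    P[(sr + pr + dy) + seq_len(n_r), (sr + pr + dx) + seq_len(n_c),
      drop = FALSE]
  ref_pad <- pad_replicate(img, pr)
  num <- matrix(0, n_r, n_c)
  den <- matrix(0, n_r, n_c)
  for (dy in -sr:sr) {
    for (dx in -sr:sr) {
      shifted_pad <- P[(sr + dy) + seq_len(n_r + 2L * pr),
                       (sr + dx) + seq_len(n_c + 2L * pr), drop = FALSE]
      d2 <- box_sum((ref_pad - shifted_pad)^2, patch)[
        pr + seq_len(n_r), pr + seq_len(n_c), drop = FALSE] / patch^2
      w <- exp(-d2 / h^2)
      num <- num + w * blk(dy, dx)
      den <- den + w
    }
  }
  num / den
}

# Classic 8-bit global histogram equalization (CDF remap). Constant images
# are returned unchanged.
equalize_hist8 <- function(img8) {
  v <- as.integer(img8)
  h <- tabulate(v + 1L, nbins = 256L)
  nz <- which(h > 0L)
  if (length(nz) < 2L) return(img8)
  cdf <- cumsum(h)
  cdf_min <- cdf[nz[1L]]
  lut <- round((cdf - cdf_min) / (length(v) - cdf_min) * 255)
  matrix(lut[v + 1L], nrow(img8), ncol(img8))
}

rescale_to_8bit <- function(x, bit_depth = 8L) {
  if (bit_depth > 8L) x <- x / (2^bit_depth - 1) * 255
  matrix(as.integer(pmin(pmax(round(x), 0L), 255L)), nrow(x), ncol(x))
}

#' Preprocess a protein-channel crop for puncta segmentation
#'
#' Fixed stage order: (1) subtract `background_threshold`, clipping at 0;
#' (2) NL-means denoising; (3) Gaussian blur; (4) rescale to 8 bit and
#' apply global histogram equalization. Equalization is per crop: each
#' recognized GUV is processed independently. All stages operate on
#' quantized integer intensities, as in the 8-bit image pipelines this
#' emulates; the quantization is what lets a structure-free crop collapse
#' to a (near-)constant image with no foreground, rather than having its
#' residual noise stretched into spurious structure.
#'
#' @param crop numeric matrix of nonnegative intensities.
#' @param background_threshold background level to subtract (typically
#'   from [compute_li_threshold()]).
#' @param params a [pipeline_params()].
#' @param bit_depth bit depth of the source image (8-bit values pass
#'   through unscaled; 16-bit values are mapped onto 0..255).
#' @return integer matrix with values in 0..255.
#' @export
preprocess_crop <- function(crop, background_threshold,
                            params = pipeline_params(), bit_depth = 8L) {
  stopifnot(inherits(params, "pipeline_params"))
  x <- pmax(crop - background_threshold, 0)
  if (max(x) > 0) {
    x <- round(nl_means_denoise(x, params$nl_h, params$nl_patch,
                                params$nl_search))
    x <- round(EBImage::gblur(x, sigma = params$blur_sigma))
    x <- pmax(x, 0)
  }
  x8 <- rescale_to_8bit(x, bit_depth)
  if (max(x8) - min(x8) <= params$min_contrast)
    return(matrix(0L, nrow(x8), ncol(x8)))
  equalize_hist8(x8)
}

# --- connected components ------------------------------------------------

# Frontier-based flood fill labelling with 4- or 8-connectivity.
label_components <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (!any(mask)) return(lab)
  offs <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))[-5L, , drop = FALSE]
  }
  todo <- which(mask)
  cur <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier) > 0L) {
      fr <- ((frontier - 1L) %% H) + 1L
      fc <- ((frontier - 1L) %/% H) + 1L
      nr <- rep(fr, nrow(offs)) + rep(offs[, 1L], each = length(frontier))
      nc <- rep(fc, nrow(offs)) + rep(offs[, 2L], each = length(frontier))
      keep <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
      idx <- unique((nc[keep] - 1L) * H + nr[keep])
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- cur
      frontier <- idx
    }
  }
  lab
}

new_punctum <- function(pixels0, channel = NA_character_) {
  structure(list(channel = channel, pixels = pixels0,
                 area = nrow(pixels0), bbox = bbox_from_pixels(pixels0),
                 centroid = colMeans(pixels0)),
            class = "punctum")
}

#' Label puncta in a binary mask
#'
#' Connected components under the configured connectivity; only components
#' strictly larger than `min_component_px` pixels (default: larger than 5,
#' i.e. area >= 6) are kept as puncta. Puncta are sorted by the top-left
#' corner of their bounding box. Pixel coordinates are 0-based; bounding
#' boxes half-open.
#'
#' @param mask logical matrix.
#' @param params a [pipeline_params()].
#' @param channel optional channel role recorded on each punctum.
#' @return list of `punctum` objects (fields `channel`, `pixels`, `area`,
#'   `bbox`, `centroid`).
#' @export
label_puncta <- function(mask, params = pipeline_params(),
                         channel = NA_character_) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  lab <- label_components(mask, params$connectivity)
  if (max(lab) == 0L) return(list())
  out <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (length(idx) <= params$min_component_px) next
    px <- cbind(row = ((idx - 1L) %% nrow(mask)),
                col = ((idx - 1L) %/% nrow(mask)))
    out[[length(out) + 1L]] <- new_punctum(px, channel)
  }
  if (length(out) == 0L) return(list())
  ord <- order(vapply(out, function(p) p$bbox[["r0"]], numeric(1L)),
               vapply(out, function(p) p$bbox[["c0"]], numeric(1L)))
  out[ord]
}

#' @export
print.punctum <- function(x, ...) {
  cat(sprintf("<punctum> area %d px, bbox [%g,%g)x[%g,%g), centroid (%.1f, %.1f)\n",
              x$area, x$bbox[["r0"]], x$bbox[["r1"]], x$bbox[["c0"]],
              x$bbox[["c1"]], x$centroid[[1L]], x$centroid[[2L]]))
  invisible(x)
}

#' Convert a list of puncta to a data.frame
#'
#' @param puncta list of `punctum` objects.
#' @return data.frame with one row per punctum.
#' @export
puncta_table <- function(puncta) {
  if (length(puncta) == 0L)
    return(data.frame(channel = character(), area = integer(),
                      r0 = numeric(), r1 = numeric(), c0 = numeric(),
                      c1 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  do.call(rbind, lapply(puncta, function(p)
    data.frame(channel = p$channel, area = p$area,
               r0 = p$bbox[["r0"]], r1 = p$bbox[["r1"]],
               c0 = p$bbox[["c0"]], c1 = p$bbox[["c1"]],
               centroid_row = p$centroid[[1L]],
               centroid_col = p$centroid[[2L]])))
}

#' Detect puncta of one protein channel within a GUV region
#'
#' Crops the region's bounding box (padded by `crop_pad`), runs the full
#' chain [compute_li_threshold()] -> [preprocess_crop()] ->
#' [compute_otsu_threshold()] -> [label_puncta()], and reports punctum
#' coordinates in the whole-image frame. A crop with no foreground yields
#' zero puncta, not an error.
#'
#' @param image an [mc_image()].
#' @param region one-row data.frame with `r0`, `r1`, `c0`, `c1` (0-based,
#'   half-open), e.g. one row of [detect_guvs()] output.
#' @param channel_role protein channel to analyze.
#' @param params a [pipeline_params()].
#' @return list of `punctum` objects in whole-image coordinates.
#' @export
detect_puncta_in_guv <- function(image, region, channel_role,
                                 params = pipeline_params()) {
  ch <- get_channel(image, channel_role)
  H <- nrow(ch); W <- ncol(ch)
  b <- clip_bbox(bbox(region$r0 - params$crop_pad,
                      region$r1 + params$crop_pad,
                      region$c0 - params$crop_pad,
                      region$c1 + params$crop_pad), H, W)
  crop <- ch[(b[["r0"]] + 1L):b[["r1"]], (b[["c0"]] + 1L):b[["c1"]],
             drop = FALSE]
  bg <- compute_li_threshold(crop)
  proc <- preprocess_crop(crop, bg, params, bit_depth = image$bit_depth)
  thr <- tryCatch(compute_otsu_threshold(proc),
                  guvmem_no_foreground = function(e) NULL)
  if (is.null(thr)) return(list())
  pk <- label_puncta(proc > thr, params, channel = channel_role)
  lapply(pk, function(p) {
    p$pixels[, 1L] <- p$pixels[, 1L] + b[["r0"]]
    p$pixels[, 2L] <- p$pixels[, 2L] + b[["c0"]]
    p$bbox <- bbox_from_pixels(p$pixels)
    p$centroid <- colMeans(p$pixels)
    p
  })
}

#' Proportion of GUVs with at least one punctum
#'
#' The headline read-out of the GUV binding assay: the number of GUVs with
#' at least one recognized punctum divided by the total number of
#' recognized GUVs.
#'
#' @param per_guv_puncta list with one element per GUV (each a list of
#'   puncta), or an integer vector of per-GUV punctum counts.
#' @return list with `proportion`, `n_guvs`, `n_positive`.
#' @export
proportion_guvs_with_puncta <- function(per_guv_puncta) {
  counts <- if (is.numeric(per_guv_puncta)) per_guv_puncta
            else vapply(per_guv_puncta, length, integer(1L))
  if (length(counts) == 0L) stopf("zero GUVs: proportion undefined")
  list(proportion = mean(counts >= 1L), n_guvs = length(counts),
       n_positive = sum(counts >= 1L))
}

# Shared counting rule for measured and planted colocalization: a box is
# colocalized iff it intersects at least one box of the other channel;
# n_colocalized counts colocalized boxes in the channel with the higher
# count (ties: the larger of the two counts, making the rule symmetric).
coloc_counts <- function(boxes_a, boxes_b) {
  n_a <- length(boxes_a); n_b <- length(boxes_b)
  hit <- function(bs, other) sum(vapply(bs, function(b)
    any(vapply(other, function(o) bbox_overlaps(b, o), logical(1L))),
    logical(1L)))
  c_a <- if (n_a > 0L && n_b > 0L) hit(boxes_a, boxes_b) else 0L
  c_b <- if (n_a > 0L && n_b > 0L) hit(boxes_b, boxes_a) else 0L
  n_col <- if (n_a > n_b) c_a else if (n_b > n_a) c_b else max(c_a, c_b)
  n_max <- max(n_a, n_b)
  list(n_a = n_a, n_b = n_b, n_colocalized = n_col, n_max = n_max,
       proportion = if (n_max > 0L) n_col / n_max else 0)
}

#' Bounding-box colocalization between two protein channels
#'
#' A punctum is colocalized iff its bounding box overlaps at least one
#' bounding box of the other channel. The proportion of colocalized
#' puncta is the number of colocalized puncta in the channel with the
#' highest punctum count divided by that count; when both channels are
#' empty the proportion is 0.
#'
#' @param puncta_a,puncta_b lists of `punctum` objects from the same GUV.
#' @return list of class `coloc_result` with `n_a`, `n_b`,
#'   `n_colocalized`, `n_max`, `proportion`.
#' @export
colocalize <- function(puncta_a, puncta_b) {
  res <- coloc_counts(lapply(puncta_a, `[[`, "bbox"),
                      lapply(puncta_b, `[[`, "bbox"))
  structure(res, class = "coloc_result")
}

#' Total above-threshold particle area in a cell image
#'
#' Binarizes the image at `> threshold` (thresholds are set per cell),
#' keeps connected components of at least `min_area` pixels, and returns
#' the summed component area, emulating an Analyze-Particles measurement.
#'
#' @param cell_image numeric matrix.
#' @param threshold intensity threshold (exclusive).
#' @param min_area minimum component area in px (default 1).
#' @param connectivity 4 or 8 (default 8).
#' @return total area in px.
#' @export
particle_area_above_threshold <- function(cell_image, threshold,
                                          min_area = 1L,
                                          connectivity = 8L) {
  lab <- label_components(cell_image > threshold, connectivity)
  if (max(lab) == 0L) return(0L)
  areas <- tabulate(lab[lab > 0L])
  sum(areas[areas >= min_area])
}

#' Quantify a whole scene: per-GUV puncta, proportions, colocalization
#'
#' Runs [detect_puncta_in_guv()] for every region and protein channel and
#' aggregates the assay read-outs. The overall colocalization proportion
#' pools GUVs: the sum of colocalized puncta divided by the summed
#' highest-channel counts.
#'
#' @param image an [mc_image()].
#' @param regions data.frame of GUV regions ([detect_guvs()] /
#'   [import_detections()] output).
#' @param channels protein channel roles to quantify (default: all
#'   non-lipid roles present).
#' @param params a [pipeline_params()].
#' @param image_id identifier used in the output tables.
#' @return list with `per_guv` (data.frame: image_id, guv, channel,
#'   n_puncta, total_area), `summary` (per channel: proportion, n_guvs,
#'   n_positive), `coloc` (per GUV) and `coloc_overall` (scalar or NA).
#' @export
quantify_scene <- function(image, regions,
                           channels = setdiff(image$channel_roles, "lipid"),
                           params = pipeline_params(),
                           image_id = "scene") {
  stopifnot(inherits(image, "mc_image"), length(channels) >= 1L)
  regions <- as.data.frame(regions)
  n_g <- nrow(regions)
  puncta <- lapply(channels, function(ch)
    lapply(seq_len(n_g), function(g)
      detect_puncta_in_guv(image, regions[g, ], ch, params)))
  names(puncta) <- channels
  per_guv <- do.call(rbind, lapply(channels, function(ch)
    do.call(rbind, lapply(seq_len(n_g), function(g) {
      pk <- puncta[[ch]][[g]]
      data.frame(image_id = image_id, guv = g, channel = ch,
                 n_puncta = length(pk),
                 total_area = sum(vapply(pk, `[[`, integer(1L), "area")))
    }))))
  summary <- do.call(rbind, lapply(channels, function(ch) {
    pr <- proportion_guvs_with_puncta(puncta[[ch]])
    data.frame(image_id = image_id, channel = ch,
               proportion = pr$proportion, n_guvs = pr$n_guvs,
               n_positive = pr$n_positive)
  }))
  coloc <- NULL; coloc_overall <- NA_real_
  if (length(channels) >= 2L) {
    rows <- lapply(seq_len(n_g), function(g)
      colocalize(puncta[[channels[1L]]][[g]], puncta[[channels[2L]]][[g]]))
    coloc <- data.frame(
      image_id = image_id, guv = seq_len(n_g),
      n_a = vapply(rows, `[[`, integer(1L), "n_a"),
      n_b = vapply(rows, `[[`, integer(1L), "n_b"),
      n_colocalized = vapply(rows, function(r)
        as.integer(r$n_colocalized), integer(1L)),
      n_max = vapply(rows, function(r) as.integer(r$n_max), integer(1L)),
      proportion = vapply(rows, `[[`, numeric(1L), "proportion"))
    coloc_overall <- if (sum(coloc$n_max) > 0)
      sum(coloc$n_colocalized) / sum(coloc$n_max) else 0
  }
  list(per_guv = per_guv, summary = summary, puncta = puncta,
       coloc = coloc, coloc_overall = coloc_overall)
}
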