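# Synthetic GUV scenes with planted ground truth. A scene emulates a
# confocal field of view: the lipid channel shows each vesicle as an
# annular Gaussian ring, protein channels show membrane-bound puncta as
# 2-D Gaussian spots centered on the ring, plus a constant background
# offset and additive Gaussian noise clipped to the bit-depth range.

#' Specification of a synthetic GUV scene
#'
#' @param height,width image size in px.
#' @param guvs data.frame with one row per GUV: `center_row`, `center_col`
#'   (0-based px), `radius` (px), `ring_amplitude`, `ring_thickness` (px,
#'   Gaussian sigma of the annulus profile).
#' @param puncta named list, one element per protein channel role, each a
#'   data.frame with columns `guv` (row index into `guvs`), `angle`
#'   (radians along the ring), `amplitude`, `sigma` (px).
#' @param channel_roles channel roles; must contain `"lipid"` and the
#'   names of `puncta`.
#' @param noise_sigma additive Gaussian noise SD (intensity units, >= 0).
#' @param background_offset constant background level (>= 0).
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; identical specs give bit-identical images.
#' @param allow_edge if `FALSE` (default) GUV discs must lie fully inside
#'   the frame.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(height, width, guvs, puncta = list(),
                       channel_roles = c("lipid", names(puncta)),
                       noise_sigma = 0, background_offset = 0,
                       bit_depth = 8L, seed = 1L, allow_edge = FALSE) {
  guvs <- as.data.frame(guvs)
  stopifnot(all(c("center_row", "center_col", "radius", "ring_amplitude",
                  "ring_thickness") %in% names(guvs)))
  if (noise_sigma < 0 || background_offset < 0)
    stopf("noise_sigma and background_offset must be >= 0")
  if (any(guvs$ring_amplitude < 0)) stopf("ring amplitudes must be >= 0")
  if (!"lipid" %in% channel_roles) stopf("channel_roles must include 'lipid'")
  if (!all(names(puncta) %in% channel_roles))
    stopf("every puncta channel must appear in channel_roles")
  if (!allow_edge) {
    r <- guvs$radius
    if (any(guvs$center_row - r < 0 | guvs$center_row + r >= height |
            guvs$center_col - r < 0 | guvs$center_col + r >= width))
      stopf("GUV discs must lie inside the frame (or set allow_edge)")
  }
  for (ch in names(puncta)) {
    p <- as.data.frame(puncta[[ch]])
    stopifnot(all(c("guv", "angle", "amplitude", "sigma") %in% names(p)))
    if (any(p$sigma <= 0))
      stopf("punctum sigma must be > 0", class = "guvmem_parameter_error")
    if (any(p$amplitude < 0)) stopf("punctum amplitudes must be >= 0")
    if (any(p$guv < 1 | p$guv > nrow(guvs)))
      stopf("puncta reference GUVs outside the spec")
    puncta[[ch]] <- p
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 guvs = guvs, puncta = puncta,
                 channel_roles = channel_roles,
                 noise_sigma = noise_sigma,
                 background_offset = background_offset,
                 bit_depth = as.integer(bit_depth), seed = seed),
            class = "scene_spec")
}

#' Randomized scene specification on a jittered grid
#'
#' Convenience constructor emulating a typical field of view: `n_guvs`
#' vesicles on a jittered grid with center separation at least twice the
#' maximum radius, one punctum per positive GUV and per protein channel.
#' In two-protein scenes the first `n_coloc` positive GUVs carry puncta of
#' both channels at the same ring position (planted colocalization); the
#' remaining double-positive GUVs carry them on opposite sides.
#'
#' @param seed RNG seed controlling layout and the rendered noise.
#' @param n_guvs number of vesicles.
#' @param n_positive number of GUVs given at least one punctum in the
#'   first protein channel.
#' @param channels protein channel roles (1 or 2).
#' @param n_positive_b,n_coloc second-channel positives and planted
#'   colocalized pairs (two-protein scenes only).
#' @param radius_range GUV radius range in px.
#' @param ring_amplitude,ring_thickness lipid ring parameters.
#' @param punctum_amplitude,punctum_sigma protein spot parameters.
#' @param noise_sigma,background_offset noise model (defaults give a spot
#'   SNR of 20).
#' @return a [scene_spec()].
#' @export
sample_scene_spec <- function(seed, n_guvs = 10L, n_positive = 7L,
                              channels = "proteinA",
                              n_positive_b = 5L, n_coloc = 4L,
                              radius_range = c(10, 15),
                              ring_amplitude = 140, ring_thickness = 1.6,
                              punctum_amplitude = 120, punctum_sigma = 2,
                              noise_sigma = 6, background_offset = 20) {
  stopifnot(n_positive <= n_guvs, length(channels) %in% 1:2)
  cell <- ceiling(2 * radius_range[2L] + 14)
  n_col <- ceiling(sqrt(n_guvs))
  n_row <- ceiling(n_guvs / n_col)
  with_seed(seed + 1L, {
    idx <- seq_len(n_guvs) - 1L
    gr <- idx %/% n_col
    gc <- idx %% n_col
    guvs <- data.frame(
      center_row = (gr + 0.5) * cell + runif(n_guvs, -3, 3),
      center_col = (gc + 0.5) * cell + runif(n_guvs, -3, 3),
      radius = runif(n_guvs, radius_range[1L], radius_range[2L]),
      ring_amplitude = ring_amplitude,
      ring_thickness = ring_thickness)
    angles <- runif(n_guvs, 0, 2 * pi)
    puncta <- list()
    puncta[[channels[1L]]] <- data.frame(
      guv = seq_len(n_positive), angle = angles[seq_len(n_positive)],
      amplitude = punctum_amplitude, sigma = punctum_sigma)
    if (length(channels) == 2L) {
      stopifnot(n_coloc <= n_positive_b, n_positive_b <= n_guvs)
      ang_b <- angles[seq_len(n_positive_b)]
      off <- seq_len(n_positive_b) > n_coloc
      ang_b[off] <- ang_b[off] + pi
      puncta[[channels[2L]]] <- data.frame(
        guv = seq_len(n_positive_b), angle = ang_b,
        amplitude = punctum_amplitude, sigma = punctum_sigma)
    }
    if (n_positive == 0L) puncta[[channels[1L]]] <- NULL
    scene_spec(height = n_row * cell, width = n_col * cell, guvs = guvs,
               puncta = puncta, channel_roles = c("lipid", channels),
               noise_sigma = noise_sigma,
               background_offset = background_offset, seed = seed)
  })
}

punctum_center <- function(guv, angle) {
  c(row = guv$center_row + guv$radius * sin(angle),
    col = guv$center_col + guv$radius * cos(angle))
}

# Continuous half-open box covering a planted Gaussian spot out to 2 sigma.
planted_spot_bbox <- function(center, sigma) {
  bbox(center[["row"]] - 2 * sigma, center[["row"]] + 2 * sigma,
       center[["col"]] - 2 * sigma, center[["col"]] + 2 * sigma)
}

#' Render a synthetic GUV scene
#'
#' Deterministic under the spec's seed. Returns the rendered image and a
#' `scene_truth` object holding exactly the planted GUV regions, per-channel
#' puncta, the per-channel proportion of GUVs with at least one punctum,
#' and pairwise planted colocalization (two planted spots colocalize when
#' their 2-sigma boxes overlap; the proportion uses the same
#' highest-count-channel denominator as [colocalize()]).
#'
#' @param spec a [scene_spec()].
#' @return list with elements `image` ([mc_image()]) and `truth`.
#' @export
generate_guv_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  rows <- matrix(seq_len(H) - 1L, H, W)
  cols <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  maxval <- 2^spec$bit_depth - 1
  n_ch <- length(spec$channel_roles)
  px <- array(spec$background_offset, dim = c(H, W, n_ch))

  li <- match("lipid", spec$channel_roles)
  for (g in seq_len(nrow(spec$guvs))) {
    gv <- spec$guvs[g, ]
    d <- sqrt((rows - gv$center_row)^2 + (cols - gv$center_col)^2)
    px[, , li] <- px[, , li] +
      gv$ring_amplitude * exp(-(d - gv$radius)^2 / (2 * gv$ring_thickness^2))
  }
  truth_puncta <- list()
  for (ch in names(spec$puncta)) {
    ci <- match(ch, spec$channel_roles)
    p <- spec$puncta[[ch]]
    ctrs <- t(vapply(seq_len(nrow(p)), function(i)
      punctum_center(spec$guvs[p$guv[i], ], p$angle[i]), numeric(2L)))
    for (i in seq_len(nrow(p))) {
      d2 <- (rows - ctrs[i, 1L])^2 + (cols - ctrs[i, 2L])^2
      px[, , ci] <- px[, , ci] +
        p$amplitude[i] * exp(-d2 / (2 * p$sigma[i]^2))
    }
    truth_puncta[[ch]] <- data.frame(
      guv = p$guv, center_row = ctrs[, 1L], center_col = ctrs[, 2L],
      amplitude = p$amplitude, sigma = p$sigma)
  }
  if (spec$noise_sigma > 0)
    px <- px + with_seed(spec$seed,
                         array(rnorm(length(px), 0, spec$noise_sigma),
                               dim = dim(px)))
  px <- round(pmin(pmax(px, 0), maxval))

  guv_regions <- data.frame(
    guv = seq_len(nrow(spec$guvs)),
    center_row = spec$guvs$center_row, center_col = spec$guvs$center_col,
    radius = spec$guvs$radius,
    r0 = floor(spec$guvs$center_row - spec$guvs$radius),
    r1 = ceiling(spec$guvs$center_row + spec$guvs$radius) + 1,
    c0 = floor(spec$guvs$center_col - spec$guvs$radius),
    c1 = ceiling(spec$guvs$center_col + spec$guvs$radius) + 1)

  prot <- names(spec$puncta)
  proportion <- vapply(prot, function(ch)
    length(unique(truth_puncta[[ch]]$guv)) / nrow(spec$guvs), numeric(1L))
  coloc <- NULL
  if (length(prot) >= 2L) {
    coloc <- truth_colocalization(truth_puncta[[prot[1L]]],
                                  truth_puncta[[prot[2L]]],
                                  nrow(spec$guvs))
  }
  truth <- structure(list(guvs = guv_regions, puncta = truth_puncta,
                          proportion_with_puncta = proportion,
                          colocalization = coloc),
                     class = "scene_truth")
  list(image = mc_image(px, spec$channel_roles, spec$bit_depth),
       truth = truth)
}

# Planted colocalization per GUV and overall, using the same counting rule
# as the measurement path (highest-count channel as denominator).
truth_colocalization <- function(pa, pb, n_guvs) {
  per_guv <- lapply(seq_len(n_guvs), function(g) {
    ba <- pa[pa$guv == g, , drop = FALSE]
    bb <- pb[pb$guv == g, , drop = FALSE]
    boxes_a <- lapply(seq_len(nrow(ba)), function(i)
      planted_spot_bbox(c(row = ba$center_row[i], col = ba$center_col[i]),
                        ba$sigma[i]))
    boxes_b <- lapply(seq_len(nrow(bb)), function(i)
      planted_spot_bbox(c(row = bb$center_row[i], col = bb$center_col[i]),
                        bb$sigma[i]))
    coloc_counts(boxes_a, boxes_b)
  })
  n_coloc <- vapply(per_guv, `[[`, numeric(1L), "n_colocalized")
  n_max <- vapply(per_guv, `[[`, numeric(1L), "n_max")
  data.frame(guv = seq_len(n_guvs), n_colocalized = n_coloc, n_max = n_max,
             proportion = ifelse(n_max > 0, n_coloc / n_max, 0))
}
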