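#' Multi-channel fluorescence image container
#'
#' Wraps an H x W x C stack of nonnegative intensities together with the
#' biological role of each channel. Channel roles are configuration, never
#' guessed from pixel content: the lipid channel drives GUV detection and
#' the protein channels drive puncta calling.
#'
#' @param pixels numeric H x W matrix (single channel) or H x W x C array of
#'   nonnegative intensities.
#' @param channel_roles character vector of length C; each entry one of
#'   `"lipid"`, `"proteinA"`, `"proteinB"` (other labels are allowed but
#'   ignored by the pipeline).
#' @param bit_depth integer, 8 or 16. Intensities must not exceed
#'   `2^bit_depth - 1`.
#' @param pixel_size_um optional positive pixel size in micrometres
#'   (metadata only).
#'
#' @return An object of class `mc_image`: a list with elements `pixels`
#'   (H x W x C array), `channel_roles`, `bit_depth`, `pixel_size_um`.
#' @export
mc_image <- function(pixels, channel_roles, bit_depth = 8L,
                     pixel_size_um = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("pixels must be an H x W matrix or H x W x C array",
          class = "guvmem_format_error")
  if (dim(pixels)[3L] != length(channel_roles))
    stopf("number of channels (%d) != length of channel_roles (%d)",
          dim(pixels)[3L], length(channel_roles),
          class = "guvmem_format_error")
  if (!bit_depth %in% c(8L, 16L))
    stopf("bit_depth must be 8 or 16")
  if (any(pixels < 0)) stopf("intensities must be nonnegative")
  if (any(pixels > 2^bit_depth - 1))
    stopf("intensities exceed 2^%d - 1", bit_depth)
  if (!is.null(pixel_size_um) &&
      (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0))
    stopf("pixel_size_um must be a positive scalar")
  structure(list(pixels = pixels, channel_roles = as.character(channel_roles),
                 bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mc_image> %d x %d px, %d channel(s) [%s], %d-bit\n",
              d[1L], d[2L], d[3L], paste(x$channel_roles, collapse = ", "),
              x$bit_depth))
  invisible(x)
}

#' Extract one channel of a multi-channel image by role
#'
#' @param img an [mc_image()].
#' @param role channel role to extract, e.g. `"lipid"`.
#' @return numeric matrix.
#' @export
get_channel <- function(img, role) {
  stopifnot(inherits(img, "mc_image"))
  i <- match(role, img$channel_roles)
  if (is.na(i)) stopf("no channel with role '%s'", role)
  img$pixels[, , i]
}

#' Read a multi-page TIFF as a multi-channel image
#'
#' Planes are mapped to channels in file order. Roles are taken from the
#' `channel_roles` argument or, when that is `NULL`, from a YAML sidecar
#' file `<path>.yaml` with fields `channel_roles` and optionally
#' `bit_depth` / `pixel_size_um`.
#'
#' @param path TIFF file with 1-4 planes of identical size.
#' @param channel_roles character vector of roles, one per plane, or `NULL`
#'   to read the sidecar.
#' @param bit_depth 8, 16 or `"auto"` (16 when any intensity exceeds 255).
#' @param pixel_size_um optional pixel size metadata.
#' @return an [mc_image()].
#' @export
read_multichannel_image <- function(path, channel_roles = NULL,
                                    bit_depth = "auto",
                                    pixel_size_um = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) == 0L)
    stopf("TIFF '%s' contains no image planes", path,
          class = "guvmem_format_error")
  dims <- lapply(planes, dim)
  if (any(vapply(dims, length, 1L) != 2L))
    stopf("TIFF '%s' has non-grayscale planes; expected one channel per page",
          path, class = "guvmem_format_error")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopf("TIFF '%s' has planes of mismatched shapes", path,
          class = "guvmem_format_error")
  if (is.null(channel_roles)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stopf("channel_roles not given and no sidecar '%s' found", sidecar,
            class = "guvmem_format_error")
    cfg <- yaml::read_yaml(sidecar)
    channel_roles <- cfg$channel_roles
    if (identical(bit_depth, "auto") && !is.null(cfg$bit_depth))
      bit_depth <- cfg$bit_depth
    if (is.null(pixel_size_um)) pixel_size_um <- cfg$pixel_size_um
  }
  if (length(channel_roles) != length(planes))
    stopf("TIFF '%s' has %d plane(s) but %d channel role(s) given", path,
          length(planes), length(channel_roles),
          class = "guvmem_format_error")
  px <- array(0, dim = c(dims[[1L]], length(planes)))
  for (i in seq_along(planes)) px[, , i] <- planes[[i]]
  if (identical(bit_depth, "auto"))
    bit_depth <- if (max(px) > 255) 16L else 8L
  mc_image(px, channel_roles, bit_depth = bit_depth,
           pixel_size_um = pixel_size_um)
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' Intensities are written at the image's declared bit depth; integer
#' intensities round-trip exactly. A YAML sidecar `<path>.yaml` recording
#' the channel roles is written alongside.
#'
#' @param img an [mc_image()].
#' @param path output TIFF path.
#' @param sidecar write the channel-role sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_multichannel_image <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "mc_image"))
  maxval <- 2^img$bit_depth - 1
  planes <- lapply(seq_len(dim(img$pixels)[3L]),
                   function(i) img$pixels[, , i] / maxval)
  tiff::writeTIFF(planes, path, bits.per.sample = img$bit_depth)
  if (sidecar) {
    cfg <- list(channel_roles = img$channel_roles,
                bit_depth = img$bit_depth)
    if (!is.null(img$pixel_size_um)) cfg$pixel_size_um <- img$pixel_size_um
    yaml::write_yaml(cfg, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Write a binary mask as a PNG file
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a results table as CSV with deterministic row order
#'
#' Rows are sorted by `image_id` then `region` (when those columns are
#' present) so repeated runs produce byte-identical files; floats keep full
#' precision. An empty record set yields a header-only file.
#'
#' @param records data.frame of results.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  keys <- intersect(c("image_id", "region", "guv", "channel"),
                    names(records))
  if (nrow(records) > 1L && length(keys) > 0L)
    records <- records[do.call(order, records[keys]), , drop = FALSE]
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' External detection records (import path for trained detectors)
#'
#' A `detection_record` carries externally produced GUV detections for one
#' image: circle centers, radii and bounding boxes in 0-based pixel
#' coordinates with half-open boxes. [write_detections()] /
#' [read_detections()] serialize records as JSON so detections from any
#' external detector (e.g. a trained network) can be fed to the pipeline in
#' place of [detect_guvs()].
#'
#' @param image_id character image identifier.
#' @param regions data.frame with columns `center_row`, `center_col`,
#'   `radius`, `r0`, `r1`, `c0`, `c1`.
#' @return object of class `detection_record`.
#' @export
detection_record <- function(image_id, regions) {
  regions <- as.data.frame(regions)
  need <- c("center_row", "center_col", "radius", "r0", "r1", "c0", "c1")
  if (!all(need %in% names(regions)))
    stopf("regions must have columns: %s", paste(need, collapse = ", "),
          class = "guvmem_format_error")
  structure(list(image_id = as.character(image_id), regions = regions),
            class = "detection_record")
}

#' @rdname detection_record
#' @param record a `detection_record`.
#' @param path JSON file path.
#' @export
write_detections <- function(record, path) {
  stopifnot(inherits(record, "detection_record"))
  jsonlite::write_json(list(image_id = record$image_id,
                            regions = record$regions),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname detection_record
#' @export
read_detections <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  detection_record(x$image_id, as.data.frame(x$regions))
}
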