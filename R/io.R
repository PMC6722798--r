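# Readers and writers for the formats the pipeline consumes and emits:
# 8-bit RGB TIFF/PNG fields, GeoJSON/CSV nucleus outlines, measurement and
# cohort CSVs, float-TIFF stain maps, and the YAML run configuration that
# accompanies every output.

#' Read an 8-bit RGB image (TIFF or PNG)
#'
#' Loads the raster with channel order RGB and no rescaling or gamma; an
#' alpha channel, if present, is dropped. Grayscale or 16-bit input is a
#' format error: the pipeline is calibrated for 8-bit RGB acquisition.
#'
#' @param path file path; format chosen by extension (.tif/.tiff/.png).
#' @param whiteRef white reference passed to [RGBImage()].
#' @return an [RGBImage-class].
#' @export
readRGBImage <- function(path, whiteRef = 255) {
  if (!file.exists(path))
    stop(sprintf("format error: file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(arr, "bits.per.sample")
    if (!is.null(bps) && bps != 8L)
      stop(sprintf("format error: %s has %d bits per sample; 8-bit required",
                   path, bps))
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L)
      stop(sprintf("format error: %s has bit depth %d; 8-bit required",
                   path, info$bit.depth))
  } else {
    stop(sprintf("format error: unsupported image extension '%s'", ext))
  }
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
    stop(sprintf("format error: %s is not an RGB image (grayscale or single-channel)",
                 path))
  RGBImage(round(arr[, , 1:3, drop = FALSE] * 255), whiteRef = whiteRef)
}

#' Write an RGBImage as 8-bit TIFF or PNG
#'
#' @param image an [RGBImage-class].
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
writeRGBImage <- function(image, path) {
  stopifnot(is(image, "RGBImage"))
  arr <- image@pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(arr, path)
  } else {
    stop(sprintf("format error: unsupported image extension '%s'", ext))
  }
  invisible(path)
}

# TIFF sample values live in [0, 1]; stain maps are stored divided by this
# fixed full-scale OD and multiplied back on read.
.STAIN_MAP_FULL_SCALE <- 4

#' Write a stain map as 32-bit float TIFF
#'
#' Optical densities are stored against a fixed full scale of 4 OD (sample
#' value = OD / 4), comfortably above the ~2.4 ceiling of the 8-bit OD
#' transform; [readStainMap()] restores the OD scale.
#'
#' @param map numeric \code{H x W} matrix of OD values in \code{[0, 4]}
#'   (e.g. [dabMap()]).
#' @param path output .tif path.
#' @return the path, invisibly.
#' @export
writeStainMap <- function(map, path) {
  if (min(map) < 0 || max(map) > .STAIN_MAP_FULL_SCALE)
    stop(sprintf("format error: stain map OD must lie in [0, %d]",
                 .STAIN_MAP_FULL_SCALE))
  tiff::writeTIFF(map / .STAIN_MAP_FULL_SCALE, path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a stain map written by [writeStainMap()]
#'
#' @param path .tif path.
#' @return numeric \code{H x W} matrix of OD values.
#' @export
readStainMap <- function(path) {
  if (!file.exists(path))
    stop(sprintf("format error: file not found: %s", path))
  tiff::readTIFF(path) * .STAIN_MAP_FULL_SCALE
}

#' Read nucleus outlines (GeoJSON or CSV)
#'
#' GeoJSON input is a FeatureCollection of Polygon features with
#' \code{id} and \code{field_id} properties (exterior ring only; the
#' closing vertex is dropped). CSV input has columns \code{roi_id},
#' \code{field_id}, \code{vertex_index}, \code{x}, \code{y} with one row
#' per vertex, ordered by \code{vertex_index} within each ROI.
#' Coordinates are 0-based pixel units, x rightward, y downward. The two
#' encodings of the same outlines load to identical ROI sets. Polygons are
#' validated on construction: at least 3 vertices, simple, positive area,
#' unique ids; violations name the offending ROI.
#'
#' @param path file path (.geojson/.json or .csv).
#' @return an [ROISet-class].
#' @export
readROIs <- function(path) {
  if (!file.exists(path))
    stop(sprintf("format error: ROI file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$features))
      stop("format error: GeoJSON input is not a FeatureCollection")
    polys <- list(); ids <- character(0); fids <- character(0)
    for (ft in gj$features) {
      if (!identical(ft$geometry$type, "Polygon"))
        stop(sprintf("format error: unsupported geometry type '%s'",
                     ft$geometry$type))
      ring <- ft$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(v)
        c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
      if (nrow(m) >= 2L && all(m[1, ] == m[nrow(m), ]))
        m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y")
      polys[[length(polys) + 1L]] <- m
      ids <- c(ids, as.character(ft$properties$id))
      fid <- ft$properties$field_id
      fids <- c(fids, if (is.null(fid)) "field_1" else as.character(fid))
    }
    roiSet(polys, ids = ids, fieldIds = fids)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("roi_id", "field_id", "vertex_index", "x", "y")
    if (!all(needed %in% names(df)))
      stop("format error: ROI CSV must have columns ",
           paste(needed, collapse = ", "))
    ord <- unique(df$roi_id)
    polys <- lapply(ord, function(id) {
      sub <- df[df$roi_id == id, ]
      sub <- sub[order(sub$vertex_index), ]
      cbind(x = sub$x, y = sub$y)
    })
    fids <- vapply(ord, function(id) df$field_id[df$roi_id == id][1],
                   character(1))
    roiSet(polys, ids = ord, fieldIds = unname(fids))
  } else {
    stop(sprintf("format error: unsupported ROI extension '%s'", ext))
  }
}

#' Write nucleus outlines as GeoJSON
#'
#' @param rois an [ROISet-class].
#' @param path output .geojson path.
#' @return the path, invisibly.
#' @export
writeROIsGeoJSON <- function(rois, path) {
  stopifnot(is(rois, "ROISet"))
  features <- lapply(seq_len(length(rois)), function(i) {
    poly <- rois@polygons[[i]]
    ring <- lapply(seq_len(nrow(poly)), function(k)
      c(poly[k, 1], poly[k, 2]))
    ring[[length(ring) + 1L]] <- ring[[1L]]  # close the ring
    list(type = "Feature",
         properties = list(id = rois@ids[i], field_id = rois@fieldIds[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a measurement or cohort table as CSV
#'
#' Deterministic CSV: '.' decimal separator, no quoting of numbers, LF
#' newlines, UTF-8 — reruns from the same configuration and seed are
#' byte-identical.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTableCSV <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Assemble and validate a run configuration
#'
#' Collects every tunable of the pipeline, validates each against the
#' corresponding module's preconditions, and returns a named list ready to
#' be serialized next to any output ([writeRunConfig()]).
#'
#' @param stainPreset name of the stain-vector preset ("h-dab") or NULL
#'   when custom vectors are given.
#' @param hematoxylin,dab custom stain vectors (numeric(3) each); override
#'   the preset when both are supplied.
#' @param gridNx,gridNy grid size (defaults 24 x 18).
#' @param threshold,detectionFloor positivity rule (defaults 0.1 and 0).
#' @param intensityBins intensity-score bin edges
#'   (default \code{c(0.1, 0.4, 0.7)}).
#' @param minFields minimum fields per case before warning (default 10).
#' @param whiteRef white reference I0 (default 255).
#' @param seed integer seed recorded with outputs.
#' @return named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(stainPreset = "h-dab", hematoxylin = NULL, dab = NULL,
                      gridNx = 24, gridNy = 18, threshold = 0.1,
                      detectionFloor = 0, intensityBins = c(0.1, 0.4, 0.7),
                      minFields = 10, whiteRef = 255, seed = 1L) {
  if (!is.null(hematoxylin) && !is.null(dab)) {
    m <- stainMatrix(hematoxylin, dab)
    stainPreset <- "custom"
  } else if (identical(stainPreset, "h-dab")) {
    m <- hdabStainMatrix()
  } else {
    stop(sprintf("config error: unknown stain preset '%s'", stainPreset))
  }
  rule <- positivityRule(threshold, detectionFloor)  # validates bounds
  if (gridNx < 1 || gridNy < 1)
    stop("config error: grid must be at least 1 x 1")
  if (any(whiteRef <= 0))
    stop("config error: white reference must be positive")
  cfg <- list(stainPreset = stainPreset,
              hematoxylin = unname(stainVectors(m)["hematoxylin", ]),
              dab = unname(stainVectors(m)["dab", ]),
              gridNx = as.integer(gridNx), gridNy = as.integer(gridNy),
              threshold = threshold, detectionFloor = detectionFloor,
              intensityBins = intensityBins,
              minFields = as.integer(minFields),
              whiteRef = whiteRef, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Serialize a run configuration as YAML
#'
#' @param config a [runConfig()] list.
#' @param path output .yaml path.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Values are re-validated through [runConfig()].
#'
#' @param path .yaml file written by [writeRunConfig()] or hand-edited.
#' @return a \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config error: file not found: %s", path))
  y <- yaml::read_yaml(path)
  runConfig(stainPreset = if (identical(y$stainPreset, "custom")) NULL
                          else y$stainPreset,
            hematoxylin = if (identical(y$stainPreset, "custom"))
                            y$hematoxylin else NULL,
            dab = if (identical(y$stainPreset, "custom")) y$dab else NULL,
            gridNx = y$gridNx %||% 24, gridNy = y$gridNy %||% 18,
            threshold = y$threshold %||% 0.1,
            detectionFloor = y$detectionFloor %||% 0,
            intensityBins = y$intensityBins %||% c(0.1, 0.4, 0.7),
            minFields = y$minFields %||% 10,
            whiteRef = y$whiteRef %||% 255, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
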