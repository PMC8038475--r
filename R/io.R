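#' Export an image or fringe pattern as 8/16-bit grayscale PNG or TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the maximum unless the input is a
#' `camera_frame` (already in `[0, 1]`). A YAML sidecar with the physical
#' metadata is written next to the image.
#'
#' @param x `fringe_pattern`, `camera_frame`, or numeric matrix.
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @param bits 8 or 16 (PNG); TIFF is written as 32-bit float.
#' @param sidecar Write the YAML sidecar? Default `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(x, path, bits = 16, sidecar = TRUE) {
  meta <- list(class = class(x)[1])
  if (inherits(x, "fringe_pattern")) {
    img <- x$intensity / max(x$intensity)
    meta <- c(meta, list(pitch_mm = x$pitch,
                         predicted_intensity_frequency = x$predicted_intensity_frequency,
                         predicted_radius_mm = x$predicted_radius,
                         source = x$source,
                         peak_intensity = max(x$intensity)))
  } else if (inherits(x, "camera_frame")) {
    img <- x$pixels
    meta <- c(meta, list(pitch_mm = x$pitch), x$meta[c("full_scale",
                                                       "clipped_fraction",
                                                       "rng_seed", "f0")])
  } else {
    img <- x / max(x)
    meta <- c(meta, list(peak = max(x)))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path, dpi = NULL)
    if (bits == 16) {
      # png::writePNG writes 16 bit when given an integer-scaled raw; the
      # default double input yields 8 bit, so rescale explicitly
      png::writePNG(round(img * 65535) / 65535, path)
    }
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 32, compression = "none")
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (sidecar) {
    yaml::write_yaml(meta, paste0(tools::file_path_sans_ext(path), ".yaml"))
  }
  invisible(path)
}

#' Save / load a float array losslessly
#'
#' The authoritative numeric container: IEEE double binary (little endian)
#' with a YAML sidecar recording the dimensions, so round trips are
#' bit-exact (8/16-bit image exports are for visualization only).
#'
#' @param m Numeric matrix.
#' @param path Output path (conventionally `.f64`); the sidecar is
#'   `<path>.yaml`.
#' @return `save_array`: invisibly `path`; `load_array`: the matrix.
#' @export
save_array <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(m), con, size = 8, endian = "little")
  yaml::write_yaml(list(nrow = nrow(m), ncol = ncol(m), type = "float64",
                        endian = "little", order = "column-major"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_array
#' @export
load_array <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = meta$nrow * meta$ncol, size = 8,
               endian = "little")
  matrix(v, meta$nrow, meta$ncol)
}

# ---- run configuration ------------------------------------------------------

config_schema <- list(
  optical = c("wavelength", "grating_period", "grating_slit", "focal_length",
              "illum_diameter", "z0", "z1", "z2", "z3", "filter_order",
              "filter_slit_width"),
  geometry = c("L", "D", "f0", "axis"),
  scene = c("direct_albedo", "scatter_fraction", "scatter_sigma",
            "background_lux", "laser_power", "texture_amp", "texture_scale",
            "texture_seed"),
  camera = c("filter_on", "filter_center", "filter_fwhm", "polarizer_on",
             "polarizer_angle", "shot_noise", "read_noise", "bit_depth",
             "exposure_headroom"),
  reconstruction = c("carrier", "half_width", "half_width_transverse",
                     "mask_threshold", "border_margin", "edge_erode"),
  run = c("seed", "out_dir", "n", "pitch", "extent")
)

#' Load and validate a run configuration
#'
#' Reads a YAML document with (optional) sections `optical`, `geometry`,
#' `scene`, `camera`, `reconstruction` and `run`, validates every key against
#' the schema, fills defaults by constructing the corresponding objects, and
#' returns them. Unknown keys and invalid values are rejected with the
#' offending field path.
#'
#' @param path Path to a YAML file, or a list already parsed.
#' @return An object of class `run_config`: list with elements `optical`
#'   ([optical_setup()]), `geometry` ([projection_geometry()]), `scene`
#'   ([photometric_scene()]), `camera` ([camera_model()]), `reconstruction`
#'   (list of options) and `run` (list), plus `$raw` (the document as read).
#' @export
load_config <- function(path) {
  doc <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  unknown_sections <- setdiff(names(doc), names(config_schema))
  if (length(unknown_sections)) {
    stop("unknown config section(s): ", paste(unknown_sections, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(doc)) {
    bad <- setdiff(names(doc[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste(paste0(sec, ".", bad), collapse = ", "), call. = FALSE)
    }
  }
  build <- function(fn, args, sec) {
    tryCatch(do.call(fn, args %||% list()),
             error = function(e) {
               stop(sprintf("invalid `%s` configuration: %s", sec,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  out <- list(
    optical = build(optical_setup, doc$optical, "optical"),
    geometry = build(projection_geometry, doc$geometry, "geometry"),
    scene = build(photometric_scene, doc$scene, "scene"),
    camera = build(camera_model, doc$camera, "camera"),
    reconstruction = doc$reconstruction %||% list(),
    run = doc$run %||% list(seed = 1),
    raw = doc
  )
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration back to YAML
#'
#' Writes the raw document (so a parse -> serialize -> parse round trip is
#' the identity).
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Save reconstruction artifacts with a manifest
#'
#' Writes the height grid as the lossless float container, the diagnostics
#' as YAML, optional visualization images, and a manifest listing every file
#' with its MD5 checksum.
#'
#' @param result A `reconstruction_result` (or a list of named matrices).
#' @param dir Output directory (created).
#' @param config Optional `run_config` embedded alongside.
#' @return Invisibly, the manifest path.
#' @export
save_artifacts <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (inherits(result, "reconstruction_result")) {
    p <- file.path(dir, "height.f64")
    save_array(result$surface$heights, p)
    files <- c(files, p, paste0(p, ".yaml"))
    pm <- file.path(dir, "mask.f64")
    save_array(result$surface$mask + 0, pm)
    files <- c(files, pm, paste0(pm, ".yaml"))
    dy <- file.path(dir, "diagnostics.yaml")
    d <- result$diagnostics
    d$carrier$peak_ratio <- unname(d$carrier$peak_ratio)
    yaml::write_yaml(d, dy)
    files <- c(files, dy)
  } else if (is.list(result)) {
    for (nm in names(result)) {
      p <- file.path(dir, paste0(nm, ".f64"))
      save_array(result[[nm]], p)
      files <- c(files, p, paste0(p, ".yaml"))
    }
  }
  if (!is.null(config)) {
    pc <- file.path(dir, "config.yaml")
    save_config(config, pc)
    files <- c(files, pc)
  }
  manifest <- file.path(dir, "MANIFEST.yaml")
  yaml::write_yaml(
    list(package = "fringeftp",
         version = as.character(utils::packageVersion("fringeftp")),
         files = lapply(files, function(f) {
           list(path = basename(f), md5 = unname(tools::md5sum(f)))
         })),
    manifest)
  invisible(manifest)
}
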