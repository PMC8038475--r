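#' Michelson contrast of a fringe image
#'
#' `(Imax - Imin) / (Imax + Imin)` with robust extrema (1st and 99th
#' percentile) inside the mask. A constant image has contrast 0.
#'
#' @param image Numeric matrix or `camera_frame`.
#' @param mask Logical matrix; default all pixels.
#' @param robust Use 1st/99th percentile extrema (default); `FALSE` uses the
#'   exact minimum and maximum (appropriate for noise-free analytic
#'   patterns).
#' @return Contrast in `[0, 1]`.
#' @export
michelson_contrast <- function(image, mask = NULL, robust = TRUE) {
  if (inherits(image, "camera_frame")) image <- image$pixels
  if (inherits(image, "fringe_pattern")) image <- image$intensity
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  q <- if (robust) {
    stats::quantile(image[mask], c(0.01, 0.99), names = FALSE)
  } else {
    range(image[mask])
  }
  if (q[1] + q[2] <= 0) return(0)
  max((q[2] - q[1]) / (q[2] + q[1]), 0)
}

#' Height RMSE between a reconstructed and a true surface
#'
#' Root-mean-square height difference over the joint mask after removing the
#' global offset implied by the reference convention (the mean difference).
#'
#' @param reconstructed,truth [surface_map()]s on the same grid.
#' @param mask Optional extra logical mask intersected with both surface
#'   masks.
#' @return List `rmse_mm`, `rmse_pct` (percent of the true peak height),
#'   `offset_mm` (the removed offset), `n` (pixels compared).
#' @export
surface_rmse <- function(reconstructed, truth, mask = NULL) {
  stopifnot(inherits(reconstructed, "surface_map"),
            inherits(truth, "surface_map"))
  if (!all(dim(truth$heights) == dim(reconstructed$heights))) {
    stop("surfaces are on different grids", call. = FALSE)
  }
  sel <- reconstructed$mask & truth$mask
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("empty evaluation mask", call. = FALSE)
  d <- reconstructed$heights[sel] - truth$heights[sel]
  off <- mean(d)
  rmse <- sqrt(mean((d - off)^2))
  peak <- max(abs(truth$heights[sel]))
  list(rmse_mm = rmse,
       rmse_pct = 100 * rmse / peak,
       offset_mm = off,
       n = sum(sel))
}

#' Qualitative accuracy grade from a reconstruction RMSE
#'
#' Declared convention mapping the relative height RMSE to the qualitative
#' grades used for reporting: High <= 5% of peak height, Moderate <= 10%,
#' Low <= 25%, else Unable. A failed reconstruction (no carrier) is Unable.
#'
#' @param rmse_pct RMSE as percent of peak height, or `NA` for a failed
#'   reconstruction.
#' @param thresholds Numeric vector `c(high, moderate, low)` in percent.
#' @return One of `"High"`, `"Moderate"`, `"Low"`, `"Unable"`.
#' @export
grade_accuracy <- function(rmse_pct, thresholds = c(5, 10, 25)) {
  if (!is.finite(rmse_pct)) return("Unable")
  if (rmse_pct <= thresholds[1]) "High"
  else if (rmse_pct <= thresholds[2]) "Moderate"
  else if (rmse_pct <= thresholds[3]) "Low"
  else "Unable"
}

#' Render-and-reconstruct one experiment cell
#' @keywords internal
run_cell <- function(surface, geom, scene, camera, seed,
                     reference_frames = TRUE) {
  frame <- render_frame(surface, geom, scene, camera, rng_seed = seed)
  ref <- NULL
  if (reference_frames) {
    flat <- surface_map(matrix(0, surface$nrow, surface$ncol), surface$pitch,
                        mask = matrix(TRUE, surface$nrow, surface$ncol))
    ref <- render_frame(flat, geom, scene, camera, rng_seed = seed + 1000L)
  }
  contrast <- michelson_contrast(frame, mask = surface$mask)
  rec <- tryCatch(reconstruct(frame, geom, reference = ref),
                  error = function(e) e)
  if (inherits(rec, "error")) {
    return(list(contrast = contrast, rmse_mm = NA_real_, rmse_pct = NA_real_,
                failure = conditionMessage(rec)))
  }
  err <- tryCatch(surface_rmse(rec$surface, surface),
                  error = function(e) NULL)
  if (is.null(err)) {
    return(list(contrast = contrast, rmse_mm = NA_real_, rmse_pct = NA_real_,
                failure = "empty evaluation mask"))
  }
  list(contrast = contrast, rmse_mm = err$rmse_mm, rmse_pct = err$rmse_pct,
       failure = NA_character_)
}

#' Run the synthetic experiment matrix
#'
#' Renders and reconstructs one-shot frames of a face phantom over a grid of
#' conditions - carrier frequency, background illuminance, filter+polarizer
#' on/off, static or moving subject - and grades each cell. Dynamic cells
#' render `dynamic_frames` rigidly moved copies of the phantom and keep the
#' worst single-frame grade (the one-shot property: motion only changes the
#' ground truth per frame). Individual cell failures are recorded as grade
#' `"Unable"`; they never abort the matrix. The projector power is raised
#' five-fold for the 1.0 cycles/mm cells, matching the experimental
#' protocol at the higher carrier frequency.
#'
#' @param f0 Carrier frequencies on the reference plane, cycles/mm.
#' @param background_lux Background illuminance levels (Lux-equivalent).
#' @param filter_polarizer Logical vector: filter and polarizer mounted?
#' @param state `"static"`, `"dynamic"` or both.
#' @param geom Base [projection_geometry()] (its `f0` is overridden).
#' @param scene Base [photometric_scene()] (its `background_lux` and
#'   `laser_power` are overridden per cell).
#' @param seed Base seed; every cell derives its own deterministic seed.
#' @param pitch Rendering pitch in mm.
#' @param extent Face phantom extent in mm.
#' @param dynamic_frames Frames per dynamic cell (default 5).
#' @param thresholds Grade thresholds, see [grade_accuracy()].
#' @return A data.frame of class `experiment_matrix` with one row per cell:
#'   config id, f0, background, filter/polarizer flag, state, fringe
#'   contrast, RMSE (mm and % of peak) and grade.
#' @export
run_matrix <- function(f0 = c(0.3, 1.0),
                       background_lux = c(0, 50, 175, 200),
                       filter_polarizer = c(TRUE, FALSE),
                       state = c("static", "dynamic"),
                       geom = projection_geometry(),
                       scene = photometric_scene(),
                       seed = 1,
                       pitch = 0.25,
                       extent = 150,
                       dynamic_frames = 5,
                       thresholds = c(5, 10, 25)) {
  grid <- expand.grid(f0 = f0, background_lux = background_lux,
                      filter_polarizer = filter_polarizer, state = state,
                      stringsAsFactors = FALSE)
  face <- make_face_phantom(seed, pitch = pitch, extent = extent)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    geom_i <- projection_geometry(L = geom$L, D = geom$D, f0 = g$f0)
    scene_i <- scene
    scene_i$background_lux <- g$background_lux
    scene_i$laser_power <- if (g$f0 >= 1.0) 5 * scene$laser_power else scene$laser_power
    cam <- camera_model(filter_on = g$filter_polarizer,
                        polarizer_on = g$filter_polarizer)
    cell_seed <- seed + 97L * i
    if (g$state == "static") {
      surfaces <- list(face)
    } else {
      set.seed(cell_seed)
      surfaces <- lapply(seq_len(dynamic_frames), function(k) {
        shift_surface(face,
                      dx = stats::runif(1, -5, 5),
                      dy = stats::runif(1, -5, 5),
                      angle = stats::runif(1, -2, 2) * pi / 180)
      })
    }
    res <- lapply(seq_along(surfaces), function(k) {
      run_cell(surfaces[[k]], geom_i, scene_i, cam, seed = cell_seed + k)
    })
    rmse_pct <- vapply(res, `[[`, numeric(1), "rmse_pct")
    worst <- if (all(is.na(rmse_pct))) NA_integer_ else which.max(
      ifelse(is.na(rmse_pct), Inf, rmse_pct))
    if (any(is.na(rmse_pct))) worst <- which(is.na(rmse_pct))[1]
    rows[[i]] <- data.frame(
      config = sprintf("f%.1f_E%d_%s_%s", g$f0, g$background_lux,
                       if (g$filter_polarizer) "fp" else "raw", g$state),
      f0 = g$f0,
      background_lux = g$background_lux,
      filter_polarizer = g$filter_polarizer,
      state = g$state,
      contrast = mean(vapply(res, `[[`, numeric(1), "contrast")),
      rmse_mm = if (is.na(worst)) NA_real_ else res[[worst]]$rmse_mm,
      rmse_pct = if (is.na(worst)) NA_real_ else res[[worst]]$rmse_pct,
      grade = grade_accuracy(if (is.na(worst)) NA_real_ else
        res[[worst]]$rmse_pct, thresholds),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_matrix", "data.frame")
  out
}

#' Write an experiment matrix as CSV and a markdown table
#'
#' @param matrix_result An `experiment_matrix` from [run_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_matrix_tables <- function(matrix_result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "experiment_matrix.csv")
  utils::write.csv(matrix_result, csv, row.names = FALSE)
  md <- file.path(dir, "experiment_matrix.md")
  f <- function(x) ifelse(is.na(x), "n/a", sprintf("%.2f", x))
  lines <- c(
    "| State | E (Lux) | f0 (/mm) | Filter+Polarizer | Contrast | RMSE (mm) | RMSE (%) | Grade |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %g | %g | %s | %s | %s | %s | %s |",
            matrix_result$state, matrix_result$background_lux,
            matrix_result$f0,
            ifelse(matrix_result$filter_polarizer, "Yes", "No"),
            f(matrix_result$contrast), f(matrix_result$rmse_mm),
            f(matrix_result$rmse_pct), matrix_result$grade))
  writeLines(lines, md)
  invisible(c(csv, md))
}
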