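#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving voxel data and voxel sizes
#' exactly on round-trip. Masks are written as uint8 and read back as
#' logical.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param data Numeric array (3D or 4D).
#' @param voxel_mm Voxel size in mm per spatial axis.
#' @return `read_volume()`: list with `data` (numeric array) and
#'   `voxel_mm`. `write_volume()` and `write_mask()`: the path,
#'   invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  list(data = array(as.numeric(img), dim = d),
       voxel_mm = RNifti::pixdim(img)[seq_len(min(3L, length(d)))])
}

#' @rdname read_volume
#' @export
write_volume <- function(data, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep_len(voxel_mm, length(dim(data)))[seq_len(min(3L, length(dim(data))))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param mask Logical array.
#' @export
write_mask <- function(mask, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- rep_len(voxel_mm, 3L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  list(data = array(v$data != 0, dim = dim(v$data)), voxel_mm = v$voxel_mm)
}

#' Check that a mask shares the analysis grid
#'
#' @param volume Numeric array.
#' @param mask Array expected on the same grid.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`; errors with an explicit message on mismatch.
#' @export
check_same_grid <- function(volume, mask, what = "mask") {
  if (!identical(dim(volume), dim(mask))) {
    stop_mq(sprintf(
      "%s grid %s does not match volume grid %s; masks must be co-registered, no resampling is performed",
      what, paste(dim(mask), collapse = "x"),
      paste(dim(volume), collapse = "x")))
  }
  invisible(TRUE)
}

#' Histology scene ground truth as JSON
#'
#' @param scene A `histo_scene`.
#' @param path Output `.json` path.
#' @return `write_scene()`: the path, invisibly; `read_scene()`: the
#'   reconstructed `histo_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "histo_scene"))
  payload <- list(
    schema = "mpioquant/histo_scene/1",
    field_um = scene$field_um, pixel_size_um = scene$pixel_size_um,
    vessels = scene$vessels, macrophages = scene$macrophages,
    single_mpio = scene$single_mpio,
    dist = unclass(scene$dist), seed = scene$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_xy <- data.frame(x = numeric(), y = numeric())
  structure(
    list(field_um = p$field_um, pixel_size_um = p$pixel_size_um,
         vessels = as.data.frame(p$vessels),
         macrophages = as.data.frame(p$macrophages),
         single_mpio = if (length(p$single_mpio)) as.data.frame(p$single_mpio)
                       else empty_xy,
         dist = structure(p$dist, class = "distance_distribution"),
         seed = p$seed),
    class = "histo_scene")
}

#' Write a rendered micrograph with pixel-size sidecar
#'
#' Saves the RGB render as PNG and a JSON sidecar recording the pixel
#' size, so segmentations of re-read images keep physical units.
#'
#' @param image Array from [render_histo()].
#' @param path Output `.png` path; the sidecar is `<path>.json`.
#' @return `write_render()`: the path, invisibly; `read_render()`: the
#'   image with its `pixel_size_um` attribute restored.
#' @export
write_render <- function(image, path) {
  png::writePNG(image, path)
  jsonlite::write_json(list(pixel_size_um = attr(image, "pixel_size_um")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_render
#' @export
read_render <- function(path) {
  img <- png::readPNG(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(img, "pixel_size_um") <-
      jsonlite::read_json(sidecar)$pixel_size_um
  }
  img
}

#' Write a cohort table as CSV
#'
#' UTF-8, comma-separated, header row, `.` decimal separator.
#'
#' @param table A [cohort_table()] data frame.
#' @param path Output `.csv` path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
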