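#' Field container I/O
#'
#' Every gridded object is stored as a NIfTI volume (voxel size in the
#' header) plus a JSON sidecar (`<path>.json`) carrying the full-precision
#' spatial metadata, units and type-specific fields; complex fields are
#' stored as paired real/imaginary volumes along a trailing dimension.
#' Reading refuses to proceed when the sidecar or any mandatory field is
#' missing -- there are no silent defaults. Round-trips are exact: NIfTI
#' headers hold voxel sizes in single precision, so the sidecar is
#' authoritative.
#'
#' @param x the object to write.
#' @param path output path (`.nii` or `.nii.gz`); the sidecar is written next
#'   to it.
#' @return `write_*` return `path` invisibly; `read_*` return the typed
#'   object.
#' @name field_io
NULL

write_meta <- function(meta, path) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_meta <- function(path, required) {
  jp <- paste0(path, ".json")
  if (!file.exists(jp))
    stop("missing sidecar ", jp, "; refusing to load without metadata")
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("sidecar ", jp, " lacks mandatory metadata: ",
         paste(miss, collapse = ", "))
  # JSON has no int/double distinction; all numeric metadata is double here
  lapply(meta, function(v) if (is.numeric(v)) as.numeric(v) else v)
}

write_nii <- function(arr, voxel_size, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size, min(3L, length(dim(arr))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nii <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' @rdname field_io
#' @export
write_label_map <- function(x, path) {
  stopifnot(inherits(x, "fus_label_map"))
  write_nii(x$labels, x$voxel_size, path)
  write_meta(list(type = "label_map", voxel_size_mm = x$voxel_size,
                  origin_mm = x$origin, label_key = as.list(x$label_key)),
             path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_label_map <- function(path) {
  meta <- read_meta(path, c("type", "voxel_size_mm", "origin_mm", "label_key"))
  if (meta$type != "label_map") stop("not a label map container: ", path)
  arr <- read_nii(path)
  storage.mode(arr) <- "integer"
  label_map(arr, meta$voxel_size_mm, meta$origin_mm, unlist(meta$label_key))
}

#' @rdname field_io
#' @export
write_voxel_model <- function(x, path) {
  stopifnot(inherits(x, "fus_voxel_model"))
  d <- dim(x$speed)
  arr <- array(c(x$speed, x$attenuation, x$density, as.numeric(x$labels)),
               c(d, 4))
  write_nii(arr, x$voxel_size, path)
  write_meta(list(type = "voxel_model", voxel_size_mm = x$voxel_size,
                  origin_mm = x$origin, frequency_Hz = x$frequency,
                  volumes = c("speed", "attenuation", "density", "labels"),
                  label_key = as.list(x$label_key)), path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_voxel_model <- function(path) {
  meta <- read_meta(path, c("type", "voxel_size_mm", "origin_mm", "frequency_Hz"))
  if (meta$type != "voxel_model") stop("not a voxel model container: ", path)
  arr <- read_nii(path)
  d <- dim(arr)[1:3]
  labels <- array(as.integer(arr[, , , 4]), d)
  structure(list(speed = array(arr[, , , 1], d),
                 attenuation = array(arr[, , , 2], d),
                 density = array(arr[, , , 3], d),
                 voxel_size = meta$voxel_size_mm, origin = meta$origin_mm,
                 frequency = meta$frequency_Hz, labels = labels,
                 label_key = unlist(meta$label_key)),
            class = "fus_voxel_model")
}

#' @rdname field_io
#' @export
write_pressure_plane <- function(x, path) {
  stopifnot(inherits(x, "fus_pressure_plane"))
  arr <- array(c(Re(x$values), Im(x$values)), c(dim(x$values), 2))
  write_nii(arr, x$pixel_size, path)
  write_meta(list(type = "pressure_plane", pixel_size_mm = x$pixel_size,
                  plane_z_mm = x$plane_z, frequency_Hz = x$frequency,
                  origin_xy_mm = x$origin_xy, volumes = c("re", "im")), path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_pressure_plane <- function(path) {
  meta <- read_meta(path, c("type", "pixel_size_mm", "plane_z_mm", "frequency_Hz"))
  if (meta$type != "pressure_plane") stop("not a pressure plane container: ", path)
  arr <- read_nii(path)
  pressure_plane(matrix(complex(real = arr[, , 1], imaginary = arr[, , 2]),
                        dim(arr)[1], dim(arr)[2]),
                 meta$pixel_size_mm, meta$plane_z_mm, meta$frequency_Hz,
                 meta$origin_xy_mm)
}

#' @rdname field_io
#' @export
write_pressure_volume <- function(x, path) {
  stopifnot(inherits(x, "fus_pressure_volume"))
  arr <- array(c(Re(x$values), Im(x$values)), c(dim(x$values), 2))
  write_nii(arr, x$voxel_size, path)
  write_meta(list(type = "pressure_volume", voxel_size_mm = x$voxel_size,
                  origin_mm = x$origin, frequency_Hz = x$frequency,
                  volumes = c("re", "im")), path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_pressure_volume <- function(path) {
  meta <- read_meta(path, c("type", "voxel_size_mm", "origin_mm", "frequency_Hz"))
  if (meta$type != "pressure_volume") stop("not a pressure volume container: ", path)
  arr <- read_nii(path)
  d <- dim(arr)[1:3]
  pressure_volume(array(complex(real = arr[, , , 1], imaginary = arr[, , , 2]), d),
                  meta$voxel_size_mm, meta$origin_mm, meta$frequency_Hz)
}

#' @rdname field_io
#' @export
write_q_volume <- function(x, path) {
  stopifnot(inherits(x, "fus_q_volume"))
  write_nii(x$Q, x$voxel_size, path)
  write_meta(list(type = "q_volume", voxel_size_mm = x$voxel_size,
                  origin_mm = x$origin, units = "W/m^3"), path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_q_volume <- function(path) {
  meta <- read_meta(path, c("type", "voxel_size_mm", "origin_mm"))
  if (meta$type != "q_volume") stop("not a power deposition container: ", path)
  structure(list(Q = read_nii(path), voxel_size = meta$voxel_size_mm,
                 origin = meta$origin_mm), class = "fus_q_volume")
}

#' @rdname field_io
#' @export
write_temperature_series <- function(x, path) {
  stopifnot(inherits(x, "fus_temperature_series"))
  write_nii(x$fields, x$voxel_size, path)
  write_meta(list(type = "temperature_series", voxel_size_mm = x$voxel_size,
                  origin_mm = x$origin, times_s = x$times, units = "degC rise"),
             path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_temperature_series <- function(path) {
  meta <- read_meta(path, c("type", "voxel_size_mm", "origin_mm", "times_s"))
  if (meta$type != "temperature_series") stop("not a temperature series container: ", path)
  temperature_series(meta$times_s, read_nii(path), meta$voxel_size_mm,
                     meta$origin_mm)
}

#' Export one temperature frame as a plain NIfTI volume
#' @param x a [temperature_series()].
#' @param frame frame index.
#' @param path output path.
#' @export
export_temperature_frame <- function(x, frame, path) {
  stopifnot(inherits(x, "fus_temperature_series"))
  write_nii(x$fields[, , , frame], x$voxel_size, path)
}
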