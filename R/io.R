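#' Read a point set from CSV or cellfinder-style XML
#'
#' CSV files must carry a header with columns `x_um`, `y_um`, `z_um` and
#' optionally `intensity` ('.' decimal separator, UTF-8). Cellfinder-style
#' XML marker files store voxel indices; these are converted to
#' micrometres at the declared voxel size (marker index i owns the voxel
#' starting at `i * voxel_size`, and the point is placed at the voxel
#' corner so the CSV round trip is exact).
#'
#' @param path file path.
#' @param format `"csv"` or `"cellfinder-xml"` (guessed from the file
#'   extension by default).
#' @param voxel_size_um voxel size for voxel-indexed XML input.
#' @param animal_id,channel metadata attached to the returned set.
#' @return data.frame with `x_um`, `y_um`, `z_um`, `intensity` and
#'   attributes `animal_id`, `channel`.
#' @export
read_points <- function(path, format = c("auto", "csv", "cellfinder-xml"),
                        voxel_size_um = 25, animal_id = NULL,
                        channel = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE))
      "cellfinder-xml" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("x_um", "y_um", "z_um")
    if (!all(need %in% names(df)))
      stop("point CSV lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    bad <- which(!stats::complete.cases(df[, need]) |
                   !apply(sapply(df[, need], is.finite), 1, all))
    if (length(bad))
      stop("malformed point row at line ", bad[1] + 1L, " of ", path)
    if (is.null(df$intensity)) df$intensity <- NA_real_
  } else {
    doc <- xml2::read_xml(path)
    mk <- xml2::xml_find_all(doc, ".//Marker")
    if (length(mk) == 0) {
      df <- data.frame(x_um = numeric(0), y_um = numeric(0),
                       z_um = numeric(0), intensity = numeric(0))
    } else {
      num <- function(tag) as.numeric(xml2::xml_text(
        xml2::xml_find_first(mk, tag)))
      vs <- rep(as.numeric(voxel_size_um), length.out = 3)
      df <- data.frame(x_um = num("MarkerX") * vs[1],
                       y_um = num("MarkerY") * vs[2],
                       z_um = num("MarkerZ") * vs[3],
                       intensity = NA_real_)
      if (anyNA(df$x_um) || anyNA(df$y_um) || anyNA(df$z_um))
        stop("malformed Marker element in ", path)
    }
  }
  attr(df, "animal_id") <- animal_id
  attr(df, "channel") <- channel
  df
}

#' Write a point set to CSV
#'
#' @param points data.frame with at least `x_um`, `y_um`, `z_um`; the
#'   standard columns plus `intensity` are written.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  cols <- intersect(c("x_um", "y_um", "z_um", "intensity"), names(points))
  utils::write.csv(points[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write region counts to long-format CSV
#' @param counts a `region_counts` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a synthetic cohort to plain-text files
#'
#' One CSV per animal and channel (`<animal>_<channel>.csv` with columns
#' `x_um,y_um,z_um,intensity`), a cohort metadata CSV
#' (`animal_id,condition,severity,bms`) and the design echoed as JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aid in names(cohort$animals))
    for (ch in names(cohort$animals[[aid]]))
      write_points(cohort$animals[[aid]][[ch]],
                   file.path(dir, paste0(aid, "_", ch, ".csv")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  design <- cohort$design
  class(design) <- NULL
  jsonlite::write_json(design, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write / read an annotation volume as multi-page TIFF with a JSON sidecar
#'
#' The label array is stored as 16-bit pages along the third axis, and the
#' voxel size, midline and orientation go into `<path>.json`.
#'
#' @param volume an [annotation_volume()].
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  mx <- max(volume$labels)
  if (mx > 65535L) stop("labels exceed 16-bit TIFF range")
  pages <- lapply(seq_len(dim(volume$labels)[3]), function(k)
    t(volume$labels[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size_um,
                            midline = volume$midline,
                            orientation = volume$orientation),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d12 <- dim(pages[[1]])
  labels <- array(0L, dim = c(d12[2], d12[1], length(pages)))
  for (k in seq_along(pages)) labels[, , k] <- t(pages[[k]])
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  annotation_volume(labels, meta$voxel_size_um, midline = meta$midline,
                    orientation = meta$orientation)
}

#' Write an image stack as multi-page TIFF
#'
#' Intensities are rescaled to 32-bit float pages; voxel size goes into a
#' JSON sidecar.
#'
#' @param stack an `image_stack`.
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  mx <- max(stack$data, 1e-12)
  pages <- lapply(seq_len(dim(stack$data)[3]), function(k)
    t(stack$data[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size_um = stack$voxel_size_um, scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d12 <- dim(pages[[1]])
  a <- array(0, dim = c(d12[2], d12[1], length(pages)))
  for (k in seq_along(pages)) a[, , k] <- t(pages[[k]])
  structure(list(data = a * meta$scale, voxel_size_um = meta$voxel_size_um),
            class = "image_stack")
}
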