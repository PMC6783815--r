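#' Read a 3D volume from a multi-page TIFF stack
#'
#' Page order maps to the first (z) axis; within-page rows to y, columns to
#' x. Voxel spacing is taken from the TIFF resolution metadata
#' (`spacing = 1 / XResolution`, ResolutionUnit "none") when present;
#' otherwise it defaults to 1.0 with a warning and all downstream
#' descriptors are in voxel units.
#'
#' @param path path to a single- or multi-page grayscale TIFF (8/16-bit
#'   unsigned integer or 32-bit float, uncompressed).
#' @param as_binary if `TRUE`, decode any nonzero voxel as 1 and return a
#'   [binary_volume()]. The mask convention on disk is 0/255 8-bit.
#' @param name sample identifier; defaults to the file name without
#'   extension.
#' @return A [volume3d()] (or [binary_volume()] if `as_binary = TRUE`).
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, as_binary = FALSE, name = NULL) {
  tf <- read_tiff_stack(path)
  spacing <- tf$spacing
  if (is.na(spacing)) {
    warning("no resolution metadata in ", path,
            "; assuming voxel spacing 1.0")
    spacing <- 1.0
  }
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  if (as_binary) {
    binary_volume(tf$data != 0, spacing = spacing, name = name)
  } else {
    volume3d(tf$data, spacing = spacing, name = name)
  }
}

#' Write a 3D volume as a multi-page TIFF stack
#'
#' Grayscale volumes are stored as 8/16-bit unsigned integer when their
#' values permit, else 32-bit float. Binary volumes are stored as 8-bit
#' 0/255. Voxel spacing is recorded in the resolution tags and survives a
#' round trip to better than 1e-9 relative.
#'
#' @param v a [volume3d()] or [binary_volume()].
#' @param path output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(v, path) {
  stopifnot_volume(v)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  write_tiff_stack(v$data, path, spacing = v$spacing)
  invisible(path)
}

DESCRIPTOR_COLUMNS <- c("name", "V", "Vc", "A", "Ac", "C", "S")

#' Read / write a descriptor table
#'
#' Descriptor tables persist one [measure()] record per individual as CSV
#' with header `name,V,Vc,A,Ac,C,S,label` (`label` optional). The round
#' trip is lossless to better than 12 significant digits.
#'
#' @param path CSV file path.
#' @return `read_descriptor_table()`: a `data.frame` of class
#'   `morph_descriptors` with the columns above.
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  missing <- setdiff(DESCRIPTOR_COLUMNS, names(df))
  if (length(missing))
    stop("descriptor table is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in setdiff(DESCRIPTOR_COLUMNS, "name")) {
    v <- df[[col]]
    if (nrow(df) == 0L) { df[[col]] <- numeric(0); next }
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in row %d, column '%s': '%s'",
                     bad[1], col, v[bad[1]]))
      df[[col]] <- conv
    }
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' is not numeric", col))
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  df <- df[c(DESCRIPTOR_COLUMNS, "label")]
  class(df) <- c("morph_descriptors", "data.frame")
  df
}

#' @param records a `morph_descriptors` data frame (from [measure()] /
#'   [measure_population()] or built by hand with the required columns).
#' @rdname read_descriptor_table
#' @export
write_descriptor_table <- function(records, path) {
  if (!is.data.frame(records))
    stop("`records` must be a data.frame of descriptors")
  missing <- setdiff(DESCRIPTOR_COLUMNS, names(records))
  if (length(missing))
    stop("records are missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(records)[, c(DESCRIPTOR_COLUMNS,
                                   intersect("label", names(records)))]
  for (col in setdiff(DESCRIPTOR_COLUMNS, "name"))
    df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
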