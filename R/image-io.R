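#' Multi-channel 3D image stack
#'
#' The in-memory container used throughout the pipeline: a 4-D intensity
#' array ordered \code{(channel, z, y, x)} with named channels and physical
#' voxel sizes. Pixels are assumed square in xy (\code{dy == dx}); the axial
#' spacing is typically coarser (0.2 um z-steps vs 0.08 um xy pitch on the
#' DeltaVision-style acquisitions this pipeline targets).
#'
#' @param data 4-D non-negative numeric array, dimensions
#'   \code{(channel, z, y, x)}.
#' @param channel_names character vector, one name per channel, e.g.
#'   \code{c("DAPI", "ACA", "Bod1")}.
#' @param voxel_size numeric length-3, \code{(dz, dy, dx)} in micrometres.
#' @return an object of class \code{ImageStack}.
#' @examples
#' st <- image_stack(array(0, c(1, 4, 8, 8)), "ACA", c(0.2, 0.08, 0.08))
#' dim(st$data)
#' @export
image_stack <- function(data, channel_names, voxel_size) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4-D array (channel, z, y, x)")
  if (dim(data)[1L] != length(channel_names))
    stop("channel dimension (", dim(data)[1L], ") != number of channel names (",
         length(channel_names), ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (dz, dy, dx) in um")
  if (abs(voxel_size[2L] - voxel_size[3L]) > 1e-9)
    stop("non-square pixels (dy != dx) are not supported")
  structure(
    list(data = data, channel_names = as.character(channel_names),
         voxel_size = voxel_size),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d channel(s) [%s], %d x %d x %d (z,y,x) voxels\n",
              d[1L], paste(x$channel_names, collapse = ", "),
              d[2L], d[3L], d[4L]))
  cat(sprintf("voxel size (dz, dy, dx): %.3f x %.3f x %.3f um\n",
              x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L]))
  invisible(x)
}

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack an \code{ImageStack}.
#' @param channel channel name.
#' @return numeric 3-D array with dimensions \code{(z, y, x)}.
#' @export
channel_array <- function(stack, channel) {
  i <- match(channel, stack$channel_names)
  if (is.na(i)) stop("no such channel: '", channel, "' (have: ",
                     paste(stack$channel_names, collapse = ", "), ")")
  d <- dim(stack$data)
  array(stack$data[i, , , ], dim = d[2:4])
}

#' Write an image stack to a multi-page TIFF file
#'
#' Pages are ordered channel-major: all z-slices of channel 1, then all
#' z-slices of channel 2, and so on. Channel names, voxel size and page
#' layout are recorded as JSON in the first page's ImageDescription tag, so
#' a stack round-trips through \code{\link{read_stack}} without any
#' side-channel metadata. Integer-valued data round-trips losslessly.
#'
#' @param stack an \code{ImageStack}.
#' @param path output path (conventionally \code{.tif}).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  nc <- d[1L]; nz <- d[2L]; ny <- d[3L]; nx <- d[4L]
  pages <- array(0, dim = c(ny, nx, nc * nz))
  p <- 0L
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    p <- p + 1L
    pages[, , p] <- stack$data[ci, zi, , ]
  }
  meta <- jsonlite::toJSON(list(
    format = "kinetoquant-stack", version = 1L,
    channel_names = stack$channel_names,
    voxel_size_um = stack$voxel_size,
    n_z = nz, page_order = "channel-major (c slow, z fast)"
  ), auto_unbox = TRUE, digits = NA)
  write_tiff_pages(pages, path, description = as.character(meta))
}

#' Read a multi-page TIFF file into an image stack
#'
#' Understands the metadata written by \code{\link{write_stack}}; for plain
#' TIFFs lacking it, \code{channel_names} and \code{voxel_size} must be
#' supplied and pages are interpreted channel-major. Supplied overrides must
#' agree with embedded metadata (channel count and name set), otherwise an
#' error is raised. The returned axis order is always \code{(c, z, y, x)}.
#'
#' @param path TIFF file path.
#' @param channel_names optional character vector of channel names.
#' @param voxel_size optional numeric \code{(dz, dy, dx)} in um.
#' @return an \code{ImageStack}.
#' @export
read_stack <- function(path, channel_names = NULL, voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tf <- read_tiff_pages(path)
  meta <- NULL
  if (nzchar(tf$description)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
    if (!is.null(meta) && !identical(meta$format, "kinetoquant-stack"))
      meta <- NULL
  }
  np <- dim(tf$pages)[3L]
  if (!is.null(meta)) {
    if (!is.null(channel_names) &&
        !identical(as.character(channel_names), as.character(meta$channel_names)))
      stop("channel_names override conflicts with embedded metadata")
    if (!is.null(voxel_size) &&
        max(abs(as.numeric(voxel_size) - as.numeric(meta$voxel_size_um))) > 1e-9)
      stop("voxel_size override conflicts with embedded metadata")
    channel_names <- as.character(meta$channel_names)
    voxel_size <- as.numeric(meta$voxel_size_um)
  } else {
    if (is.null(channel_names) || is.null(voxel_size))
      stop("TIFF has no stack metadata; channel_names and voxel_size ",
           "must be supplied")
  }
  nc <- length(channel_names)
  if (np %% nc != 0L)
    stop("page count ", np, " is not a multiple of channel count ", nc)
  nz <- np %/% nc
  ny <- dim(tf$pages)[1L]; nx <- dim(tf$pages)[2L]
  data <- array(0, dim = c(nc, nz, ny, nx))
  p <- 0L
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    p <- p + 1L
    data[ci, zi, , ] <- tf$pages[, , p]
  }
  image_stack(data, channel_names, voxel_size)
}

# ---- result tables ----------------------------------------------------------

# Column schemas are versioned: every file carries schema name + version in
# its first two columns so downstream readers can refuse foreign files with a
# precise error instead of mis-parsing.
RESULT_SCHEMAS <- list(
  kinetochore = c("cell_id", "label", "channel", "n_mask_voxels",
                  "n_annulus_voxels", "background_mean", "raw_sum",
                  "corrected_sum", "centroid_z", "centroid_y", "centroid_x",
                  "centroid_z_um", "centroid_y_um", "centroid_x_um", "flagged"),
  cell = c("cell_id", "condition", "phase", "channel", "summary", "n_regions"),
  volcano = c("protein_id", "gene_name", "log2_fc", "p_value", "neg_log10_p",
              "fdr", "significant", "flagged", "annotation_flags"),
  ground_truth = c("cell_id", "spot_id", "pair_id", "z", "y", "x",
                   "z_um", "y_um", "x_um", "channel", "amplitude"),
  manifest = c("cell_id", "path", "condition", "phase", "seed")
)
RESULT_SCHEMA_VERSION <- 1L

#' Write a pipeline results table as CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal. The schema name and version are stored
#' in leading \code{.schema}/\code{.schema_version} columns so that
#' \code{\link{read_results_table}} can validate files. An empty row set
#' produces a header-only file.
#'
#' @param rows data.frame matching one of the registered schemas.
#' @param path output path.
#' @param schema schema name, one of \code{names(RESULT_SCHEMAS)}.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path,
                                schema = names(RESULT_SCHEMAS)) {
  schema <- match.arg(schema)
  cols <- RESULT_SCHEMAS[[schema]]
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0L)
    stop("rows lack required column(s) for schema '", schema, "': ",
         paste(missing, collapse = ", "))
  out <- rows[, cols, drop = FALSE]
  out <- cbind(.schema = rep(schema, nrow(out)),
               .schema_version = rep(RESULT_SCHEMA_VERSION, nrow(out)),
               out, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L)
    out <- out[0L, c(".schema", ".schema_version", cols), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pipeline results table written by \code{\link{write_results_table}}
#'
#' @param path CSV path.
#' @param schema expected schema name.
#' @return data.frame with the schema's columns (metadata columns dropped).
#' @export
read_results_table <- function(path, schema = names(RESULT_SCHEMAS)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  cols <- RESULT_SCHEMAS[[schema]]
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop("file '", path, "' does not match schema '", schema,
         "'; missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) > 0L && ".schema" %in% names(df) &&
      !all(df$.schema == schema))
    stop("file '", path, "' carries schema '", df$.schema[1L],
         "', expected '", schema, "'")
  df[, cols, drop = FALSE]
}
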