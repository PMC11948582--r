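## JSON serialization for generator specs and QC configuration.

#' Write / read a tissue spec as JSON
#'
#' @param spec a [tissue_spec()].
#' @param path file path.
#' @return `read_tissue_spec_json` returns a `tissue_spec`.
#' @export
write_tissue_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "tissue_spec"))
  x <- unclass(spec)
  x$exclusion_polygons <- lapply(x$exclusion_polygons, function(p)
    as.data.frame(p))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_tissue_spec_json
#' @export
read_tissue_spec_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (f in c("mixing", "isolated_fraction", "pixel_size_um"))
    if (length(x[[f]]) == 0) x[f] <- list(NULL)
  polys <- lapply(x$exclusion_polygons, function(p)
    cbind(x = p$x, y = p$y))
  do.call(tissue_spec, c(
    x[c("field_width_um", "field_height_um", "n_tumor_nests",
        "nest_radius_um", "platform", "subtype", "tma_id")],
    list(cell_types = as.data.frame(x$cell_types),
         mixing = x$mixing, isolated_fraction = x$isolated_fraction,
         pixel_size_um = x$pixel_size_um,
         exclusion_polygons = polys)))
}

#' Write a long-format spatial metric table as CSV
#'
#' @param metrics data frame from [compute_spatial_metrics()].
#' @param path file path.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Read / write multichannel images and label masks as (OME-style) TIFF
#'
#' Multichannel images are stored as multi-page TIFF, one page per marker in
#' panel order; label masks as single-channel integer TIFF. Requires the
#' `tiff` package.
#'
#' @param channels named list of numeric matrices.
#' @param path file path.
#' @param markers marker names to assign to pages on read.
#' @param mask integer label mask.
#' @param scale intensity scale returned by the writer (TIFF stores values
#'   in \[0,1\]; the writer divides by this scale, the reader multiplies).
#' @return `write_multichannel_tiff` returns the intensity scale used;
#'   readers return the named channel list / integer mask.
#' @export
write_multichannel_tiff <- function(channels, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF IO")
  sc <- max(1, vapply(channels, max, numeric(1)))
  tiff::writeTIFF(lapply(channels, function(ch) ch / sc), path,
                  bits.per.sample = 32L)
  invisible(sc)
}

#' @rdname write_multichannel_tiff
#' @export
read_multichannel_tiff <- function(path, markers, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF IO")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(markers))
    stopf("TIFF has %d pages but %d markers were given", length(pages),
          length(markers))
  pages <- lapply(pages, function(p) p * scale)
  names(pages) <- markers
  pages
}

#' @rdname write_multichannel_tiff
#' @export
write_label_mask_tiff <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF IO")
  ## labels are scaled into [0,1] at 16 bits; recover with the max id
  m <- max(mask)
  tiff::writeTIFF(mask / max(m, 1), path, bits.per.sample = 16L)
  attr(path, "max_id") <- m
  invisible(path)
}

#' @rdname write_multichannel_tiff
#' @param max_id largest label id stored in the mask.
#' @export
read_label_mask_tiff <- function(path, max_id) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF IO")
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * max_id)), nrow(m), ncol(m))
}
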