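#' Two-channel microscope field
#'
#' Container for one field: channel 1 the Hoechst/nuclei image, channel 2
#' the marker image (alpha-actinin at 60x, active YAP1 at 4x), both
#' integer-valued 16-bit rasters of identical shape, plus the pixel size
#' and well/field identifiers.
#'
#' @param nuclei,marker numeric matrices (same shape, values 0..65535)
#' @param pixel_size_um um per pixel (> 0)
#' @param well well identifier
#' @param field field index within the well
#' @param mode "sarcomere_60x" or "yap_4x"
#' @return a `field_image` list
#' @export
field_image <- function(nuclei, marker, pixel_size_um, well = "W01",
                        field = 1L, mode = "sarcomere_60x") {
  stopifnot(is.matrix(nuclei), is.matrix(marker),
            all(dim(nuclei) == dim(marker)), pixel_size_um > 0)
  structure(list(nuclei = nuclei, marker = marker,
                 pixel_size_um = pixel_size_um,
                 well = well, field = as.integer(field), mode = mode),
            class = "field_image")
}

#' Write a field as a 2-page 16-bit TIFF
#'
#' Page 1 is the nuclei channel, page 2 the marker channel. Intensities are
#' stored as 16-bit unsigned integers.
#'
#' @param fi a [field_image]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_field_tiff <- function(fi, path) {
  pages <- list(fi$nuclei / 65535, fi$marker / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 2-page field TIFF written by [write_field_tiff]
#'
#' @param path TIFF path
#' @param pixel_size_um pixel size to stamp on the field
#' @param well,field,mode identifiers to stamp on the field
#' @return a [field_image]
#' @export
read_field_tiff <- function(path, pixel_size_um, well = "W01", field = 1L,
                            mode = "sarcomere_60x") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a 2-page TIFF: ", path)
  field_image(round(pages[[1]] * 65535), round(pages[[2]] * 65535),
              pixel_size_um, well = well, field = field, mode = mode)
}
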