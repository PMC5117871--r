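# Thin TIFF / CSV IO wrappers around the tiff package and write.csv.

#' Read and write intensity images as TIFF
#'
#' Intensities are rescaled into `[0, 1]` on write (the scale and offset
#' are not preserved; the pipeline is intensity-scale invariant with CDF
#' equalisation on). Multi-frame stacks are handled as lists of matrices.
#'
#' @param path TIFF file path.
#' @param image matrix, or list of matrices for a stack.
#' @return `read_image_tiff`: a matrix, or list of matrices for stacks;
#'   `write_image_tiff`: `path`, invisibly.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) == 1L) img[[1L]] else img
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  if (is.matrix(image)) image <- list(image)
  image <- lapply(image, function(m) {
    rng <- range(m)
    if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
  })
  tiff::writeTIFF(image, path)
  invisible(path)
}

#' Write an AP profile data frame to CSV
#'
#' @param profile any of the package's profile data frames.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
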