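# Pia / white-matter / vessel landmark extraction from low-resolution
# section images (bright background, darker tissue, dark vessel lumina).

#' Extract pia, WM and vessel landmarks from a low-resolution section
#'
#' The tissue is segmented by an Otsu threshold against the bright
#' background; the pia is the outer boundary of the hole-filled tissue mask.
#' The WM boundary is taken from the largest interior hole of the tissue
#' mask when one exists (tangential sections through the ring of cortex) or
#' otherwise from a second, darker intensity class within the tissue.
#' Vessels are small dark blobs inside the tissue.
#'
#' @param image numeric matrix, intensities 0..1 (background bright).
#' @param pixel_size micrometers per pixel.
#' @param origin um coordinates of pixel `[1, 1]`.
#' @param vessel_max_area maximal vessel blob area in um^2.
#' @return list with `pia` (n x 2 um polygon), `wm` (polygon or `NULL`),
#'   `vessels` (k x 2 um matrix of blob centers) and `clipped` (`TRUE` when
#'   the tissue touches the image border).
#' @export
extract_macro_landmarks <- function(image, pixel_size = 20, origin = c(0, 0),
                                    vessel_max_area = 5000) {
  image <- as.matrix(image)
  xs <- origin[1] + (seq_len(nrow(image)) - 1) * pixel_size
  ys <- origin[2] + (seq_len(ncol(image)) - 1) * pixel_size
  thr <- otsu_threshold(as.vector(image))
  tissue <- image < thr
  if (!any(tissue)) stop("no tissue found in image")
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(tissue * 1))) > 0.5
  # keep the largest tissue object
  lab <- as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(filled * 1))))
  sizes <- tabulate(lab[lab > 0])
  filled <- lab == which.max(sizes)
  clipped <- any(filled[1, ]) || any(filled[nrow(filled), ]) ||
    any(filled[, 1]) || any(filled[, ncol(filled)])
  pia <- mask_contour(filled, xs, ys)

  holes <- filled & !tissue
  wm <- NULL
  if (sum(holes) > 9) {
    hlab <- as.matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(holes * 1))))
    hsizes <- tabulate(hlab[hlab > 0])
    if (length(hsizes) && max(hsizes) > 9)
      wm <- mask_contour(hlab == which.max(hsizes), xs, ys)
  }
  if (is.null(wm)) {
    tvals <- image[filled]
    thr2 <- otsu_threshold(tvals)
    dark <- filled & image < thr2
    if (sum(dark) > 9 && mean(image[dark]) < thr2 - 0.02) {
      dlab <- as.matrix(EBImage::imageData(
        EBImage::bwlabel(EBImage::Image(dark * 1))))
      dsizes <- tabulate(dlab[dlab > 0])
      if (length(dsizes) && max(dsizes) * pixel_size^2 > vessel_max_area)
        wm <- mask_contour(dlab == which.max(dsizes), xs, ys)
    }
  }

  # vessels: very dark small blobs inside tissue
  tvals <- image[tissue]
  vthr <- stats::quantile(tvals, 0.02)
  cand <- tissue & image <= vthr & image < 0.6 * mean(tvals)
  vessels <- matrix(numeric(0), 0, 2)
  if (any(cand)) {
    vlab <- as.matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(cand * 1))))
    ids <- seq_len(max(vlab))
    for (id in ids) {
      pix <- which(vlab == id, arr.ind = TRUE)
      if (nrow(pix) * pixel_size^2 > vessel_max_area || nrow(pix) < 2) next
      vessels <- rbind(vessels, c(mean(xs[pix[, 1]]), mean(ys[pix[, 2]])))
    }
  }
  list(pia = pia, wm = wm, vessels = vessels, clipped = clipped)
}
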