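# Wound segmentation from the white-light frame, standardizing the visual
# delineation step: median smoothing, Otsu threshold, largest 8-connected
# component, hole filling, one binary opening.

# Merge 4-connected labels across diagonal adjacencies to obtain
# 8-connectivity components (EBImage::bwlabel is 4-connected).
label8 <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

#' Segment the wound from a white-light frame
#'
#' Automates the visual wound delineation: the white frame is median-smoothed
#' (3x3), thresholded by Otsu's method, and the wound taken as the darker
#' class (the wound bed reflects less white light than shaved skin; set
#' `wound_darker = FALSE` to invert). The largest 8-connected component is
#' kept (ties broken by centroid closest to the frame centre, since wounds
#' are centred by protocol), holes are filled, and one binary opening of
#' radius 1 removes speckle.
#'
#' @param white A raw white-light [channel_frame()].
#' @param wound_darker Logical; wound is the below-threshold class.
#' @return A [wound_mask()] with `source = "auto"`.
#' @export
segment_wound <- function(white, wound_darker = TRUE) {
  stopifnot(inherits(white, "channel_frame"))
  if (white$channel != "WHITE") {
    rw_stop("rw_segmentation_error",
            "segmentation expects the white-light channel (got %s)", white$channel)
  }
  x <- white$pixels / MAX_DN
  x[x > 1] <- 1
  sm <- EBImage::medianFilter(x, size = 1)
  if (diff(range(sm)) < 1e-6) {
    rw_stop("rw_segmentation_error",
            "white frame has no contrast; supply a manual mask")
  }
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  wound <- if (wound_darker) sm < th else sm > th
  if (!any(wound)) {
    rw_stop("rw_segmentation_error",
            "empty wound class after thresholding; supply a manual mask")
  }

  lab <- label8(wound)
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: centroid nearest the frame centre
    ctr <- (dim(lab) + 1) / 2
    d2 <- vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      sum((colMeans(idx) - ctr)^2)
    }, numeric(1))
    best <- best[which.min(d2)]
  }
  mask <- lab == best
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, shape = "disc")) > 0
  if (!any(mask)) {
    rw_stop("rw_segmentation_error",
            "mask empty after post-processing; supply a manual mask")
  }
  wound_mask(matrix(as.logical(mask), nrow(x), ncol(x)), source = "auto")
}

#' Load a manually drawn wound mask
#'
#' Reads an 8-bit PNG or TIFF mask (nonzero = wound) matching the shape of
#' the target frame; supports the visual-delineation workflow for real data.
#'
#' @param path Path to the mask image.
#' @param target_frame The [channel_frame()] the mask belongs to.
#' @return A [wound_mask()] with `source = "manual"`.
#' @export
load_manual_mask <- function(path, target_frame) {
  stopifnot(inherits(target_frame, "channel_frame"))
  if (!file.exists(path)) rw_stop("rw_mask_error", "mask file not found: %s", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  want <- dim(target_frame$pixels)
  if (!identical(dim(img), want)) {
    rw_stop("rw_mask_error", "mask shape %s does not match frame shape %s",
            paste(dim(img), collapse = "x"), paste(want, collapse = "x"))
  }
  mask <- img > 0
  if (!any(mask)) rw_stop("rw_mask_error", "mask file is entirely zero")
  wound_mask(mask, source = "manual")
}

#' Apply a wound mask to a frame
#'
#' Sets every pixel outside the mask to zero and leaves wound pixels
#' unchanged; idempotent for a fixed mask.
#'
#' @param frame A [channel_frame()].
#' @param mask A [wound_mask()] of the same shape.
#' @return The masked frame.
#' @export
apply_mask <- function(frame, mask) {
  stopifnot(inherits(frame, "channel_frame"), inherits(mask, "wound_mask"))
  if (!identical(dim(frame$pixels), dim(mask$mask))) {
    rw_stop("rw_mask_error", "mask shape %s does not match frame shape %s",
            paste(dim(mask$mask), collapse = "x"),
            paste(dim(frame$pixels), collapse = "x"))
  }
  out <- frame
  out$pixels[!mask$mask] <- 0
  out
}

#' Wound mask of a processed cryo biopsy
#'
#' Biopsies are whole-wound excisions, so the default volumetric wound mask
#' is every voxel that survives background zeroing in both fluorescence
#' channels.
#'
#' @param nadh,fad Background-zeroed [cryo_stack()]s.
#' @return A 3D [wound_mask()].
#' @export
cryo_wound_mask <- function(nadh, fad) {
  stopifnot(inherits(nadh, "cryo_stack"), inherits(fad, "cryo_stack"))
  if (!nadh$background_zeroed || !fad$background_zeroed) {
    rw_stop("rw_mask_error", "cryo masks require background-zeroed stacks")
  }
  wound_mask(nadh$voxels > 0 & fad$voxels > 0, source = "auto")
}
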