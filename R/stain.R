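# Colour deconvolution for hematoxylin / DAB immunohistochemistry.
#
# Stain amounts are additive in optical density (OD) space: for an
# 8-bit channel value v, OD = -log10((v + 1) / 256).  Each stain
# absorbs along a characteristic unit vector in RGB-OD space; the
# standard hematoxylin and DAB vectors (Ruifrok & Johnston) are used,
# completed with their normalized cross product so the 3x3 stain matrix
# is invertible.

stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  res <- c(h[2] * d[3] - h[3] * d[2],
           h[3] * d[1] - h[1] * d[3],
           h[1] * d[2] - h[2] * d[1])
  res <- res / sqrt(sum(res^2))
  cbind(hematoxylin = h, dab = d, residual = res)
}

rgb_to_od <- function(v) -log10((v + 1) / 256)
od_to_rgb <- function(od) pmin(pmax(round(256 * 10^(-od) - 1), 0), 255)

assert_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an 8-bit RGB image as an h x w x 3 array", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("RGB values must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

#' Separate hematoxylin and DAB staining by colour deconvolution
#'
#' Converts an 8-bit RGB image to optical density (`-log10((v+1)/256)`
#' per channel) and unmixes it with the standard hematoxylin/DAB stain
#' matrix. Negative stain amounts (noise outside the stain simplex) are
#' clipped to zero.
#'
#' @param image 8-bit RGB image, an `h x w x 3` array with values in
#'   `[0, 255]`.
#' @return a list with numeric matrices `hematoxylin` and `dab` holding
#'   per-pixel stain OD.
#' @examples
#' img <- array(255, c(8, 8, 3))     # pure white: no absorbance
#' od <- deconvolve_stains(img)
#' max(od$hematoxylin, od$dab)       # ~0
#' @export
deconvolve_stains <- function(image) {
  assert_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  od <- rgb_to_od(matrix(as.numeric(image), ncol = 3L))
  conc <- od %*% t(solve(stain_matrix()))
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1L], h, w),
       dab         = matrix(conc[, 2L], h, w))
}

# Otsu's threshold on a numeric vector (256-bin histogram).  Returns
# the upper edge of the bin maximizing between-class variance, so that
# `x >= threshold` selects exactly the upper class.
otsu_threshold <- function(x, bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = bins)
  mid <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(cnt)
  m1 <- cumsum(cnt * mid)
  total <- w1[bins]; mu <- m1[bins]
  w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, bins)
  bcv[valid] <- (mu * w1[valid] / total - m1[valid])^2 /
    (w1[valid] * w2[valid]) * total
  br[which.max(bcv) + 1L]
}

#' Segment nuclei inside the tumour compartment
#'
#' Thresholds hematoxylin OD within the tumour mask with Otsu's method,
#' fills holes and drops objects below a minimum area. When a DAB OD
#' raster is supplied, strongly DAB-positive pixels whose hematoxylin
#' signal clears half the threshold are also admitted, so nuclei whose
#' counterstain is partially quenched by chromogen are not lost.
#'
#' @param hematoxylin_od numeric matrix of hematoxylin OD.
#' @param tumour_mask logical matrix marking tumour pixels.
#' @param dab_od optional numeric matrix of DAB OD (same size).
#' @param min_area minimum object area in pixels (default 30).
#' @return logical matrix: nuclear pixels, a subset of `tumour_mask`.
#' @export
segment_nuclei <- function(hematoxylin_od, tumour_mask, dab_od = NULL,
                           min_area = 30L) {
  if (!all(dim(hematoxylin_od) == dim(tumour_mask))) {
    stop("hematoxylin OD and tumour mask dimensions differ", call. = FALSE)
  }
  if (!any(tumour_mask)) {
    return(matrix(FALSE, nrow(tumour_mask), ncol(tumour_mask)))
  }
  thr <- otsu_threshold(hematoxylin_od[tumour_mask])
  nuc <- tumour_mask & hematoxylin_od >= thr
  if (!is.null(dab_od)) {
    if (!all(dim(dab_od) == dim(tumour_mask))) {
      stop("DAB OD and tumour mask dimensions differ", call. = FALSE)
    }
    dab_hi <- quantile(dab_od[tumour_mask], 0.90, names = FALSE)
    nuc <- nuc | (tumour_mask & dab_od >= max(dab_hi, 0.4) &
                    hematoxylin_od >= thr / 2)
  }
  nuc <- .fill_holes(nuc) & tumour_mask
  .remove_small(nuc, as.integer(min_area))
}

#' Count nuclei in a segmented nuclear mask
#'
#' Touching nuclei are declumped by a one-pixel erosion before
#' connected components are counted; fragments below `min_area` are
#' ignored.
#'
#' @param nuclear_mask logical matrix from [segment_nuclei()].
#' @param min_area minimum eroded-object area counted as a nucleus.
#' @return integer nucleus count.
#' @export
count_nuclei <- function(nuclear_mask, min_area = 8L) {
  m <- nuclear_mask
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  er <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  lab <- .cc_label(.remove_small(er, as.integer(min_area)), 4L)
  attr(lab, "n")
}
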