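# Positive-pixel quantification of the nuclear and cytoplasmic
# compartments within tumour.

#' DAB positivity thresholds (OD scale)
#'
#' A pixel is positive when its DAB OD exceeds `weak`; positive pixels
#' are binned weak/medium/strong at the `medium` and `strong` cut
#' points. `od_max` normalizes mean positive OD to the `[0, 1]`
#' intensity used by the autoscore.
#'
#' @param weak,medium,strong increasing OD cut points.
#' @param od_max OD mapped to intensity 1.
#' @return a `positivity_config` list.
#' @export
positivity_config <- function(weak = 0.15, medium = 0.40, strong = 0.80,
                              od_max = 2.0) {
  if (!(weak < medium && medium < strong)) {
    stop("positivity thresholds must satisfy weak < medium < strong",
         call. = FALSE)
  }
  stopifnot_nonneg(weak, "weak")
  stopifnot_nonneg(od_max, "od_max")
  structure(list(weak = weak, medium = medium, strong = strong,
                 od_max = od_max),
            class = "positivity_config")
}

# Bin a single OD value; NA when not positive.
dab_bin <- function(od, cfg = positivity_config()) {
  if (od <= cfg$weak) return(NA_character_)
  if (od <= cfg$medium) return("weak")
  if (od <= cfg$strong) return("medium")
  "strong"
}

new_compartment_quant <- function(nuclear, cytoplasmic, tumour_px,
                                  evaluable = NA) {
  structure(list(nuclear = nuclear, cytoplasmic = cytoplasmic,
                 tumour_px = as.integer(tumour_px), evaluable = evaluable),
            class = "compartment_quant")
}

#' @export
as.data.frame.compartment_quant <- function(x, ...) {
  row <- function(cp, prefix) {
    d <- data.frame(
      total_px = cp$total_px, positive_px = cp$positive_px,
      weak = cp$bins[["weak"]], medium = cp$bins[["medium"]],
      strong = cp$bins[["strong"]],
      mean_positive_od = cp$mean_positive_od
    )
    names(d) <- paste(prefix, names(d), sep = "_")
    d
  }
  cbind(row(x$nuclear, "nuclear"), row(x$cytoplasmic, "cyt"),
        data.frame(tumour_px = x$tumour_px, evaluable = x$evaluable))
}

#' @export
print.compartment_quant <- function(x, ...) {
  cat("Compartment quantification (tumour", x$tumour_px, "px,",
      if (isTRUE(x$evaluable)) "evaluable" else "non-evaluable", ")\n")
  for (cp in c("nuclear", "cytoplasmic")) {
    c0 <- x[[cp]]
    cat(sprintf("  %-12s %d/%d positive (w/m/s %d/%d/%d), mean OD %.3f\n",
                cp, c0$positive_px, c0$total_px, c0$bins[["weak"]],
                c0$bins[["medium"]], c0$bins[["strong"]],
                c0$mean_positive_od))
  }
  invisible(x)
}

quant_one_compartment <- function(dab, mask, cfg) {
  vals <- dab[mask]
  pos <- vals > cfg$weak
  npos <- sum(pos)
  bins <- c(
    weak   = sum(pos & vals <= cfg$medium),
    medium = sum(vals > cfg$medium & vals <= cfg$strong),
    strong = sum(vals > cfg$strong)
  )
  list(
    total_px = length(vals),
    positive_px = as.integer(npos),
    bins = as.integer(bins) |> setNames(names(bins)),
    mean_positive_od = if (npos > 0) mean(vals[pos]) else 0
  )
}

#' Quantify DAB positivity in nuclear and cytoplasmic compartments
#'
#' Takes an RGB core image and a five-class tissue map, deconvolves the
#' stains, segments nuclei within tumour on the hematoxylin channel,
#' defines cytoplasm as tumour minus nuclei, and counts DAB-positive
#' pixels (binned weak/medium/strong) per compartment.
#'
#' @param image 8-bit RGB array.
#' @param tissue a [classify_tissue()] result or an integer label
#'   matrix over the five tissue classes.
#' @param thresholds a [positivity_config()].
#' @param min_tumour_px evaluability floor on tumour area; default
#'   scales the reference 2000 px (at 512 x 512) with image area.
#' @param min_nucleus_area minimum nuclear object size in pixels.
#' @return a `compartment_quant` with per-compartment totals, positive
#'   counts, bin counts, mean positive OD, tumour area and the
#'   evaluability flag, plus the masks used (attribute `masks`).
#' @export
quantify_compartments <- function(image, tissue,
                                  thresholds = positivity_config(),
                                  min_tumour_px = NULL,
                                  min_nucleus_area = 30L) {
  assert_rgb_image(image)
  labels <- tissue_labels_matrix(tissue)
  if (!all(dim(labels) == dim(image)[1:2])) {
    stop("tissue map dimensions do not match the image", call. = FALSE)
  }
  if (!all(labels %in% TISSUE_LABELS)) {
    stop("tissue map contains labels outside the five known classes",
         call. = FALSE)
  }
  if (is.null(min_tumour_px)) {
    min_tumour_px <- default_min_tumour_px(ncol(labels), nrow(labels))
  }
  od <- deconvolve_stains(image)
  tumour <- labels == TISSUE_LABELS[["tumour_positive"]] |
    labels == TISSUE_LABELS[["tumour_negative"]]
  nuclear <- segment_nuclei(od$hematoxylin, tumour, od$dab,
                            min_area = min_nucleus_area)
  cyto <- tumour & !nuclear
  q <- new_compartment_quant(
    nuclear = quant_one_compartment(od$dab, nuclear, thresholds),
    cytoplasmic = quant_one_compartment(od$dab, cyto, thresholds),
    tumour_px = sum(tumour)
  )
  q$evaluable <- assess_evaluability(q, min_tumour_px = min_tumour_px)
  attr(q, "masks") <- list(nuclear = nuclear, cytoplasm = cyto,
                           tumour = tumour)
  attr(q, "od") <- od
  q
}

tissue_labels_matrix <- function(tissue) {
  if (inherits(tissue, "tissue_map")) return(tissue$labels)
  if (is.matrix(tissue)) {
    storage.mode(tissue) <- "integer"
    return(tissue)
  }
  stop("`tissue` must be a tissue_map or an integer label matrix",
       call. = FALSE)
}

#' Render a pseudo-colour mark-up image
#'
#' Paints positive nuclear pixels red and positive cytoplasmic pixels
#' orange (medium/strong) or yellow (weak); all other pixels keep their
#' original colour.
#'
#' @param image 8-bit RGB array.
#' @param quant a [quantify_compartments()] result carrying its masks,
#'   or a list with `nuclear` and `cytoplasm` logical masks.
#' @param thresholds the [positivity_config()] used for quantification.
#' @return an 8-bit RGB array of the same size.
#' @export
render_markup <- function(image, quant, thresholds = positivity_config()) {
  assert_rgb_image(image)
  masks <- if (inherits(quant, "compartment_quant")) attr(quant, "masks")
           else quant
  od <- if (inherits(quant, "compartment_quant") &&
            !is.null(attr(quant, "od"))) attr(quant, "od")
        else deconvolve_stains(image)
  if (is.null(masks) || !all(dim(masks$nuclear) == dim(image)[1:2])) {
    stop("mark-up masks do not match the image", call. = FALSE)
  }
  dab <- od$dab
  out <- image
  paint <- function(out, mask, rgb) {
    for (k in 1:3) {
      ch <- out[, , k]
      ch[mask] <- rgb[k]
      out[, , k] <- ch
    }
    out
  }
  nuc_pos <- masks$nuclear & dab > thresholds$weak
  cyt_weak <- masks$cytoplasm & dab > thresholds$weak &
    dab <= thresholds$medium
  cyt_ms <- masks$cytoplasm & dab > thresholds$medium
  out <- paint(out, nuc_pos, c(255L, 0L, 0L))        # red
  out <- paint(out, cyt_weak, c(255L, 255L, 0L))     # yellow
  out <- paint(out, cyt_ms, c(255L, 140L, 0L))       # orange
  out
}
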