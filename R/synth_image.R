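# Synthetic H&DAB-stained TMA core images with pixel-level ground
# truth.
#
# A circular tissue core is composed of tumour nests (elliptical nuclei
# on a jittered grid, each wrapped in a cytoplasmic annulus), stroma
# with a smooth fibrous texture, lymphocyte patches (dense small
# strongly-hematoxylin nuclei) and white slide background.  Staining is
# rendered by Beer-Lambert composition: per-pixel RGB =
# round(256 * 10^(-OD_rgb) - 1) where OD_rgb is the hematoxylin/DAB OD
# pair mapped through the standard stain vectors, with Gaussian OD
# noise added before exponentiation.  Because rendering and
# deconvolution share the same stain matrix, deconvolution recovers the
# drawn OD exactly up to noise and 8-bit rounding.

#' Staining and layout parameters for a synthetic TMA core
#'
#' @param fraction_positive_nuclei proportion of tumour nuclei drawn
#'   DAB-positive (Bernoulli per nucleus).
#' @param fraction_positive_cytoplasm proportion of tumour cells whose
#'   cytoplasmic annulus is drawn DAB-positive.
#' @param nuclear_dab_od DAB OD painted on positive nuclei.
#' @param cytoplasmic_dab_od DAB OD painted on positive cytoplasm.
#' @param hematoxylin_od hematoxylin OD of tumour nuclei; other tissue
#'   elements scale from it (cytoplasm 0.18x, stroma ~0.3x, lymphocyte
#'   nuclei 1.3x).
#' @param tumour_area_fraction target fraction of the core covered by
#'   tumour nests.
#' @param lymphocyte_area_fraction target fraction covered by
#'   lymphocyte patches.
#' @param nuclei_per_1000px2 tumour nuclear density (nuclei per 1000
#'   square pixels of tumour).
#' @param noise_sd standard deviation of Gaussian OD noise added to
#'   each RGB OD channel.
#' @return validated `stain_params` list.
#' @export
stain_params <- function(fraction_positive_nuclei = 0.5,
                         fraction_positive_cytoplasm = 0.6,
                         nuclear_dab_od = 0.9,
                         cytoplasmic_dab_od = 0.35,
                         hematoxylin_od = 0.8,
                         tumour_area_fraction = 0.45,
                         lymphocyte_area_fraction = 0.08,
                         nuclei_per_1000px2 = 6,
                         noise_sd = 0.04) {
  stopifnot_scalar_prop(fraction_positive_nuclei, "fraction_positive_nuclei")
  stopifnot_scalar_prop(fraction_positive_cytoplasm,
                        "fraction_positive_cytoplasm")
  stopifnot_scalar_prop(tumour_area_fraction, "tumour_area_fraction")
  stopifnot_scalar_prop(lymphocyte_area_fraction, "lymphocyte_area_fraction")
  stopifnot_nonneg(nuclear_dab_od, "nuclear_dab_od")
  stopifnot_nonneg(cytoplasmic_dab_od, "cytoplasmic_dab_od")
  stopifnot_nonneg(hematoxylin_od, "hematoxylin_od")
  stopifnot_nonneg(nuclei_per_1000px2, "nuclei_per_1000px2")
  stopifnot_nonneg(noise_sd, "noise_sd")
  if (tumour_area_fraction + lymphocyte_area_fraction > 1) {
    stop("tumour and lymphocyte area fractions must sum to at most 1",
         call. = FALSE)
  }
  structure(list(
    fraction_positive_nuclei = fraction_positive_nuclei,
    fraction_positive_cytoplasm = fraction_positive_cytoplasm,
    nuclear_dab_od = nuclear_dab_od,
    cytoplasmic_dab_od = cytoplasmic_dab_od,
    hematoxylin_od = hematoxylin_od,
    tumour_area_fraction = tumour_area_fraction,
    lymphocyte_area_fraction = lymphocyte_area_fraction,
    nuclei_per_1000px2 = nuclei_per_1000px2,
    noise_sd = noise_sd
  ), class = "stain_params")
}

#' Generate a synthetic TMA core image with ground truth
#'
#' Draws one circular H&DAB core and returns both the rendered 8-bit
#' RGB image and the generator's own bookkeeping: the five-class tissue
#' mask, disjoint nuclear and cytoplasmic masks, and the exact
#' compartment quantities that a perfect quantifier would recover.
#'
#' @param params a [stain_params()] object.
#' @param width,height image size in pixels (at least 64).
#' @param seed RNG seed; the call neither reads nor perturbs the
#'   session RNG.
#' @return list with `image` (h x w x 3 integer array, 0-255) and
#'   `truth`: `class_mask` (0 background, 1 tumour positive, 2 tumour
#'   negative, 3 stroma, 4 lymphocyte), `nuclear_mask`,
#'   `cytoplasm_mask`, `true_quant` (a `compartment_quant`), and the
#'   `params` used.
#' @export
generate_core_image <- function(params, width = 256L, height = 256L,
                                seed = 1L) {
  if (!inherits(params, "stain_params")) {
    stop("`params` must be created by stain_params()", call. = FALSE)
  }
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 64L || height < 64L) {
    stop("width and height must be at least 64 pixels", call. = FALSE)
  }
  with_seed(seed, draw_core(params, width, height))
}

draw_core <- function(p, w, h) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  R <- 0.47 * min(w, h)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  core <- (xs - cx)^2 + (ys - cy)^2 <= R^2
  core_px <- sum(core)

  tumour <- matrix(FALSE, h, w)
  target_tum <- p$tumour_area_fraction * core_px
  if (target_tum > 0) {
    r_lo <- 0.09 * min(w, h); r_hi <- 0.15 * min(w, h)
    tries <- 0L
    while (sum(tumour) < target_tum && tries < 400L) {
      tries <- tries + 1L
      ang <- runif(1, 0, 2 * pi)
      rad <- R * sqrt(runif(1))
      ncx <- cx + rad * cos(ang); ncy <- cy + rad * sin(ang)
      nrx <- runif(1, r_lo, r_hi); nry <- runif(1, r_lo, r_hi)
      idx <- ellipse_px(ncx, ncy, nrx, nry, h, w)
      idx <- idx[core[idx]]
      tumour[idx] <- TRUE
    }
  }

  lymph <- matrix(FALSE, h, w)
  target_lym <- p$lymphocyte_area_fraction * core_px
  if (target_lym > 0) {
    r_lo <- 0.04 * min(w, h); r_hi <- 0.07 * min(w, h)
    tries <- 0L
    while (sum(lymph) < target_lym && tries < 400L) {
      tries <- tries + 1L
      ang <- runif(1, 0, 2 * pi)
      rad <- R * sqrt(runif(1))
      pcx <- cx + rad * cos(ang); pcy <- cy + rad * sin(ang)
      prx <- runif(1, r_lo, r_hi); pry <- runif(1, r_lo, r_hi)
      idx <- ellipse_px(pcx, pcy, prx, pry, h, w)
      idx <- idx[core[idx] & !tumour[idx]]
      lymph[idx] <- TRUE
    }
  }

  stroma <- core & !tumour & !lymph

  # tumour nuclei on a jittered grid whose spacing matches the target
  # density; elliptical, clipped to tumour
  nuclear <- matrix(FALSE, h, w)
  cyto <- matrix(FALSE, h, w)
  pos_mask <- matrix(FALSE, h, w)
  nuc_pos_px <- 0L; nuc_tot_px <- 0L
  cyt_pos_px <- 0L; cyt_tot_px <- 0L
  n_nuclei <- 0L
  if (any(tumour) && p$nuclei_per_1000px2 > 0) {
    s <- sqrt(1000 / p$nuclei_per_1000px2)
    # annulus wide enough that cytoplasm tiles the nest between nuclei
    cyto_width <- 0.75 * s
    # jitter and radii bounded so neighbouring nuclei never touch:
    # min centre distance s - 0.24s = 0.76s > 2 * max semi-axis 0.74s;
    # min nucleus area ~33 px clears the 30 px segmentation floor
    gx <- seq(1, w, by = s); gy <- seq(1, h, by = s)
    centers_x <- rep(gx, times = length(gy)) +
      runif(length(gx) * length(gy), -0.12 * s, 0.12 * s)
    centers_y <- rep(gy, each = length(gx)) +
      runif(length(gx) * length(gy), -0.12 * s, 0.12 * s)
    ix <- pmin(pmax(round(centers_x), 1), w)
    iy <- pmin(pmax(round(centers_y), 1), h)
    keep <- tumour[(ix - 1L) * h + iy]
    centers_x <- centers_x[keep]; centers_y <- centers_y[keep]
    n <- length(centers_x)
    if (n > 0L) {
      ra <- 0.32 * s * runif(n, 0.85, 1.15)
      rb <- 0.27 * s * runif(n, 0.85, 1.15)
      nuc_pos <- runif(n) < p$fraction_positive_nuclei
      cyt_pos <- runif(n) < p$fraction_positive_cytoplasm
      nuc_idx <- vector("list", n)
      for (i in seq_len(n)) {
        idx <- ellipse_px(centers_x[i], centers_y[i], ra[i], rb[i], h, w)
        idx <- idx[tumour[idx] & !nuclear[idx]]
        nuc_idx[[i]] <- idx
        nuclear[idx] <- TRUE
      }
      for (i in seq_len(n)) {
        ann <- ellipse_px(centers_x[i], centers_y[i],
                          ra[i] + cyto_width, rb[i] + cyto_width, h, w)
        ann <- ann[tumour[ann] & !nuclear[ann] & !cyto[ann]]
        cyto[ann] <- TRUE
        if (cyt_pos[i]) pos_mask[ann] <- TRUE
        cyt_tot_px <- cyt_tot_px + length(ann)
        if (cyt_pos[i]) cyt_pos_px <- cyt_pos_px + length(ann)
      }
      for (i in seq_len(n)) {
        if (nuc_pos[i]) pos_mask[nuc_idx[[i]]] <- TRUE
        nuc_tot_px <- nuc_tot_px + length(nuc_idx[[i]])
        if (nuc_pos[i]) nuc_pos_px <- nuc_pos_px + length(nuc_idx[[i]])
      }
      n_nuclei <- sum(lengths(nuc_idx) > 0L)
    }
  }

  # lymphocyte nuclei: small, dense, strongly hematoxylin
  lymph_nuc <- matrix(FALSE, h, w)
  if (any(lymph)) {
    s <- 6
    gx <- seq(1, w, by = s); gy <- seq(1, h, by = s)
    lx <- rep(gx, times = length(gy)) +
      runif(length(gx) * length(gy), -2, 2)
    ly <- rep(gy, each = length(gx)) +
      runif(length(gx) * length(gy), -2, 2)
    ix <- pmin(pmax(round(lx), 1), w)
    iy <- pmin(pmax(round(ly), 1), h)
    keep <- lymph[(ix - 1L) * h + iy]
    lx <- lx[keep]; ly <- ly[keep]
    for (i in seq_along(lx)) {
      idx <- ellipse_px(lx[i], ly[i], 2.4, 2.4, h, w)
      idx <- idx[lymph[idx]]
      lymph_nuc[idx] <- TRUE
    }
  }

  # optical density composition
  od_h <- matrix(0, h, w)
  od_d <- matrix(0, h, w)
  if (any(stroma)) {
    tex <- smooth_noise(h, w, r = 6L)
    od_h[stroma] <- 0.30 * p$hematoxylin_od * (0.6 + 0.8 * tex[stroma])
  }
  od_h[lymph] <- 0.35 * p$hematoxylin_od
  od_h[lymph_nuc] <- 1.3 * p$hematoxylin_od
  od_h[tumour] <- 0.18 * p$hematoxylin_od
  od_h[nuclear] <- p$hematoxylin_od
  od_d[pos_mask & nuclear] <- p$nuclear_dab_od
  od_d[pos_mask & cyto] <- p$cytoplasmic_dab_od

  sm <- stain_matrix()
  od_rgb <- cbind(as.vector(od_h), as.vector(od_d)) %*% t(sm[, 1:2])
  if (p$noise_sd > 0) {
    od_rgb <- od_rgb + matrix(rnorm(length(od_rgb), 0, p$noise_sd),
                              nrow = nrow(od_rgb))
    od_rgb[od_rgb < 0] <- 0
  }
  image <- array(od_to_rgb(od_rgb), dim = c(h, w, 3L))
  storage.mode(image) <- "integer"

  class_mask <- matrix(0L, h, w)
  class_mask[stroma] <- TISSUE_LABELS[["stroma"]]
  class_mask[lymph] <- TISSUE_LABELS[["lymphocyte"]]
  class_mask[tumour & pos_mask] <- TISSUE_LABELS[["tumour_positive"]]
  class_mask[tumour & !pos_mask] <- TISSUE_LABELS[["tumour_negative"]]

  tumour_px <- sum(tumour)
  bin_of <- function(od, npx) {
    bins <- c(weak = 0L, medium = 0L, strong = 0L)
    if (npx > 0L) {
      b <- dab_bin(od)
      if (!is.na(b)) bins[b] <- npx
    }
    bins
  }
  true_quant <- new_compartment_quant(
    nuclear = list(
      total_px = nuc_tot_px, positive_px = nuc_pos_px,
      bins = bin_of(p$nuclear_dab_od, nuc_pos_px),
      mean_positive_od = if (nuc_pos_px > 0L) p$nuclear_dab_od else 0
    ),
    cytoplasmic = list(
      total_px = cyt_tot_px, positive_px = cyt_pos_px,
      bins = bin_of(p$cytoplasmic_dab_od, cyt_pos_px),
      mean_positive_od = if (cyt_pos_px > 0L) p$cytoplasmic_dab_od else 0
    ),
    tumour_px = tumour_px
  )
  true_quant$evaluable <- assess_evaluability(
    true_quant, min_tumour_px = default_min_tumour_px(w, h))

  list(
    image = image,
    truth = list(
      class_mask = class_mask,
      nuclear_mask = nuclear,
      cytoplasm_mask = cyto,
      n_nuclei = n_nuclei,
      true_quant = true_quant,
      params = p
    )
  )
}

# min tumour area default: 2000 px at the 512 x 512 reference scale,
# scaled with image area.
default_min_tumour_px <- function(w, h) {
  max(1L, as.integer(round(2000 * (as.numeric(w) * h) / (512 * 512))))
}
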