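# Spatial mapping: place biopsy punches in pre-expansion coordinates via
# the registration, and render per-protein z-score abundance maps over
# the tissue image.

#' Map punch annotations into pre-expansion geometry
#'
#' Punch centres (post-expansion um) are mapped through the registration
#' ([map_point()]); diameters are divided by the estimated linear
#' expansion factor; pre-expansion volume and cell estimates come from
#' the geometry calculus.
#'
#' @param punches data.frame with columns `punch_id`, `sample_id`,
#'   `x_um`, `y_um` (post-expansion centre), `diameter_um`
#'   (post-expansion), and optionally `region`, `replicate`.
#' @param registration an `expansion_registration` (or a plain
#'   [similarity_transform()], in which case the non-rigid residual is
#'   taken as zero).
#' @param thickness section thickness, um (default 30).
#' @param density_cells_per_nL cell density for the cell estimate.
#' @return the input with added `x_pre_um`, `y_pre_um`,
#'   `pre_diameter_um`, `pre_volume_nL`, `cell_estimate`.
#' @export
place_punches <- function(punches, registration, thickness = 30,
                          density_cells_per_nL = default_cell_density()) {
  need <- c("punch_id", "sample_id", "x_um", "y_um", "diameter_um")
  if (!all(need %in% names(punches)))
    stop_invalid("punch table needs columns ", paste(need, collapse = ", "))
  if (inherits(registration, "similarity_transform")) {
    tf <- registration
    pre_xy <- apply_similarity(tf, cbind(punches$x_um, punches$y_um))
    mask <- NULL
  } else if (inherits(registration, "expansion_registration")) {
    tf <- registration$similarity
    pre_xy <- predict(registration, cbind(punches$x_um, punches$y_um))
    mask <- registration$mask
  } else stop_invalid("'registration' must be an expansion_registration or similarity_transform")
  lef <- estimate_expansion_factor(tf)
  out <- punches
  out$x_pre_um <- pre_xy[, 1]
  out$y_pre_um <- pre_xy[, 2]
  out$pre_diameter_um <- punches$diameter_um / lef
  out$pre_volume_nL <- cylinder_volume_nL(out$pre_diameter_um, thickness)
  out$cell_estimate <- estimate_cells(out$pre_volume_nL, density_cells_per_nL)
  if (!is.null(mask)) {
    psz <- pixel_size(registration$pre)
    i <- pmin(pmax(round(pre_xy[, 2] / psz) + 1L, 1L), nrow(mask))
    j <- pmin(pmax(round(pre_xy[, 1] / psz) + 1L, 1L), ncol(mask))
    outside <- !mask[cbind(i, j)]
    if (any(outside))
      warning(sprintf("%d punch centre(s) fall outside the tissue mask: %s",
                      sum(outside),
                      paste(punches$punch_id[outside], collapse = ", ")))
  }
  out
}

#' Per-punch z-score abundance map for one protein
#'
#' Standardizes one protein's abundance over a cohort of punches
#' (z = (value - cohort mean) / cohort SD, sample SD) and renders the
#' punches as colour-coded circles over the pre-expansion tissue image.
#' Punches with a missing value are rendered hollow.
#'
#' @param am an [abundance_matrix()].
#' @param protein protein id (row of `am`).
#' @param punches data.frame with `punch_id`, `sample_id`, `x_pre_um`,
#'   `y_pre_um`, `pre_diameter_um` and optionally `replicate`
#'   (as produced by [place_punches()]).
#' @param cohort sample ids defining the standardization cohort; default
#'   all samples of `punches` found in `am`.
#' @param image optional background [gray_image()] (pre-expansion).
#' @param file optional PNG path for the rendered map.
#' @return data.frame of class `spatial_map` with per-punch `value` and
#'   `zscore` (`NA` where unobserved).
#' @export
zscore_map <- function(am, protein, punches, cohort = NULL, image = NULL,
                       file = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (!protein %in% rownames(am$intensities))
    stop_invalid("protein '", protein, "' not in the matrix")
  if (is.null(cohort)) cohort <- unique(punches$sample_id)
  cohort <- intersect(cohort, colnames(am$intensities))
  vals <- am$intensities[protein, cohort]
  obs <- vals[!is.na(vals)]
  if (length(obs) < 2L)
    stop_invalid("need >= 2 observed punches in the cohort")
  mu <- mean(obs); s <- sd(obs)
  if (s == 0) {
    warning("zero cohort SD: all z-scores set to 0")
    z <- setNames(ifelse(is.na(vals), NA_real_, 0), names(vals))
  } else {
    z <- (vals - mu) / s
  }
  out <- punches
  out$value <- unname(vals[match(punches$sample_id, cohort)])
  out$zscore <- unname(z[match(punches$sample_id, cohort)])
  class(out) <- c("spatial_map", "data.frame")
  attr(out, "protein") <- protein
  if (!is.null(file)) {
    png(file, width = 1000, height = 900, res = 140)
    on.exit(dev.off())
    draw_zscore_map(out, image)
  }
  out
}

draw_zscore_map <- function(map, image = NULL) {
  zr <- max(abs(map$zscore), 1, na.rm = TRUE)
  pal <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
  col_of <- function(z) pal[pmin(pmax(round((z + zr) / (2 * zr) * 254) + 1, 1), 255)]
  if (!is.null(image)) {
    psz <- pixel_size(image)
    ylim <- c((nrow(image) - 1) * psz, 0)
    image(x = (seq_len(ncol(image)) - 1) * psz,
          y = (seq_len(nrow(image)) - 1) * psz,
          z = t(unclass(image)), col = gray(seq(0.2, 1, length.out = 64)),
          xlab = "x (um)", ylab = "y (um)", ylim = ylim, useRaster = TRUE)
  } else {
    plot(map$x_pre_um, map$y_pre_um, type = "n", xlab = "x (um)",
         ylab = "y (um)", ylim = rev(range(map$y_pre_um) +
                                       c(-1, 1) * max(map$pre_diameter_um)),
         asp = 1)
  }
  filled <- !is.na(map$zscore)
  symbols(map$x_pre_um, map$y_pre_um, circles = map$pre_diameter_um / 2,
          inches = FALSE, add = TRUE,
          bg = ifelse(filled, col_of(map$zscore), NA),
          fg = "black")
  if (!is.null(map$replicate))
    text(map$x_pre_um, map$y_pre_um, map$replicate, cex = 0.7)
  title(sprintf("%s (z-score, cohort n = %d)", attr(map, "protein"),
                sum(filled)))
  invisible(map)
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("Spatial z-score map of %s: %d punches (%d observed)\n",
              attr(x, "protein"), nrow(x), sum(!is.na(x$zscore))))
  print.data.frame(utils::head(as.data.frame(
    x[, intersect(c("punch_id", "sample_id", "region", "replicate",
                    "zscore"), names(x))]), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}
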