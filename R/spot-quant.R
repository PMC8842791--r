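#' Background subtraction
#'
#' Subtracts a scalar background estimate from a channel image and clamps at
#' zero: either a fixed constant or a low percentile of the pixel intensity
#' distribution.
#'
#' @param img numeric matrix (AU).
#' @param estimator `"percentile"` or `"constant"`.
#' @param value the percentile in `[0, 100]`, or the constant (AU).
#' @return corrected matrix with attributes `background_estimator` and
#'   `background_value` recording what was subtracted.
#' @export
subtract_background <- function(img, estimator = c("percentile", "constant"),
                                value = 5) {
  check_image(img, "img")
  estimator <- match.arg(estimator)
  bg <- if (estimator == "percentile") {
    if (value < 0 || value > 100)
      stop("percentile must be in [0, 100]", call. = FALSE)
    as.numeric(stats::quantile(img, value / 100))
  } else value
  out <- pmax(img - bg, 0)
  attr(out, "background_estimator") <- estimator
  attr(out, "background_value") <- bg
  out
}

#' Unsharp sharpening
#'
#' 3x3 unsharp mask: `out = img - amount * Laplacian(img)` with the
#' 4-neighbor Laplacian and replicated edges, clamped at zero. `amount = 0`
#' is the identity; a flat field is always unchanged.
#'
#' @param img numeric matrix.
#' @param amount non-negative sharpening strength.
#' @return sharpened matrix.
#' @export
sharpen <- function(img, amount = 1) {
  check_image(img, "img")
  if (amount < 0) stop("amount must be >= 0", call. = FALSE)
  if (amount == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  up <- img[clamp_index(seq_len(nr) - 1L, nr), , drop = FALSE]
  dn <- img[clamp_index(seq_len(nr) + 1L, nr), , drop = FALSE]
  lf <- img[, clamp_index(seq_len(nc) - 1L, nc), drop = FALSE]
  rt <- img[, clamp_index(seq_len(nc) + 1L, nc), drop = FALSE]
  lap <- up + dn + lf + rt - 4 * img
  pmax(img - amount * lap, 0)
}

#' Rolling-ball background removal
#'
#' Estimates the smooth image background as the grayscale opening with a
#' disc structuring element of the given radius (the flat form of the
#' rolling-ball background filter) and subtracts it, enhancing features
#' narrower than the disc while removing broad background. The result is
#' non-negative, never exceeds the input, and the whole operation is
#' homogeneous: scaling the image by c > 0 scales the output by c.
#'
#' @param img numeric matrix.
#' @param radius ball radius in pixels (>= 1). A radius exceeding the
#'   smallest image dimension degenerates to subtracting the global minimum
#'   (with a warning).
#' @return background-subtracted matrix.
#' @export
rolling_ball <- function(img, radius) {
  check_image(img, "img")
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (radius > min(dim(img))) {
    warning("rolling-ball radius exceeds image size; ",
            "background taken as global minimum", call. = FALSE)
    return(img - min(img))
  }
  se <- ball_element(radius)
  pmax(img - opening_gray(img, se), 0)
}

#' Segment telomeric spots
#'
#' Thresholds the enhanced Cy3 image, removes connected components outside
#' an area band, and grows the surviving components outward by a few pixels
#' so the measurement mask recovers the PSF-spread tail of each spot.
#' Growth preserves component identity (each grown pixel is claimed by its
#' nearest component), so neighbouring spots never merge into one record.
#'
#' @param enhanced numeric matrix (output of the enhancement chain).
#' @param threshold `"noise"` (default: 4 times the median of the positive
#'   enhanced pixels, which sits just above the ceiling of the
#'   sharpened-and-opened noise floor and is insensitive to how bright the
#'   spot population is), `"otsu"`, or a fixed numeric threshold (AU);
#'   foreground is strictly above the threshold.
#' @param min_area,max_area component area band in pixels (applied before
#'   growing).
#' @param connectivity 4 or 8.
#' @param grow growth rounds (px) applied after size filtering; 0 disables.
#' @return integer spot label mask (0 = background, k = spot k; nonzero
#'   pixels form the binary measurement mask) with attribute
#'   `threshold_value`.
#' @export
segment_spots <- function(enhanced, threshold = "noise", min_area = 2L,
                          max_area = 1000L, connectivity = 8L, grow = 2.5) {
  check_image(enhanced, "enhanced")
  stopifnot(min_area >= 1, max_area > min_area, grow >= 0)
  thr <- if (identical(threshold, "noise")) {
    pos <- enhanced[enhanced > 0]
    if (length(pos)) 4 * stats::median(pos) else Inf
  } else if (identical(threshold, "otsu")) otsu_threshold(enhanced)
  else as.numeric(threshold)
  mask <- enhanced > thr
  lab <- matrix(0L, nrow(enhanced), ncol(enhanced))
  if (any(mask)) {
    lab <- label_components(mask, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    bad <- which(sizes < min_area | sizes > max_area)
    if (length(bad)) {
      lab[lab %in% bad] <- 0L
      if (any(lab > 0L)) {
        ids <- sort(unique(lab[lab > 0L]))
        lab[lab > 0L] <- match(lab[lab > 0L], ids)
      }
    }
    if (grow > 0 && any(lab > 0L)) lab <- grow_labels(lab, grow)
  }
  attr(lab, "threshold_value") <- thr
  lab
}

#' Measure telomeric spots
#'
#' Labels the connected components of a binary spot mask and measures each
#' on the (unenhanced) Cy3 image: area `A` (px), mean intensity `I` (AU) and
#' spot value `v = I * A` (AU*px, the integrated intensity). Each spot is
#' assigned to the cell whose ROI label lies under its centroid; a centroid
#' on background gives `cell_label 0`.
#'
#' @param mask spot mask: either a logical matrix (connected components are
#'   labeled here) or an integer spot label mask from [segment_spots()]
#'   (labels used as-is).
#' @param raw_cy3 Cy3 image to measure on (background-normalized but not
#'   enhanced).
#' @param rois integer ROI label matrix.
#' @param connectivity 4 or 8.
#' @return data.frame: spot_id, cell_label, area, mean_intensity,
#'   spot_value, centroid_x, centroid_y.
#' @export
extract_spots <- function(mask, raw_cy3, rois, connectivity = 8L) {
  if (!all(dim(mask) == dim(raw_cy3)) || !all(dim(mask) == dim(rois)))
    stop("mask, raw_cy3 and rois must share dimensions", call. = FALSE)
  lab <- if (is.integer(mask) && !is.logical(mask)) mask
         else label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0)
    return(data.frame(spot_id = integer(0), cell_label = integer(0),
                      area = numeric(0), mean_intensity = numeric(0),
                      spot_value = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0)))
  fg <- which(lab > 0L)
  ids <- lab[fg]
  nr <- nrow(lab)
  ys <- ((fg - 1L) %% nr) + 1L
  xs <- ((fg - 1L) %/% nr) + 1L
  area <- as.numeric(tabulate(ids, n))
  tot <- as.numeric(rowsum(raw_cy3[fg], ids))
  cx <- as.numeric(rowsum(as.numeric(xs), ids)) / area
  cy <- as.numeric(rowsum(as.numeric(ys), ids)) / area
  cell <- rois[cbind(clamp_index(round(cy), nrow(rois)),
                     clamp_index(round(cx), ncol(rois)))]
  data.frame(spot_id = seq_len(n), cell_label = as.integer(cell),
             area = area, mean_intensity = tot / area,
             spot_value = tot, centroid_x = cx, centroid_y = cy)
}

#' Per-cell telomere fluorescence intensity
#'
#' Sums each cell's spot values, measures its total DAPI signal over the ROI
#' and forms the per-cell TFI `= total_spot_value / dapi_total` (optionally
#' times a display scale). Cells with no detected spots are retained with
#' `tfi = 0`; cells whose DAPI total is not positive are excluded with a
#' recorded warning.
#'
#' @param spots data.frame from [extract_spots()]; spots with
#'   `cell_label 0` (background) are ignored.
#' @param dapi DAPI image to integrate (background-normalized).
#' @param rois integer ROI label matrix aligned with `dapi`.
#' @param scale display multiplier applied to the TFI ratio (recorded in the
#'   `tfi_scale` attribute).
#' @return data.frame: cell_label, n_spots, total_spot_value, dapi_total,
#'   tfi; attribute `log` carries exclusion messages.
#' @export
quantify_cells <- function(spots, dapi, rois, scale = 1) {
  if (!all(dim(dapi) == dim(rois)))
    stop("dapi and rois must share dimensions", call. = FALSE)
  stopifnot(scale > 0)
  labs <- sort(unique(rois[rois > 0L]))
  run_log <- character(0)
  if (length(labs) == 0) {
    out <- data.frame(cell_label = integer(0), n_spots = integer(0),
                      total_spot_value = numeric(0), dapi_total = numeric(0),
                      tfi = numeric(0))
    attr(out, "log") <- run_log
    attr(out, "tfi_scale") <- scale
    return(out)
  }
  fg <- which(rois > 0L)
  dsum <- rowsum(dapi[fg], rois[fg])
  dtot <- as.numeric(dsum)[match(labs, as.integer(rownames(dsum)))]
  sp <- spots[spots$cell_label > 0L, , drop = FALSE]
  nsp <- integer(length(labs))
  vsum <- numeric(length(labs))
  if (nrow(sp)) {
    nsp <- as.integer(table(factor(sp$cell_label, levels = labs)))
    agg_v <- rowsum(sp$spot_value, sp$cell_label)
    m <- match(labs, as.integer(rownames(agg_v)))
    vsum <- ifelse(is.na(m), 0, as.numeric(agg_v)[m])
  }
  out <- data.frame(cell_label = labs, n_spots = nsp,
                    total_spot_value = vsum, dapi_total = dtot,
                    tfi = ifelse(dtot > 0, scale * vsum / dtot, NA_real_))
  bad <- which(!(dtot > 0))
  if (length(bad)) {
    msg <- paste0("excluded ", length(bad),
                  " cell(s) with non-positive DAPI total: ",
                  paste(labs[bad], collapse = ", "))
    warning(msg, call. = FALSE)
    run_log <- c(run_log, msg)
    out <- out[-bad, , drop = FALSE]
  }
  attr(out, "log") <- run_log
  attr(out, "tfi_scale") <- scale
  out
}

#' Full spot-quantification chain for one image pair
#'
#' Applies the measurement chain to a Cy3/DAPI pair plus ROI labels:
#' background subtraction on both channels, sharpening and rolling-ball
#' enhancement of the Cy3 channel (used only to build the segmentation
#' mask), then spot measurement on the background-subtracted Cy3 image and
#' DAPI integration per ROI.
#'
#' @param cy3,dapi channel images (AU).
#' @param rois integer ROI label matrix.
#' @param config configuration list, see [pipeline_config()].
#' @return list with `cells`, `spots` (data.frames) and `log`.
#' @export
quantify_image <- function(cy3, dapi, rois, config = pipeline_config()) {
  cfg <- config
  cy3_bg <- subtract_background(cy3, cfg$background$method,
                                cfg$background$value)
  dapi_bg <- subtract_background(dapi, cfg$background$method,
                                 cfg$background$value)
  enh <- rolling_ball(sharpen(cy3_bg, cfg$sharpen$amount),
                      cfg$rollingball$radius)
  mask <- segment_spots(enh, cfg$segment$threshold, cfg$segment$min_area,
                        cfg$segment$max_area, cfg$segment$connectivity,
                        cfg$segment$grow)
  spots <- extract_spots(mask, cy3_bg, rois, cfg$segment$connectivity)
  cells <- quantify_cells(spots, dapi_bg, rois, cfg$tfi$scale)
  list(cells = cells, spots = spots, log = attr(cells, "log"))
}
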