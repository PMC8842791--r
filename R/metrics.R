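# Cell tables: one row per measured cell with at least the columns
# specimen_id, image_id, cell_label, compartment ("epithelial"/"stromal"),
# subtype ("mucus"/"non-mucus"/"unknown"/"not-applicable"), tfi.

check_cells <- function(cells, need = c("tfi")) {
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols))
    stop("cell table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  invisible(cells)
}

#' Per-cell epithelial/stromal telomere length ratios
#'
#' Divides each epithelial cell's TFI by the mean TFI of all stromal cells
#' of the same image, correcting per-image staining and exposure variation.
#' Stromal cells receive no ratio. An image with epithelial cells but no
#' stromal cells is an error (no silent fallback to cohort-level stroma).
#'
#' @param cells cell table with columns image_id, compartment, tfi (plus any
#'   carried columns).
#' @return the epithelial rows of `cells` with an added `ratio` column.
#' @export
epithelial_stromal_ratios <- function(cells) {
  check_cells(cells, c("image_id", "compartment", "tfi"))
  out <- list()
  for (img in unique(cells$image_id)) {
    sub <- cells[cells$image_id == img, , drop = FALSE]
    epi <- sub[sub$compartment == "epithelial", , drop = FALSE]
    if (nrow(epi) == 0) next
    stromal_tfi <- sub$tfi[sub$compartment == "stromal"]
    if (length(stromal_tfi) == 0)
      stop("image '", img, "' has no stromal cells; ",
           "epithelial/stromal ratio undefined", call. = FALSE)
    epi$ratio <- epi$tfi / mean(stromal_tfi)
    out[[length(out) + 1L]] <- epi
  }
  if (length(out) == 0) {
    cells$ratio <- numeric(0)
    return(cells[0, , drop = FALSE])
  }
  do.call(rbind, out)
}

#' Specimen mean of a per-cell telomere value
#'
#' Arithmetic mean over all contributing cells of one specimen (cells pooled
#' across images, not a mean of image means).
#'
#' @param cells cell table for one specimen.
#' @param value column to average: `"tfi"` or `"ratio"`.
#' @return list with `mean` and contributing `n`.
#' @export
specimen_mean <- function(cells, value = c("tfi", "ratio")) {
  value <- match.arg(value)
  check_cells(cells, value)
  x <- cells[[value]]
  x <- x[!is.na(x)]
  if (length(x) < 1) stop("no contributing cells", call. = FALSE)
  list(mean = mean(x), n = length(x))
}

#' Cell-to-cell telomere length variation (TLV)
#'
#' Sample standard deviation (n - 1 denominator) of the chosen per-cell
#' telomere value within one biological specimen. Low TLV indicates uniform
#' telomere lengths, consistent with clonal expansion.
#'
#' @param cells cell table for one specimen.
#' @param value `"tfi"` or `"ratio"`.
#' @return the standard deviation (>= 0).
#' @export
tlv <- function(cells, value = c("tfi", "ratio")) {
  value <- match.arg(value)
  check_cells(cells, value)
  x <- cells[[value]]
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("TLV requires at least 2 cells", call. = FALSE)
  stats::sd(x)
}

#' Mucus and non-mucus mean ratios for one specimen
#'
#' Mean epithelial/stromal ratio separately for mucus and non-mucus
#' epithelial cells; a specimen lacking one subtype yields `NA` for that
#' side (to be dropped pairwise by a paired test). Cells with subtype
#' `"unknown"`/`"not-applicable"` are ignored here.
#'
#' @param cells cell table for one specimen, with a `ratio` column (see
#'   [epithelial_stromal_ratios()]).
#' @return list with `mucus_mean_ratio` and `nonmucus_mean_ratio`.
#' @export
subtype_means <- function(cells) {
  check_cells(cells, c("subtype", "ratio"))
  sub_mean <- function(s) {
    x <- cells$ratio[cells$subtype == s & !is.na(cells$ratio)]
    if (length(x) < 1) NA_real_ else mean(x)
  }
  list(mucus_mean_ratio = sub_mean("mucus"),
       nonmucus_mean_ratio = sub_mean("non-mucus"))
}

#' Per-specimen summary table
#'
#' Builds one row per specimen: cell count, mean TFI, mean epithelial/
#' stromal ratio, subtype mean ratios and TLV. TLV is computed on the
#' epithelial cells' raw TFI by default, switchable to the per-cell ratio.
#'
#' @param cells cohort cell table (specimen_id, tissue_class, image_id,
#'   compartment, subtype, tfi).
#' @param tlv_value `"tfi"` or `"ratio"`: per-cell value whose specimen SD
#'   is reported as TLV (epithelial cells only).
#' @return data.frame with one row per specimen; also returns the per-cell
#'   ratio table as attribute `ratios`.
#' @export
summarize_specimens <- function(cells, tlv_value = c("tfi", "ratio")) {
  tlv_value <- match.arg(tlv_value)
  check_cells(cells, c("specimen_id", "image_id", "compartment", "tfi"))
  if (is.null(cells$subtype)) cells$subtype <- "unknown"
  if (is.null(cells$tissue_class)) cells$tissue_class <- NA_character_
  ratios <- epithelial_stromal_ratios(cells)
  rows <- list()
  for (sid in unique(cells$specimen_id)) {
    sub <- cells[cells$specimen_id == sid, , drop = FALSE]
    rsub <- ratios[ratios$specimen_id == sid, , drop = FALSE]
    epi <- sub[sub$compartment == "epithelial", , drop = FALSE]
    sm <- subtype_means(rsub)
    tlv_cells <- if (tlv_value == "ratio") rsub else epi
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = sid,
      tissue_class = sub$tissue_class[1],
      n_cells = nrow(sub),
      mean_tfi = specimen_mean(sub, "tfi")$mean,
      mean_ratio = if (nrow(rsub)) specimen_mean(rsub, "ratio")$mean
                   else NA_real_,
      mucus_mean_ratio = sm$mucus_mean_ratio,
      nonmucus_mean_ratio = sm$nonmucus_mean_ratio,
      tlv = if (nrow(tlv_cells) >= 2) tlv(tlv_cells, tlv_value)
            else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "ratios") <- ratios
  out
}
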