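#' Acquisition settings for the synthetic qFISH renderer
#'
#' Describes the virtual microscope/camera: frame size, point-spread blur,
#' additive background (constant offset plus a linear gradient along x),
#' Poisson shot noise, Gaussian read noise, bit depth and the per-channel
#' exposure gains (held constant within a cohort, mirroring constant
#' exposure-time acquisition). The noiseless render is linear in the true
#' signal; noise and quantization are applied afterwards.
#'
#' @param width,height frame size in pixels (>= 16).
#' @param psf_sigma Gaussian point-spread sigma in pixels (0 disables blur).
#' @param background_offset additive background, AU.
#' @param background_gradient additive background slope, AU per pixel along x.
#' @param read_noise_sd Gaussian read noise SD, AU.
#' @param shot_noise logical; Poisson-resample each pixel.
#' @param bit_depth bits per pixel; values are clipped to `[0, 2^bit_depth-1]`.
#' @param exposure_scale_cy3,exposure_scale_dapi dimensionless channel gains.
#' @param spot_sigma sigma (pixels) of the rendered telomeric spot blobs; the
#'   blob's integrated (not peak) intensity equals the drawn spot signal.
#' @param roi_margin widening (pixels) of each ROI label beyond the rendered
#'   nucleus, emulating generous manual circumscription of the blurred DAPI
#'   blob; margins never overwrite another cell's nucleus.
#' @return a list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(width = 256L, height = 256L, psf_sigma = 1,
                             background_offset = 100,
                             background_gradient = 0.05,
                             read_noise_sd = 5, shot_noise = TRUE,
                             bit_depth = 16L,
                             exposure_scale_cy3 = 1, exposure_scale_dapi = 1,
                             spot_sigma = 1.5, roi_margin = 2) {
  stopifnot(width >= 16, height >= 16, psf_sigma >= 0,
            background_offset >= 0, background_gradient >= 0,
            read_noise_sd >= 0, bit_depth >= 8,
            exposure_scale_cy3 >= 0, exposure_scale_dapi >= 0,
            spot_sigma > 0, roi_margin >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 psf_sigma = psf_sigma,
                 background_offset = background_offset,
                 background_gradient = background_gradient,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 bit_depth = as.integer(bit_depth),
                 exposure_scale_cy3 = exposure_scale_cy3,
                 exposure_scale_dapi = exposure_scale_dapi,
                 spot_sigma = spot_sigma, roi_margin = roi_margin),
            class = "acquisition_spec")
}

#' Cell-population settings for one tissue compartment
#'
#' One compartment of a synthetic specimen: how many nuclei, their size,
#' spatial arrangement (crypt rings for epithelium, scattered for stroma),
#' the per-cell telomeric spot count (Poisson) and per-spot integrated
#' intensity (lognormal, AU*px), and the total nuclear DAPI signal
#' (lognormal, AU). Mucus (goblet) cells can render vacuole holes in the
#' DAPI channel only; the ROI label mask keeps the full nucleus.
#'
#' @param compartment `"epithelial"` or `"stromal"`.
#' @param n_cells number of cells.
#' @param subtype `"not-applicable"`, `"mucus"` or `"non-mucus"`.
#' @param nucleus_radius length-2 `c(mean, sd)` of the nuclear semi-major
#'   axis in pixels (minor axis = 0.65 major).
#' @param spots_per_cell_lambda Poisson mean spot count per cell.
#' @param spot_intensity_mu,spot_intensity_sigma log-scale parameters of the
#'   lognormal integrated spot signal (mean `exp(mu + sigma^2/2)` AU*px).
#' @param dapi_total_mu,dapi_total_sigma log-scale parameters of the
#'   lognormal total nuclear DAPI signal (AU).
#' @param arrangement `"crypt-ring"` or `"scattered"`; defaults to crypt
#'   rings for epithelial cells and scattered placement for stromal cells.
#' @param vacuole render vacuole holes in the DAPI channel (mucus look).
#' @return a list of class `compartment_spec`.
#' @export
compartment_spec <- function(compartment = c("epithelial", "stromal"),
                             n_cells,
                             subtype = c("not-applicable", "mucus", "non-mucus"),
                             nucleus_radius = c(6, 0.8),
                             spots_per_cell_lambda = 6,
                             spot_intensity_mu = log(5000) - 0.35^2 / 2,
                             spot_intensity_sigma = 0.35,
                             dapi_total_mu = log(5e4) - 0.2^2 / 2,
                             dapi_total_sigma = 0.2,
                             arrangement = NULL,
                             vacuole = FALSE) {
  compartment <- match.arg(compartment)
  subtype <- match.arg(subtype)
  if (is.null(arrangement))
    arrangement <- if (compartment == "epithelial") "crypt-ring" else "scattered"
  arrangement <- match.arg(arrangement, c("crypt-ring", "scattered"))
  stopifnot(n_cells >= 0, length(nucleus_radius) == 2, nucleus_radius[1] > 0,
            nucleus_radius[2] >= 0, spots_per_cell_lambda >= 0,
            spot_intensity_sigma >= 0, dapi_total_sigma >= 0)
  structure(list(compartment = compartment, subtype = subtype,
                 n_cells = as.integer(n_cells),
                 nucleus_radius = as.numeric(nucleus_radius),
                 spots_per_cell_lambda = spots_per_cell_lambda,
                 spot_intensity_mu = spot_intensity_mu,
                 spot_intensity_sigma = spot_intensity_sigma,
                 dapi_total_mu = dapi_total_mu,
                 dapi_total_sigma = dapi_total_sigma,
                 arrangement = arrangement, vacuole = isTRUE(vacuole)),
            class = "compartment_spec")
}

#' Full description of one synthetic specimen
#'
#' @param specimen_id identifier, unique within a cohort.
#' @param tissue_class free tissue label (e.g. `"cardia"`, `"BE"`, `"LGD"`).
#' @param acquisition an [acquisition_spec()].
#' @param compartments list of [compartment_spec()] objects.
#' @param seed integer RNG seed for this specimen.
#' @return a list of class `specimen_spec`.
#' @export
specimen_spec <- function(specimen_id, tissue_class,
                          acquisition = acquisition_spec(),
                          compartments, seed = 1L) {
  stopifnot(inherits(acquisition, "acquisition_spec"),
            is.list(compartments), length(compartments) >= 1)
  for (cc in compartments)
    stopifnot(inherits(cc, "compartment_spec"))
  structure(list(specimen_id = as.character(specimen_id),
                 tissue_class = as.character(tissue_class),
                 acquisition = acquisition, compartments = compartments,
                 seed = as.integer(seed)),
            class = "specimen_spec")
}

#' Paper-style specimen template
#'
#' Convenience constructor for a specimen with crypt-arranged epithelium over
#' scattered stroma, where epithelial telomeric signal is a chosen multiple
#' of the stromal signal (the quantity the epithelial/stromal ratio should
#' recover). Optionally splits the epithelium into mucus and non-mucus
#' subtypes with a mucus/non-mucus signal factor.
#'
#' @param tissue_class tissue label.
#' @param epithelial_stromal_ratio true epithelial:stromal mean-signal ratio.
#' @param n_epithelial,n_stromal cell counts.
#' @param mucus_fraction fraction of epithelial cells rendered as mucus
#'   (vacuolated) cells; 0 keeps a single epithelial compartment.
#' @param mucus_nonmucus_factor true mucus:non-mucus signal factor (applied on
#'   top of `epithelial_stromal_ratio`, which then describes non-mucus cells).
#' @param spot_intensity_sigma lognormal sdlog of per-spot signal (cell-to-cell
#'   heterogeneity knob; larger values raise TLV).
#' @param acquisition an [acquisition_spec()].
#' @param seed RNG seed (overridden per specimen by [simulate_cohort()]).
#' @return a `specimen_spec`.
#' @export
specimen_template <- function(tissue_class, epithelial_stromal_ratio = 1,
                              n_epithelial = 65L, n_stromal = 35L,
                              mucus_fraction = 0,
                              mucus_nonmucus_factor = 1,
                              spot_intensity_sigma = 0.35,
                              acquisition = acquisition_spec(),
                              seed = 1L) {
  stopifnot(epithelial_stromal_ratio > 0, mucus_fraction >= 0,
            mucus_fraction <= 1, mucus_nonmucus_factor > 0)
  base_mu <- log(5000) - spot_intensity_sigma^2 / 2
  stroma <- compartment_spec("stromal", n_cells = n_stromal,
                             nucleus_radius = c(5.5, 0.7),
                             spot_intensity_mu = base_mu,
                             spot_intensity_sigma = spot_intensity_sigma)
  epi_mu <- base_mu + log(epithelial_stromal_ratio)
  n_mucus <- round(mucus_fraction * n_epithelial)
  comps <- list()
  if (n_mucus > 0) {
    comps <- c(comps, list(compartment_spec(
      "epithelial", n_cells = n_mucus, subtype = "mucus",
      spot_intensity_mu = epi_mu + log(mucus_nonmucus_factor),
      spot_intensity_sigma = spot_intensity_sigma, vacuole = TRUE)))
  }
  if (n_epithelial - n_mucus > 0) {
    comps <- c(comps, list(compartment_spec(
      "epithelial", n_cells = n_epithelial - n_mucus,
      subtype = if (n_mucus > 0) "non-mucus" else "not-applicable",
      spot_intensity_mu = epi_mu,
      spot_intensity_sigma = spot_intensity_sigma)))
  }
  comps <- c(comps, list(stroma))
  specimen_spec(paste0(tissue_class, "_template"), tissue_class,
                acquisition, comps, seed = seed)
}

# ---- geometry helpers ------------------------------------------------------

# pixel coordinates (y, x) inside a rotated ellipse, plus linear indices
ellipse_pixels <- function(nr, nc, cx, cy, a, b, theta) {
  x0 <- max(1L, as.integer(floor(cx - a))); x1 <- min(nc, as.integer(ceiling(cx + a)))
  y0 <- max(1L, as.integer(floor(cy - a))); y1 <- min(nr, as.integer(ceiling(cy + a)))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(NULL)
  yy <- rep(ys, times = length(xs))[inside]
  xx <- rep(xs, each = length(ys))[inside]
  list(y = yy, x = xx, idx = (xx - 1L) * nr + yy)
}

# uniform random point inside a rotated ellipse scaled by `shrink`
point_in_ellipse <- function(cx, cy, a, b, theta, shrink = 1) {
  r <- sqrt(stats::runif(1)); ang <- stats::runif(1, 0, 2 * pi)
  u <- shrink * a * r * cos(ang); v <- shrink * b * r * sin(ang)
  c(x = cx + u * cos(theta) - v * sin(theta),
    y = cy + u * sin(theta) + v * cos(theta))
}

overlaps_any <- function(cx, cy, r, placed, gap = 1) {
  if (nrow(placed) == 0) return(FALSE)
  any((placed$cx - cx)^2 + (placed$cy - cy)^2 < (placed$r + r + gap)^2)
}

MAX_PLACE_ATTEMPTS <- 200L

place_scattered <- function(n, radii, nr, nc, placed, compartment) {
  out <- placed[0, ]
  for (i in seq_len(n)) {
    a <- radii[i]
    ok <- FALSE
    for (att in seq_len(MAX_PLACE_ATTEMPTS)) {
      cx <- stats::runif(1, a + 2, nc - a - 1)
      cy <- stats::runif(1, a + 2, nr - a - 1)
      if (!overlaps_any(cx, cy, a, rbind(placed, out))) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place ", compartment, " cell without overlap after ",
           MAX_PLACE_ATTEMPTS, " attempts", call. = FALSE)
    out <- rbind(out, data.frame(cx = cx, cy = cy, r = a,
                                 theta = stats::runif(1, 0, pi)))
  }
  out
}

# crypt-ring placement: cells in rings of ~10, tangentially aligned ellipses
place_crypts <- function(n, radii, a_mean, nr, nc, placed, compartment) {
  out <- placed[0, ]
  remaining <- n
  i0 <- 0L
  while (remaining > 0) {
    m <- min(10L, remaining)
    ring_r <- max(m * (2 * a_mean * 1.25) / (2 * pi), 2.5 * a_mean)
    crypt_r <- ring_r + a_mean
    ok <- FALSE
    for (att in seq_len(MAX_PLACE_ATTEMPTS)) {
      ccx <- stats::runif(1, crypt_r + 2, nc - crypt_r - 1)
      ccy <- stats::runif(1, crypt_r + 2, nr - crypt_r - 1)
      if (!overlaps_any(ccx, ccy, crypt_r, rbind(placed, out), gap = 2)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not place ", compartment,
           " crypt without overlap after ", MAX_PLACE_ATTEMPTS,
           " attempts", call. = FALSE)
    phase <- stats::runif(1, 0, 2 * pi)
    ang <- phase + 2 * pi * (seq_len(m) - 1) / m +
      stats::runif(m, -0.04, 0.04)
    new <- data.frame(cx = ccx + ring_r * cos(ang),
                      cy = ccy + ring_r * sin(ang),
                      r = radii[i0 + seq_len(m)],
                      theta = ang + pi / 2)
    out <- rbind(out, new)
    i0 <- i0 + m
    remaining <- remaining - m
  }
  out
}

# ---- rendering -------------------------------------------------------------

render_channel <- function(signal, gain, acq) {
  maxval <- 2^acq$bit_depth - 1
  img <- gaussian_blur(signal * gain, acq$psf_sigma)
  signal_px <- img > 1e-9
  bg <- acq$background_offset +
    acq$background_gradient * matrix(rep(0:(acq$width - 1L), each = acq$height),
                                     acq$height, acq$width)
  img <- img + bg
  noisy <- acq$shot_noise || acq$read_noise_sd > 0
  if (acq$shot_noise)
    img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                  nrow(img), ncol(img))
  if (acq$read_noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, acq$read_noise_sd)
  if (noisy) img <- round(img)
  n_clip <- sum(img > maxval & signal_px)
  img[img > maxval] <- maxval
  img[img < 0] <- 0
  list(img = img, n_clip = n_clip, n_signal = sum(signal_px))
}

#' Simulate one two-channel qFISH specimen
#'
#' Renders a Cy3 telomere channel, a DAPI nuclear channel, an integer ROI
#' label mask and a ground-truth table for one specimen. Nuclei are filled
#' ellipses placed without overlap (crypt rings or scattered, per
#' compartment); each telomeric spot is a Gaussian blob whose integrated
#' intensity over the cell mask equals its drawn signal, so the noiseless
#' Cy3 integral over a cell equals `T_true * exposure_scale_cy3`. Vacuole
#' holes are carved in the DAPI render only; the label mask keeps the full
#' nucleus. The same spec and seed reproduce identical output bitwise.
#'
#' @param spec a [specimen_spec()].
#' @return list of class `qfish_specimen` with elements `cy3`, `dapi`
#'   (numeric matrices, AU), `labels` (integer matrix), `truth` (data.frame:
#'   cell_label, compartment, subtype, T_true, D_true, centroid_x,
#'   centroid_y) and `log` (character vector of recorded warnings).
#' @export
simulate_specimen <- function(spec) {
  stopifnot(inherits(spec, "specimen_spec"))
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  })
  set.seed(spec$seed)
  acq <- spec$acquisition
  nr <- acq$height; nc <- acq$width
  cy3_sig <- matrix(0, nr, nc)
  dapi_sig <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  run_log <- character(0)
  placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                       theta = numeric(0))
  truth <- list()
  margins <- list()
  lab <- 0L
  for (comp in spec$compartments) {
    if (comp$n_cells == 0) next
    radii <- pmax(2, stats::rnorm(comp$n_cells, comp$nucleus_radius[1],
                                  comp$nucleus_radius[2]))
    pos <- if (comp$arrangement == "crypt-ring")
      place_crypts(comp$n_cells, radii, comp$nucleus_radius[1], nr, nc,
                   placed, comp$compartment)
    else
      place_scattered(comp$n_cells, radii, nr, nc, placed, comp$compartment)
    placed <- rbind(placed, pos)
    for (i in seq_len(comp$n_cells)) {
      lab <- lab + 1L
      a <- pos$r[i]; b <- 0.65 * a
      cx <- pos$cx[i]; cy <- pos$cy[i]; theta <- pos$theta[i]
      px <- ellipse_pixels(nr, nc, cx, cy, a, b, theta)
      free <- labels[px$idx] == 0L
      idx <- px$idx[free]; yy <- px$y[free]; xx <- px$x[free]
      labels[idx] <- lab
      if (acq$roi_margin > 0)
        margins[[lab]] <- ellipse_pixels(nr, nc, cx, cy, a + acq$roi_margin,
                                         b + acq$roi_margin, theta)$idx
      # DAPI: lognormal total, uniform over the nucleus; vacuole holes are
      # carved before renormalizing so the rendered total stays D_true
      D_true <- stats::rlnorm(1, comp$dapi_total_mu, comp$dapi_total_sigma)
      w <- rep(1, length(idx))
      if (comp$vacuole) {
        n_vac <- 1L + stats::rpois(1, 1)
        for (v in seq_len(n_vac)) {
          ctr <- point_in_ellipse(cx, cy, a, b, theta, shrink = 0.6)
          vr <- stats::runif(1, 0.2, 0.35) * b
          w[(xx - ctr["x"])^2 + (yy - ctr["y"])^2 < vr^2] <- 0
        }
        if (sum(w) == 0) w <- rep(1, length(idx))
      }
      dapi_sig[idx] <- dapi_sig[idx] + D_true * w / sum(w)
      # telomeric spots: Poisson count, lognormal integrated intensity,
      # Gaussian blob (support truncated at 2.5 sigma) normalized on the mask
      n_sp <- stats::rpois(1, comp$spots_per_cell_lambda)
      T_true <- 0
      for (s in seq_len(n_sp)) {
        v <- stats::rlnorm(1, comp$spot_intensity_mu, comp$spot_intensity_sigma)
        ctr <- point_in_ellipse(cx, cy, a, b, theta, shrink = 0.75)
        d2 <- (xx - ctr["x"])^2 + (yy - ctr["y"])^2
        ws <- exp(-d2 / (2 * acq$spot_sigma^2))
        ws[d2 > (2.5 * acq$spot_sigma)^2] <- 0
        if (sum(ws) == 0) ws[which.min(d2)] <- 1
        cy3_sig[idx] <- cy3_sig[idx] + v * ws / sum(ws)
        T_true <- T_true + v
      }
      truth[[lab]] <- data.frame(cell_label = lab,
                                 compartment = comp$compartment,
                                 subtype = comp$subtype,
                                 T_true = T_true, D_true = D_true,
                                 centroid_x = cx, centroid_y = cy,
                                 stringsAsFactors = FALSE)
    }
  }
  # ROI margins claim only pixels no nucleus owns, emulating generous
  # manual circumscription; cores always keep their own pixels
  for (l in seq_along(margins)) {
    mi <- margins[[l]]
    mi <- mi[labels[mi] == 0L]
    labels[mi] <- l
  }
  cy3_r <- render_channel(cy3_sig, acq$exposure_scale_cy3, acq)
  dapi_r <- render_channel(dapi_sig, acq$exposure_scale_dapi, acq)
  for (ch in list(c("Cy3", cy3_r$n_clip, cy3_r$n_signal),
                  c("DAPI", dapi_r$n_clip, dapi_r$n_signal))) {
    n_clip <- as.numeric(ch[2]); n_sig <- as.numeric(ch[3])
    if (n_sig > 0 && n_clip / n_sig > 0.01) {
      msg <- sprintf("%s: clipping affected %.1f%% of signal pixels in %s",
                     ch[1], 100 * n_clip / n_sig, spec$specimen_id)
      warning(msg, call. = FALSE)
      run_log <- c(run_log, msg)
    }
  }
  truth_df <- if (lab > 0) do.call(rbind, truth) else
    data.frame(cell_label = integer(0), compartment = character(0),
               subtype = character(0), T_true = numeric(0),
               D_true = numeric(0), centroid_x = numeric(0),
               centroid_y = numeric(0), stringsAsFactors = FALSE)
  structure(list(specimen_id = spec$specimen_id,
                 tissue_class = spec$tissue_class,
                 cy3 = cy3_r$img, dapi = dapi_r$img, labels = labels,
                 truth = truth_df, log = run_log),
            class = "qfish_specimen")
}

#' Simulate a cohort of specimens and write it to disk
#'
#' Derives a recorded sub-seed for each specimen from one master seed, writes
#' per-specimen TIFFs (`<id>_cy3.tif`, `<id>_dapi.tif`, `<id>_labels.tif`),
#' a combined `truth.csv` and a `manifest.json` listing every file and seed.
#'
#' @param groups list of groups, each a list with elements `tissue_class`,
#'   `template` (a [specimen_spec()], e.g. from [specimen_template()]) and
#'   `n_specimens` (>= 1).
#' @param master_seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
simulate_cohort <- function(groups, master_seed, out_dir) {
  stopifnot(is.list(groups), length(groups) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unlist(lapply(groups, function(g) {
    if (is.null(g$n_specimens) || g$n_specimens < 1)
      stop("each group needs n_specimens >= 1", call. = FALSE)
    sprintf("%s_%02d", g$tissue_class, seq_len(g$n_specimens))
  }))
  if (anyDuplicated(ids))
    stop("duplicate specimen_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  specimens <- list()
  truth_all <- list()
  k <- 0L
  for (g in groups) {
    stopifnot(inherits(g$template, "specimen_spec"))
    for (j in seq_len(g$n_specimens)) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", g$tissue_class, j)
      sub_seed <- as.integer((as.numeric(master_seed) + 104729 * k) %%
                               2147483647)
      sp <- g$template
      sp$specimen_id <- sid
      sp$tissue_class <- g$tissue_class
      sp$seed <- sub_seed
      sim <- simulate_specimen(sp)
      files <- file.path(out_dir, paste0(sid, c("_cy3.tif", "_dapi.tif",
                                                "_labels.tif")))
      write_channel_tiff(sim$cy3, files[1], sp$acquisition$bit_depth)
      write_channel_tiff(sim$dapi, files[2], sp$acquisition$bit_depth)
      write_labels_tiff(sim$labels, files[3])
      truth_all[[k]] <- cbind(specimen_id = sid, tissue_class = g$tissue_class,
                              sim$truth, stringsAsFactors = FALSE)
      specimens[[k]] <- list(specimen_id = sid, tissue_class = g$tissue_class,
                             seed = sub_seed, files = basename(files),
                             n_cells = nrow(sim$truth))
    }
  }
  truth <- do.call(rbind, truth_all)
  write_csv_file(truth, file.path(out_dir, "truth.csv"))
  manifest <- list(master_seed = master_seed,
                   n_specimens = length(specimens),
                   truth = "truth.csv", specimens = specimens)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
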