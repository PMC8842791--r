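# Brute-force grayscale opening oracle: per-pixel double loop, independent
# of the shift-based implementation in the package.
brute_opening <- function(img, radius, height = 0) {
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  h <- height * sqrt(pmax(0, 1 - (offs$dy^2 + offs$dx^2) / radius^2))
  nr <- nrow(img); nc <- ncol(img)
  ero <- matrix(NA_real_, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    v <- Inf
    for (k in seq_len(nrow(offs))) {
      yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
      if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc)
        v <- min(v, img[yy, xx] - h[k])
    }
    ero[y, x] <- v
  }
  out <- matrix(NA_real_, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    v <- -Inf
    for (k in seq_len(nrow(offs))) {
      yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
      if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc)
        v <- max(v, ero[yy, xx] + h[k])
    }
    out[y, x] <- v
  }
  out
}

# Compact synthetic specimens for fast tests
small_acq <- function(...) acquisition_spec(width = 128L, height = 128L, ...)

small_template <- function(tissue_class, ratio = 1, seed = 1L, ...) {
  specimen_template(tissue_class, epithelial_stromal_ratio = ratio,
                    n_epithelial = 10L, n_stromal = 10L,
                    acquisition = small_acq(), seed = seed, ...)
}

# Noise-free, blur-free acquisition for exact-recovery checks
clean_acq <- function(...) {
  acquisition_spec(psf_sigma = 0, background_offset = 0,
                   background_gradient = 0, read_noise_sd = 0,
                   shot_noise = FALSE, ...)
}

# Cell-table builder for metric tests
cell_table <- function(tfi, compartment, image_id = "img1",
                       specimen_id = "s1", subtype = "unknown",
                       tissue_class = "x") {
  data.frame(specimen_id = specimen_id, tissue_class = tissue_class,
             image_id = image_id,
             cell_label = seq_along(tfi), compartment = compartment,
             subtype = subtype, tfi = tfi, stringsAsFactors = FALSE)
}
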