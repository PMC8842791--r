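# Raster convention used throughout: a channel image is a plain numeric
# matrix m[y, x] in arbitrary intensity units (AU); origin top-left,
# x rightward along columns, y downward along rows, pixel centers at
# integer coordinates. Label masks are integer matrices, 0 = background.

clamp_index <- function(i, n) pmin(pmax(i, 1L), n)

# out[y, x] = mat[y + dy, x + dx] where in range, `pad` elsewhere
shift_pad <- function(mat, dy, dx, pad) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(pad, nr, nc)
  y0 <- max(1L, 1L - dy); y1 <- min(nr, nr - dy)
  x0 <- max(1L, 1L - dx); x1 <- min(nc, nc - dx)
  if (y0 <= y1 && x0 <= x1)
    out[y0:y1, x0:x1] <- mat[(y0 + dy):(y1 + dy), (x0 + dx):(x1 + dx)]
  out
}

check_image <- function(img, what = "image") {
  if (!is.matrix(img) || length(img) == 0)
    stop(what, " must be a non-empty numeric matrix", call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(img)
}

#' Separable Gaussian blur
#'
#' Convolves an image with an isotropic Gaussian kernel (truncated at three
#' standard deviations), replicating edge pixels so that a flat field is
#' preserved exactly.
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels; `sigma <= 0` returns the
#'   input unchanged.
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  check_image(img)
  if (sigma <= 0) return(img)
  k <- as.integer(ceiling(3 * sigma))
  off <- (-k):k
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc)
  for (i in seq_along(off))
    tmp <- tmp + w[i] * img[clamp_index(seq_len(nr) + off[i], nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(off))
    out <- out + w[i] * tmp[, clamp_index(seq_len(nc) + off[i], nc), drop = FALSE]
  out
}

# Disc structuring element: offsets within a disc of the given radius, with
# an optional sphere-cap height profile (height = 0 gives the flat disc).
ball_element <- function(radius, height = 0) {
  r <- as.integer(floor(radius))
  g <- expand.grid(dy = (-r):r, dx = (-r):r)
  d2 <- g$dy^2 + g$dx^2
  keep <- d2 <= radius^2
  list(dy = g$dy[keep], dx = g$dx[keep],
       h = height * sqrt(pmax(0, 1 - d2[keep] / radius^2)))
}

erode_gray <- function(img, se) {
  out <- matrix(Inf, nrow(img), ncol(img))
  for (i in seq_along(se$dy))
    out <- pmin(out, shift_pad(img, se$dy[i], se$dx[i], Inf) - se$h[i])
  out
}

dilate_gray <- function(img, se) {
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (i in seq_along(se$dy))
    out <- pmax(out, shift_pad(img, se$dy[i], se$dx[i], -Inf) + se$h[i])
  out
}

# Grayscale opening (erosion then dilation with the reflected element; the
# ball is symmetric). Anti-extensive: opening(img) <= img everywhere.
opening_gray <- function(img, se) dilate_gray(erode_gray(img, se), se)

#' Otsu threshold
#'
#' Histogram-based threshold maximizing between-class variance. Returns a
#' single intensity value; pixels strictly above it are foreground. An
#' all-equal image yields `Inf` (empty foreground), not an error.
#'
#' @param img numeric matrix.
#' @param n_bins number of histogram bins.
#' @return threshold intensity (AU).
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  check_image(img)
  rng <- range(img)
  if (diff(rng) == 0) return(Inf)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(img, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sb2 <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)
  breaks[k + 1L]
}

neighbor_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  off <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    off <- c(off, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  off
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation; components are numbered 1..n in order
#' of their smallest column-major pixel index.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask != 0
  off <- neighbor_offsets(connectivity)
  n_fg <- sum(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (n_fg == 0) return(out)
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(n_fg)
  repeat {
    new <- lab
    for (o in off)
      new <- pmin(new, shift_pad(lab, o[1], o[2], Inf))
    new[!mask] <- Inf
    if (all(new[mask] == lab[mask])) break
    lab <- new
  }
  ids <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], ids)
  out
}

# Binary dilation of a mask by a disc of the given radius (in pixels).
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask != 0)
  se <- ball_element(radius, height = 0)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  m <- mask != 0
  for (i in seq_along(se$dy))
    out <- out | shift_pad(m, se$dy[i], se$dx[i], FALSE)
  out
}

# Label-preserving growth: expands every labeled component outward by
# `radius` pixels, each newly claimed pixel taking the label of the nearest
# existing component (ties to the lower label); components never merge.
grow_labels <- function(lab, radius) {
  if (radius <= 0) return(lab)
  off <- neighbor_offsets(8L)
  for (step in seq_len(as.integer(ceiling(radius)))) {
    cand <- matrix(Inf, nrow(lab), ncol(lab))
    for (o in off) {
      s <- shift_pad(lab, o[1], o[2], 0L)
      s[s == 0L] <- .Machine$integer.max
      cand <- pmin(cand, s)
    }
    new_px <- lab == 0L & is.finite(cand) & cand < .Machine$integer.max
    lab[new_px] <- as.integer(cand[new_px])
  }
  lab
}
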