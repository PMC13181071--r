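#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization is controlled by a clip
#' limit (maximum contrast amplification), a tile grid (spatial scale of local
#' enhancement) and the histogram bin count. The clip limit is expressed
#' relative to the mean bin height of a tile: the effective per-bin cap is
#' `max(1, clip_limit * tile_area / n_bins)`, which makes the number
#' independent of tile size (a uniform tile histogram has mean bin height
#' `tile_area / n_bins`).
#'
#' @param clip_limit positive contrast cap, default 2.0.
#' @param tile_grid integer length-2 `(rows, cols)`, default `c(8, 8)`.
#' @param n_bins histogram bins over the 8-bit range, default 256.
#' @return an object of class `clahe_params`.
#' @export
clahe_params <- function(clip_limit = 2.0, tile_grid = c(8, 8), n_bins = 256) {
  if (!is_scalar_number(clip_limit) || clip_limit <= 0) {
    drf_stop("`clip_limit` must be positive")
  }
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(is.na(tile_grid)) || any(tile_grid < 1L)) {
    drf_stop("`tile_grid` must be two positive integers (rows, cols)")
  }
  if (!is_scalar_number(n_bins) || n_bins < 1 || n_bins != round(n_bins)) {
    drf_stop("`n_bins` must be a positive integer")
  }
  structure(list(clip_limit = clip_limit, tile_grid = tile_grid,
                 n_bins = as.integer(n_bins)),
            class = "clahe_params")
}

assert_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    drf_stop("expected a grayscale image as a numeric H x W matrix")
  }
  if (anyNA(img) || any(img < 0) || any(img > 255) || any(img != round(img))) {
    drf_stop("pixel values must be integers in [0, 255]")
  }
  invisible(img)
}

assert_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    drf_stop("expected an RGB image as a numeric H x W x 3 array")
  }
  if (anyNA(img) || any(img < 0) || any(img > 255) || any(img != round(img))) {
    drf_stop("pixel values must be integers in [0, 255]")
  }
  invisible(img)
}

#' Clip a histogram and redistribute the excess
#'
#' Bins above `limit` are truncated to `limit`; the total truncated excess is
#' spread uniformly over all bins in a single pass, so total mass is conserved
#' exactly. (After redistribution bins may marginally exceed the limit; the
#' one-pass rule is deterministic and standard practice.)
#'
#' @param hist nonnegative numeric vector of bin counts.
#' @param limit positive clip level.
#' @return clipped histogram, same length and total mass as `hist`.
#' @examples
#' clip_histogram(c(10, 0, 0, 0), 4)  # 5.5 1.5 1.5 1.5
#' @export
clip_histogram <- function(hist, limit) {
  h <- as.numeric(hist)
  if (length(h) < 1L || anyNA(h) || any(h < 0)) {
    drf_stop("`hist` must be a nonnegative numeric vector")
  }
  if (!is_scalar_number(limit) || limit <= 0) drf_stop("`limit` must be positive")
  excess <- sum(pmax(h - limit, 0))
  pmin(h, limit) + excess / length(h)
}

#' Equalization lookup table from a (clipped) histogram
#'
#' Builds the 256-level mapping `LUT(v) = round(255 * CDF(v))` from the
#' normalized cumulative histogram. The LUT is non-decreasing and maps the
#' last occupied bin to 255.
#'
#' @param hist nonnegative bin counts over the 8-bit range (any number of
#'   bins; bin `b` covers intensities `[(b-1)*256/n_bins, b*256/n_bins)`).
#' @return integer vector of length 256: output level for each input value
#'   0..255 (index `v + 1`).
#' @export
equalize_map <- function(hist) {
  h <- as.numeric(hist)
  if (length(h) < 1L || anyNA(h) || any(h < 0)) {
    drf_stop("`hist` must be a nonnegative numeric vector")
  }
  total <- sum(h)
  if (total <= 0) drf_stop("cannot equalize a zero-mass histogram")
  cdf <- cumsum(h) / total
  bin_of <- pmin(floor((0:255) * length(h) / 256), length(h) - 1) + 1
  as.integer(round(255 * cdf[bin_of]))
}

# Map 8-bit values to histogram bins (1-based).
value_bins <- function(values, n_bins) {
  pmin(floor(values * n_bins / 256), n_bins - 1) + 1L
}

#' Contrast-limited adaptive histogram equalization (grayscale)
#'
#' The image is divided into a grid of tiles (edge-replicated padding brings
#' each dimension to a multiple of the tile size; the result is cropped back).
#' Each tile's histogram is clipped at the effective limit
#' `max(1, clip_limit * tile_area / n_bins)` and equalized into a lookup
#' table. Every output pixel is the bilinear blend of the LUT outputs of the
#' four nearest tile centers (clamped at borders and corners), which removes
#' visible tile seams.
#'
#' @param img grayscale image: numeric `H x W` matrix of integers in
#'   `[0, 255]`.
#' @param params a [clahe_params()].
#' @return enhanced image, same dimensions, integer values in `[0, 255]`.
#' @export
clahe_gray <- function(img, params = clahe_params()) {
  if (is.array(img) && length(dim(img)) == 3L) {
    drf_stop("clahe_gray() expects a grayscale matrix; use clahe_color() for RGB")
  }
  assert_gray(img)
  if (!inherits(params, "clahe_params")) drf_stop("expected `clahe_params`")
  H <- nrow(img); W <- ncol(img)
  tr <- params$tile_grid[1]; tc <- params$tile_grid[2]
  th <- ceiling(H / tr); tw <- ceiling(W / tc)
  Hp <- th * tr; Wp <- tw * tc
  # pad by edge replication
  pad <- img[clamp(seq_len(Hp), 1, H), clamp(seq_len(Wp), 1, W), drop = FALSE]

  n_bins <- params$n_bins
  clip_eff <- max(1, params$clip_limit * th * tw / n_bins)
  # one 256-entry LUT per tile, stored as rows of an (tr*tc) x 256 matrix
  luts <- matrix(0L, nrow = tr * tc, ncol = 256)
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- pad[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw)]
      h <- tabulate(value_bins(tile, n_bins), nbins = n_bins)
      luts[(i - 1) * tc + j, ] <- equalize_map(clip_histogram(h, clip_eff))
    }
  }

  # bilinear blend between the four nearest tile centers; tile i's center sits
  # at (i - 0.5) * tile_size in 0-based pixel-center coordinates
  axis_blend <- function(np, tsize, ntiles) {
    t <- (seq_len(np) - 0.5) / tsize + 0.5  # fractional 1-based tile index
    i0 <- clamp(floor(t), 1, ntiles)
    i1 <- clamp(i0 + 1, 1, ntiles)
    w <- clamp(t - floor(t), 0, 1)
    w[t < 1] <- 0   # clamp beyond first/last center
    w[t > ntiles] <- 0
    list(i0 = as.integer(i0), i1 = as.integer(i1), w = w)
  }
  by <- axis_blend(Hp, th, tr)
  bx <- axis_blend(Wp, tw, tc)

  v1 <- as.vector(pad) + 1L                      # LUT column index per pixel
  cell <- function(iy, ix) (rep(iy, times = Wp) - 1L) * tc + rep(ix, each = Hp)
  wy <- rep(by$w, times = Wp)
  wx <- rep(bx$w, each = Hp)
  out <- (1 - wy) * (1 - wx) * luts[cbind(cell(by$i0, bx$i0), v1)] +
         (1 - wy) * wx       * luts[cbind(cell(by$i0, bx$i1), v1)] +
         wy       * (1 - wx) * luts[cbind(cell(by$i1, bx$i0), v1)] +
         wy       * wx       * luts[cbind(cell(by$i1, bx$i1), v1)]
  out <- matrix(round(out), nrow = Hp, ncol = Wp)
  out[seq_len(H), seq_len(W), drop = FALSE]
}

#' CLAHE on the luminance channel of an RGB image
#'
#' Computes the BT.601 luma `Y = 0.299 R + 0.587 G + 0.114 B`, enhances it
#' with [clahe_gray()], and adds the luma change back to each channel so the
#' chroma planes (channel differences against luma) are untouched; the result
#' is clipped to `[0, 255]`. Grayscale content stored as RGB therefore matches
#' [clahe_gray()] on the single channel.
#'
#' @param img RGB image: numeric `H x W x 3` array of integers in `[0, 255]`.
#' @param params a [clahe_params()].
#' @return enhanced RGB image, same dimensions.
#' @export
clahe_color <- function(img, params = clahe_params()) {
  if (is.matrix(img)) {
    drf_stop("clahe_color() expects an RGB array; use clahe_gray() for grayscale")
  }
  assert_rgb(img)
  y <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  y_enh <- clahe_gray(y, params)
  delta <- y_enh - y
  out <- img
  for (ch in 1:3) out[, , ch] <- clamp(round(img[, , ch] + delta), 0, 255)
  out
}

#' Bilinear image resize
#'
#' Resamples with the half-pixel-center convention
#' `src = (dst + 0.5) * scale - 0.5` (clamped at borders), so an identity-size
#' resize returns the input unchanged.
#'
#' @param img grayscale matrix or RGB array with integer values in
#'   `[0, 255]`.
#' @param height,width positive target dimensions.
#' @return resized image of the requested dimensions.
#' @export
resize_bilinear <- function(img, height, width) {
  if (!is_scalar_number(height) || !is_scalar_number(width) ||
      height < 1 || width < 1) {
    drf_stop("target `height` and `width` must be positive")
  }
  height <- as.integer(height); width <- as.integer(width)
  if (length(dim(img)) == 3L) {
    assert_rgb(img)
    out <- array(0, dim = c(height, width, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) {
      out[, , ch] <- resize_plane(img[, , ch], height, width)
    }
    return(out)
  }
  assert_gray(img)
  resize_plane(img, height, width)
}

resize_plane <- function(plane, height, width) {
  H <- nrow(plane); W <- ncol(plane)
  axis_map <- function(nd, ns) {
    src <- (seq_len(nd) - 0.5) * ns / nd - 0.5   # 0-based source coordinate
    i0 <- clamp(floor(src), 0, ns - 1)
    i1 <- clamp(i0 + 1, 0, ns - 1)
    list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L,
         w = clamp(src - i0, 0, 1))
  }
  ay <- axis_map(height, H)
  ax <- axis_map(width, W)
  wy <- matrix(ay$w, height, width)
  wx <- matrix(ax$w, height, width, byrow = TRUE)
  p <- function(iy, ix) plane[iy, ix, drop = FALSE]
  out <- (1 - wy) * (1 - wx) * p(ay$i0, ax$i0) +
         (1 - wy) * wx       * p(ay$i0, ax$i1) +
         wy       * (1 - wx) * p(ay$i1, ax$i0) +
         wy       * wx       * p(ay$i1, ax$i1)
  matrix(as.integer(round(out)), height, width)
}

#' Read an 8-bit PNG as an integer image
#' @param path PNG file.
#' @return grayscale matrix or RGB array of integers in `[0, 255]` (an alpha
#'   channel, if present, is dropped).
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) drf_stop(sprintf("image not found: %s", path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) {
    x <- x[, , 1:3, drop = FALSE]
  } else if (length(dim(x)) == 3L) {
    x <- x[, , 1]
  }
  y <- round(x * 255)
  if (length(dim(x)) == 3L) array(y, dim(x)) else matrix(y, nrow(x), ncol(x))
}

#' Write an integer image to PNG
#' @param img grayscale matrix or RGB array of integers in `[0, 255]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (length(dim(img)) == 3L) assert_rgb(img) else assert_gray(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
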