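#' Colour quantization by median cut
#'
#' Reduces an RGB image (or a pooled set of images) to at most `n_colors`
#' distinct colours. Boxes of the RGB histogram are split recursively along
#' their widest channel at the pixel-weighted median; each pixel is then
#' assigned the palette entry nearest in Euclidean RGB distance. The
#' procedure is deterministic: ties are broken by lexicographic RGB order,
#' so no seed is involved.
#'
#' @param image integer `h x w x 3` array with values in `[0, 255]`.
#' @param n_colors palette budget (`>= 1`), default 128.
#' @param palette optional fixed `k x 3` palette; when supplied the median
#'   cut is skipped and pixels are assigned to this palette (used to share
#'   one palette across an image set).
#' @return an object of class `quantized_image`: list with `image` (RGB
#'   array), `index` (`h x w` matrix of palette row indices) and `palette`
#'   (`k x 3` integer matrix).
#' @seealso [quantize_image_set()] for a shared palette across images.
#' @export
quantize_colors <- function(image, n_colors = 128, palette = NULL) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L) {
    stopf("'image' must be a non-empty h x w x 3 array")
  }
  if (is.null(palette)) {
    if (!is.numeric(n_colors) || n_colors < 1) stopf("'n_colors' must be >= 1")
    palette <- median_cut_palette(list(image), n_colors)
  }
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  idx <- nearest_palette_index(px, palette)
  out <- array(0L, d)
  for (ch in 1:3) out[, , ch] <- matrix(palette[idx, ch], d[1], d[2])
  structure(list(image = out,
                 index = matrix(idx, d[1], d[2]),
                 palette = palette),
            class = "quantized_image")
}

#' Quantize an image set against one shared palette
#'
#' Pools the pixels of all images, builds a single median-cut palette, and
#' quantizes every image against it so that colour-frequency columns align
#' across images.
#'
#' @param images list of `h x w x 3` arrays.
#' @param n_colors shared palette budget.
#' @return list of [quantize_colors()] results sharing one `palette`.
#' @export
quantize_image_set <- function(images, n_colors = 128) {
  if (!length(images)) stopf("'images' must be a non-empty list")
  pal <- median_cut_palette(images, n_colors)
  lapply(images, quantize_colors, palette = pal)
}

# Median-cut palette over the pooled unique colours of a list of images.
median_cut_palette <- function(images, n_colors) {
  px <- do.call(rbind, lapply(images, function(im) {
    cbind(as.vector(im[, , 1]), as.vector(im[, , 2]), as.vector(im[, , 3]))
  }))
  key <- px[, 1] * 65536 + px[, 2] * 256 + px[, 3]
  tab <- table(key)
  keys <- as.numeric(names(tab))
  cols <- cbind(keys %/% 65536, (keys %/% 256) %% 256, keys %% 256)
  wts <- as.numeric(tab)
  ord <- order(cols[, 1], cols[, 2], cols[, 3])  # lexicographic, deterministic
  cols <- cols[ord, , drop = FALSE]; wts <- wts[ord]
  boxes <- list(seq_len(nrow(cols)))
  repeat {
    if (length(boxes) >= n_colors) break
    # candidate: box with the widest channel range; ties -> heavier box,
    # then lower index
    ranges <- vapply(boxes, function(b) {
      if (length(b) < 2L) return(-1)
      max(apply(cols[b, , drop = FALSE], 2, function(v) max(v) - min(v)))
    }, numeric(1))
    if (all(ranges <= 0)) break
    weight <- vapply(boxes, function(b) sum(wts[b]), numeric(1))
    pick <- order(-ranges, -weight)[1]
    b <- boxes[[pick]]
    sub <- cols[b, , drop = FALSE]
    ch <- which.max(apply(sub, 2, function(v) max(v) - min(v)))
    o <- order(sub[, ch], sub[, 1], sub[, 2], sub[, 3])
    b <- b[o]
    csum <- cumsum(wts[b])
    half <- csum[length(csum)] / 2
    cut <- which(csum >= half)[1]
    if (cut >= length(b)) cut <- length(b) - 1L
    boxes[[pick]] <- b[seq_len(cut)]
    boxes[[length(boxes) + 1L]] <- b[(cut + 1L):length(b)]
  }
  pal <- t(vapply(boxes, function(b) {
    if (length(b) == 1L) as.numeric(cols[b, ]) else
      round(colSums(cols[b, , drop = FALSE] * wts[b]) / sum(wts[b]))
  }, numeric(3)))
  pal <- unique(pal)
  pal <- pal[order(pal[, 1], pal[, 2], pal[, 3]), , drop = FALSE]
  storage.mode(pal) <- "integer"
  colnames(pal) <- c("R", "G", "B")
  pal
}

# Nearest palette row per pixel row; ties resolved toward the lower palette
# index (palette is lexicographically sorted, so ties go to the smaller RGB).
nearest_palette_index <- function(px, palette) {
  d2 <- outer(rowSums(px^2), rep(1, nrow(palette))) -
    2 * px %*% t(palette) +
    outer(rep(1, nrow(px)), rowSums(palette^2))
  max.col(-d2, ties.method = "first")
}

#' Colour-frequency matrix with background filtering
#'
#' Counts pixels per palette colour for each quantized image (rows = images,
#' columns = palette colours), then removes the columns whose colour lies
#' within `tolerance` RGB units (Euclidean) of any background-palette
#' colour — trays, walls, labels and other non-plant scene elements. After
#' filtering, row sums equal plant-pixel counts.
#'
#' @param qimages list of [quantize_colors()] results sharing one palette
#'   (e.g. from [quantize_image_set()]); names are used as image labels.
#' @param background_palette `k x 3` matrix of background RGB triples (or
#'   `NULL` for no filtering).
#' @param tolerance RGB distance below which a palette colour counts as
#'   background (default 10).
#' @return an object of class `colour_freq`: a counts matrix whose columns
#'   are named `"R_G_B"`, with attributes `palette` (kept colours),
#'   `removed` (per-image pixel count filtered out) and `total`
#'   (per-image total pixels).
#' @export
frequency_matrix <- function(qimages, background_palette = NULL,
                             tolerance = 10) {
  if (!length(qimages)) stopf("'qimages' must be non-empty")
  if (!all(vapply(qimages, inherits, logical(1), "quantized_image"))) {
    stopf("'qimages' must be quantized images (see quantize_colors)")
  }
  pal <- qimages[[1]]$palette
  same <- vapply(qimages, function(q) identical(q$palette, pal), logical(1))
  if (!all(same)) stopf("images were quantized with different palettes")
  k <- nrow(pal)
  counts <- t(vapply(qimages, function(q) tabulate(q$index, nbins = k),
                     numeric(k)))
  rownames(counts) <- names(qimages) %||% sprintf("img%02d", seq_along(qimages))
  colnames(counts) <- apply(pal, 1, paste, collapse = "_")
  total <- rowSums(counts)
  keep <- rep(TRUE, k)
  if (!is.null(background_palette) && nrow(background_palette) > 0) {
    bgd <- vapply(seq_len(k), function(j) {
      min(sqrt(colSums((t(background_palette) - pal[j, ])^2)))
    }, numeric(1))
    keep <- bgd > tolerance
  }
  out <- counts[, keep, drop = FALSE]
  structure(out,
            palette = pal[keep, , drop = FALSE],
            removed = total - rowSums(out),
            total = total,
            class = c("colour_freq", "matrix"))
}

#' Green/yellow senescence trajectory from a colour-frequency matrix
#'
#' Classifies each (background-filtered) palette colour by its HSV hue into
#' green, yellow or other, and computes per-image fractions of plant pixels
#' in each class. Yellow area rising at the expense of green is the digital
#' signature of senescence.
#'
#' @param freq a [frequency_matrix()] result.
#' @param green_hue,yellow_hue half-open hue intervals `[lo, hi)` in degrees;
#'   defaults green `[70, 160)`, yellow `[40, 70)`. Must be disjoint.
#' @return data frame with columns `time` (1-based image index), `image`,
#'   `green_fraction`, `yellow_fraction`.
#' @export
senescence_trajectory <- function(freq, green_hue = c(70, 160),
                                  yellow_hue = c(40, 70)) {
  if (!inherits(freq, "colour_freq")) stopf("'freq' must come from frequency_matrix()")
  if (max(green_hue[1], yellow_hue[1]) < min(green_hue[2], yellow_hue[2])) {
    stopf("green and yellow hue intervals must be disjoint")
  }
  pal <- attr(freq, "palette")
  hue <- if (nrow(pal)) {
    grDevices::rgb2hsv(t(pal), maxColorValue = 255)[1, ] * 360
  } else numeric(0)
  in_iv <- function(h, iv) h >= iv[1] & h < iv[2]
  g_cols <- in_iv(hue, green_hue)
  y_cols <- in_iv(hue, yellow_hue)
  m <- unclass(freq)
  tot <- rowSums(m)
  tot[tot == 0] <- NA_real_
  data.frame(time = seq_len(nrow(m)),
             image = rownames(m),
             green_fraction = rowSums(m[, g_cols, drop = FALSE]) / tot,
             yellow_fraction = rowSums(m[, y_cols, drop = FALSE]) / tot,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a colour-frequency matrix as TSV
#'
#' First column `image`, remaining columns `R_G_B` palette headers.
#'
#' @param freq a [frequency_matrix()] result.
#' @param path file path.
#' @export
write_frequency_tsv <- function(freq, path) {
  df <- data.frame(image = rownames(freq), unclass(freq), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
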