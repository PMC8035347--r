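#' Gaussian noise-reduction filter
#'
#' Convolves a 2D intensity image with a normalized, separable Gaussian
#' kernel `exp(-(x - mu)^2 / (2 sigma^2))` (mu = 0 for filtering; sigma is
#' the standard deviation in pixels). Boundaries are handled by reflection.
#' `sigma = 0` is the identity.
#'
#' @param src numeric matrix.
#' @param sigma kernel standard deviation in pixels (>= 0).
#' @param truncation kernel half-width in units of sigma.
#' @return Filtered matrix, same dimensions as `src`.
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 1
#' f <- gaussian_filter(img, sigma = 1)
#' sum(f)  # unit-sum kernel preserves total intensity away from borders
#' @export
gaussian_filter <- function(src, sigma, truncation = 3) {
  stopifnot(is.matrix(src))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(src)
  k <- gaussian_kernel_1d(sigma, truncation)
  conv_sep(src, k)
}

gaussian_kernel_1d <- function(sigma, truncation = 3) {
  hw <- max(1L, as.integer(ceiling(truncation * sigma)))
  x <- (-hw):hw
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with reflected (edge-duplicating) boundaries
conv_sep <- function(src, k) {
  hw <- (length(k) - 1L) %/% 2L
  src <- conv_axis(src, k, hw)            # along rows (vertical)
  t(conv_axis(t(src), k, hw))             # along columns
}

conv_axis <- function(src, k, hw) {
  n <- nrow(src)
  idx <- reflect_idx(n, hw)
  pad <- src[idx, , drop = FALSE]
  acc <- matrix(0, n, ncol(src))
  for (t in seq_along(k)) {
    acc <- acc + k[t] * pad[t:(t + n - 1L), , drop = FALSE]
  }
  acc
}

reflect_idx <- function(n, hw) {
  i <- (1L - hw):(n + hw)
  # fold until inside [1, n]; handles hw > n
  repeat {
    below <- i < 1L
    above <- i > n
    if (!any(below) && !any(above)) break
    i[below] <- 1L - i[below]
    i[above] <- 2L * n + 1L - i[above]
  }
  i
}

#' Structuring element for morphological filtering
#'
#' @param shape `"disk"` (pixels with `x^2 + y^2 <= r^2`) or `"square"`.
#' @param radius element radius in pixels (>= 1); the element is a
#'   `(2 radius + 1)` square logical matrix, symmetric about its centre.
#' @return Logical matrix of class `struct_elem`.
#' @export
structuring_element <- function(shape = c("disk", "square"), radius = 2) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  d <- 2L * radius + 1L
  el <- if (shape == "square") {
    matrix(TRUE, d, d)
  } else {
    x <- matrix(rep(-radius:radius, d), d, d)
    x^2 + t(x)^2 <= radius^2
  }
  structure(el, class = c("struct_elem", class(el)),
            shape = shape, radius = radius)
}

# grayscale erosion/dilation by min/max over the element's offsets;
# positions outside the image are ignored (padded with +/- Inf)
morph_minmax <- function(src, element, op = c("erode", "dilate")) {
  op <- match.arg(op)
  stopifnot(is.matrix(src), is.matrix(element))
  r <- (dim(element) - 1L) %/% 2L
  pad_val <- if (op == "erode") Inf else -Inf
  h <- nrow(src); w <- ncol(src)
  pad <- matrix(pad_val, h + 2L * r[1], w + 2L * r[2])
  pad[(r[1] + 1L):(r[1] + h), (r[2] + 1L):(r[2] + w)] <- src
  off <- which(element, arr.ind = TRUE)
  out <- matrix(pad_val, h, w)
  cmp <- if (op == "erode") pmin else pmax
  for (i in seq_len(nrow(off))) {
    di <- off[i, 1]; dj <- off[i, 2]
    out <- cmp(out, pad[di:(di + h - 1L), dj:(dj + w - 1L)])
  }
  out
}

#' Morphological erosion and dilation
#'
#' Grayscale (min/max) morphology; on 0/1 images this reduces to the usual
#' binary set operations. Pixels outside the image are ignored.
#'
#' @param src numeric (or logical) matrix.
#' @param element a [structuring_element()] or logical matrix of odd
#'   dimensions.
#' @return Numeric matrix of the same size.
#' @export
morph_erode <- function(src, element) {
  morph_minmax(to_num(src), element, "erode")
}

#' @rdname morph_erode
#' @export
morph_dilate <- function(src, element) {
  morph_minmax(to_num(src), element, "dilate")
}

#' Morphological opening: `dilate(erode(src, element), element)`
#'
#' Removes foreground objects smaller than the element; anti-extensive and
#' idempotent.
#'
#' @inheritParams morph_erode
#' @return Numeric matrix of the same size.
#' @examples
#' img <- matrix(0, 7, 7); img[4, 4] <- 1   # isolated pixel
#' all(morph_open(img, structuring_element("square", 1)) == 0)
#' @export
morph_open <- function(src, element) {
  morph_dilate(morph_erode(src, element), element)
}

#' Morphological closing: `erode(dilate(src, element), element)`
#'
#' Fills holes smaller than the element; extensive and idempotent.
#'
#' @inheritParams morph_erode
#' @return Numeric matrix of the same size.
#' @export
morph_close <- function(src, element) {
  morph_erode(morph_dilate(src, element), element)
}

to_num <- function(x) {
  if (is.logical(x)) {
    y <- matrix(as.numeric(x), nrow(x), ncol(x))
    y
  } else x
}

#' Preprocess a z-stack for segmentation and spot detection
#'
#' Applies, per layer, Gaussian filtering followed by morphological opening
#' and closing to the DAPI channel (the segmentation input) and Gaussian
#' filtering only to the FITC and TRITC channels: sub-resolution gene
#' signals (about 0.6 um, i.e. a few pixels) would be erased by morphology.
#'
#' @param stack a [zstack()].
#' @param config a [fish_config()].
#' @return Named list with elements `DAPI`, `FITC`, `TRITC`, each a list of
#'   per-layer matrices.
#' @export
preprocess_stack <- function(stack, config = fish_config()) {
  stopifnot(inherits(stack, "zstack"))
  validate_config(config)
  el <- structuring_element(config$morphology_shape, config$morphology_radius)
  sig <- config$gaussian_sigma
  tr <- config$gaussian_truncation
  out <- list()
  for (ch in c("DAPI", "FITC", "TRITC")) {
    layers <- channel_layers(stack, ch)
    out[[ch]] <- lapply(layers, function(m) {
      m <- gaussian_filter(m, sig, tr)
      if (ch == "DAPI") m <- morph_close(morph_open(m, el), el)
      m
    })
  }
  out
}
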