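#' Template matching scores
#'
#' Slides a template `T` (h x w) over a source image `I` (H x W) and returns
#' the score matrix `R` of size `(H - h + 1) x (W - w + 1)`; `R[y, x]` is the
#' score of the window whose top-left pixel is `(y, x)`. Six scores are
#' available:
#' \describe{
#'   \item{SD}{square difference, `sum (T - I)^2` (0 = perfect match)}
#'   \item{NSD}{SD normalized by `sqrt(sum T^2 * sum I^2)`}
#'   \item{C}{cross correlation, `sum T * I`}
#'   \item{NC}{C normalized by `sqrt(sum T^2 * sum I^2)` (1 = perfect, for
#'     non-negative inputs)}
#'   \item{CC}{correlation coefficient, `sum T' * I'` where `T'` and `I'`
#'     subtract the template/window mean}
#'   \item{NcC}{CC normalized by `sqrt(sum T'^2 * sum I'^2)`, i.e. Pearson
#'     correlation of template and window, in `[-1, 1]`}
#' }
#' Windows (or templates) with vanishing energy in a normalized score are
#' assigned the method's worst value (`Inf` for NSD, 0 for NC, -1 for NcC).
#'
#' Scores are evaluated by FFT cross-correlation, which agrees with direct
#' summation to floating-point round-off.
#'
#' @param I numeric source matrix (H x W).
#' @param T numeric template matrix (h x w), no larger than `I`.
#' @param method one of `"SD"`, `"NSD"`, `"C"`, `"NC"`, `"CC"`, `"NcC"`.
#' @return Numeric score matrix with attributes `method` and `template_dim`.
#' @examples
#' I <- matrix(1:4, 2, 2, byrow = TRUE)
#' match_template(I, I, "SD")    # 0: exact match
#' match_template(I, I, "NC")    # 1
#' @export
match_template <- function(I, T, method = c("NcC", "SD", "NSD", "C", "NC", "CC")) {
  method <- match.arg(method)
  stopifnot(is.matrix(I), is.matrix(T))
  if (nrow(T) > nrow(I) || ncol(T) > ncol(I)) {
    stop("template must not be larger than the image")
  }
  plan <- xcorr_plan(I, nrow(T), ncol(T))
  R <- score_from_plan(plan, T, method)
  attr(R, "method") <- method
  attr(R, "template_dim") <- dim(T)
  class(R) <- c("match_result", class(R))
  R
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> method %s, %d x %d scores\n",
              attr(x, "method"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

# precompute the image-side transforms shared by all templates of one size
xcorr_plan <- function(I, h, w) {
  H <- nrow(I); W <- ncol(I)
  N1 <- stats::nextn(H); N2 <- stats::nextn(W)
  FI <- stats::fft(pad_to(I, N1, N2))
  FI2 <- stats::fft(pad_to(I * I, N1, N2))
  Fones <- stats::fft(pad_to(matrix(1, h, w), N1, N2))
  vh <- H - h + 1L; vw <- W - w + 1L
  S1 <- xcorr_valid(FI, Fones, N1, N2, vh, vw)    # window sums of I
  S2 <- xcorr_valid(FI2, Fones, N1, N2, vh, vw)   # window sums of I^2
  list(FI = FI, N1 = N1, N2 = N2, h = h, w = w, vh = vh, vw = vw,
       S1 = S1, S2 = pmax(S2, 0))
}

pad_to <- function(m, N1, N2) {
  P <- matrix(0, N1, N2)
  P[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  P
}

xcorr_valid <- function(FA, FB, N1, N2, vh, vw) {
  full <- Re(stats::fft(FA * Conj(FB), inverse = TRUE)) / (N1 * N2)
  full[seq_len(vh), seq_len(vw), drop = FALSE]
}

score_from_plan <- function(plan, T, method) {
  FT <- stats::fft(pad_to(T, plan$N1, plan$N2))
  C <- xcorr_valid(plan$FI, FT, plan$N1, plan$N2, plan$vh, plan$vw)
  n <- plan$h * plan$w
  sumT <- sum(T); sumT2 <- sum(T * T)
  eps <- 1e-12
  switch(method,
    SD = sumT2 - 2 * C + plan$S2,
    NSD = {
      den <- sqrt(sumT2 * plan$S2)
      out <- (sumT2 - 2 * C + plan$S2) / den
      out[den <= eps] <- Inf
      out
    },
    C = C,
    NC = {
      den <- sqrt(sumT2 * plan$S2)
      out <- C / den
      out[den <= eps] <- 0
      out
    },
    CC = C - sumT * plan$S1 / n,
    NcC = {
      eT <- max(sumT2 - sumT^2 / n, 0)
      eI <- pmax(plan$S2 - plan$S1^2 / n, 0)
      den <- sqrt(eT * eI)
      out <- (C - sumT * plan$S1 / n) / den
      out[den <= eps] <- -1
      out
    },
    stop("unknown method: ", method))
}

# higher score = better match?
method_is_similarity <- function(method) {
  !(method %in% c("SD", "NSD"))
}

#' Parametric nucleus template bank
#'
#' Renders filled ellipses over a grid of sizes, aspect ratios and
#' orientations on a common square canvas, for use as DAPI nucleus templates.
#' Circular templates get a single orientation. User-supplied templates (in
#' `config$templates`, a list of numeric matrices) override the parametric
#' bank.
#'
#' @param config a [fish_config()]; uses `template_radii_um` (semi-major
#'   axes), `template_aspects`, `template_angle_step` and `pixel_size_xy`.
#' @return A list of class `template_set`; each element has the template
#'   image (`img`), its support, the ellipse semi-axes in pixels and its
#'   orientation.
#' @export
template_bank <- function(config = fish_config()) {
  validate_config(config)
  px <- config$pixel_size_xy
  if (!is.null(config$templates)) {
    k <- max(vapply(config$templates, function(t) max(dim(t)), 1L))
    if (k %% 2L == 0L) k <- k + 1L
    bank <- lapply(config$templates, function(t) {
      img <- embed_center(t, k)
      list(img = img, support = img > 0,
           a_px = NA_real_, b_px = NA_real_, theta = NA_real_)
    })
    return(structure(bank, class = "template_set", provenance = "user_supplied",
                     canvas = k))
  }
  a_px <- config$template_radii_um / px
  k <- 2L * as.integer(ceiling(max(a_px))) + 1L
  bank <- list()
  for (a in a_px) {
    for (asp in config$template_aspects) {
      thetas <- if (asp == 1) 0 else {
        seq(0, 180 - config$template_angle_step, by = config$template_angle_step)
      }
      for (th in thetas) {
        sup <- ellipse_mask(k, a, a / asp, th * pi / 180)
        bank[[length(bank) + 1L]] <- list(
          img = matrix(as.numeric(sup), k, k), support = sup,
          a_px = a, b_px = a / asp, theta = th * pi / 180)
      }
    }
  }
  structure(bank, class = "template_set", provenance = "parametric",
            canvas = k)
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d template(s), %s, canvas %d px\n",
              length(x), attr(x, "provenance"), attr(x, "canvas")))
  invisible(x)
}

embed_center <- function(m, k) {
  P <- matrix(0, k, k)
  r0 <- (k - nrow(m)) %/% 2L
  c0 <- (k - ncol(m)) %/% 2L
  P[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  P
}

# filled rotated ellipse, centred on a k x k canvas (a, b in pixels)
ellipse_mask <- function(k, a, b, theta) {
  c0 <- (k + 1) / 2
  x <- matrix(rep(seq_len(k) - c0, each = k), k, k)   # column offsets
  y <- matrix(rep(seq_len(k) - c0, times = k), k, k)  # row offsets
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}
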