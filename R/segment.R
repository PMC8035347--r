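#' Segment one DAPI layer by template matching
#'
#' Matches every template in the bank against the (preprocessed) DAPI layer
#' with the configured score, keeps score peaks that pass
#' `config$match_threshold` (`>=` for similarity scores, `<=` for SD/NSD),
#' applies greedy non-maximum suppression (a peak is dropped when its
#' footprint overlaps an already-accepted footprint by more than
#' `config$nms_overlap` of the smaller one), and returns the union of the
#' accepted footprints intersected with the Otsu foreground of the layer.
#'
#' The image is zero-padded by half a template canvas on each side before
#' matching, so nuclei anywhere inside the image can be matched by a centred
#' window; peak positions are reported in image coordinates (the window
#' centre).
#'
#' @param dapi preprocessed DAPI layer (numeric matrix, values in `[0, 1]`).
#' @param templates a [template_bank()].
#' @param config a [fish_config()].
#' @return Logical mask of the layer, with attribute `"peaks"` (a data frame
#'   of accepted peak positions, scores and template indices).
#' @export
segment_layer <- function(dapi, templates, config = fish_config()) {
  stopifnot(is.matrix(dapi), inherits(templates, "template_set"))
  validate_config(config)
  H <- nrow(dapi); W <- ncol(dapi)
  k <- attr(templates, "canvas")
  m <- (k - 1L) %/% 2L
  method <- config$match_method
  sim <- method_is_similarity(method)

  fg <- otsu_foreground(dapi)

  Ipad <- matrix(0, H + 2L * m, W + 2L * m)
  Ipad[(m + 1L):(m + H), (m + 1L):(m + W)] <- dapi
  plan <- xcorr_plan(Ipad, k, k)

  peaks <- list()
  for (ti in seq_along(templates)) {
    R <- score_from_plan(plan, templates[[ti]]$img, method)
    P <- if (sim) R else -R
    thr <- if (sim) config$match_threshold else -config$match_threshold
    pk <- local_maxima(P, thr)
    if (nrow(pk)) {
      peaks[[length(peaks) + 1L]] <- data.frame(
        row = pk$row, col = pk$col, score = R[cbind(pk$row, pk$col)],
        goodness = P[cbind(pk$row, pk$col)], template = ti)
    }
  }
  empty_peaks <- data.frame(row = integer(), col = integer(),
                            score = numeric(), template = integer())
  if (!length(peaks)) {
    return(structure(matrix(FALSE, H, W), peaks = empty_peaks))
  }
  peaks <- do.call(rbind, peaks)
  peaks <- peaks[order(-peaks$goodness, peaks$template, peaks$row, peaks$col), ,
                 drop = FALSE]

  claim <- matrix(0L, H, W)
  sizes <- numeric(0)
  accepted <- empty_peaks
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(peaks))) {
    idx <- footprint_idx(templates[[peaks$template[i]]], config$footprint_scale,
                         peaks$row[i], peaks$col[i], H, W)
    if (!length(idx)) next
    hit <- claim[idx]
    keep <- TRUE
    if (any(hit > 0)) {
      tab <- tabulate(hit[hit > 0], nbins = length(sizes))
      if (any(tab / pmin(length(idx), sizes) > config$nms_overlap)) keep <- FALSE
    }
    if (keep) {
      sizes <- c(sizes, length(idx))
      claim[idx] <- length(sizes)
      mask[idx] <- TRUE
      accepted <- rbind(accepted, peaks[i, c("row", "col", "score", "template")])
    }
  }
  structure(mask & fg, peaks = accepted)
}

otsu_foreground <- function(layer) {
  v <- pmin(pmax(layer, 0), 1)
  if (diff(range(v)) < 1e-6) return(matrix(FALSE, nrow(v), ncol(v)))
  thr <- EBImage::otsu(v, range = c(0, 1))
  v > thr
}

# strict-or-equal local maxima of a score surface, above a threshold
local_maxima <- function(P, thr) {
  H <- nrow(P); W <- ncol(P)
  ok <- P >= thr & is.finite(P)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- P
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (P >= pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)])
  }
  idx <- which(ok, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2])
}

# linear (column-major) pixel indices of a template's footprint placed with
# its canvas centre at image position (r, c); parametric templates use their
# ellipse scaled by `fs`, user templates their raw support
footprint_idx <- function(tmpl, fs, r, c, H, W) {
  if (is.na(tmpl$a_px)) {
    sup <- tmpl$support
    k <- nrow(sup)
  } else {
    a <- tmpl$a_px * fs
    k <- 2L * as.integer(ceiling(a)) + 1L
    sup <- ellipse_mask(k, a, tmpl$b_px * fs, tmpl$theta)
  }
  mm <- (k - 1L) %/% 2L
  off <- which(sup, arr.ind = TRUE)
  rows <- r + off[, 1] - 1L - mm
  cols <- c + off[, 2] - 1L - mm
  inside <- rows >= 1L & rows <= H & cols >= 1L & cols <= W
  (cols[inside] - 1L) * H + rows[inside]
}

#' Label connected components of a binary mask
#'
#' Maximal 8-connected foreground sets receive distinct positive integer
#' labels; components smaller than `min_size` pixels (isolated vertices in
#' the component hypergraph) are erased to background. Labels are assigned
#' in scan order of each component's first pixel (column-major, the native R
#' order).
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param min_size minimum component size in pixels.
#' @return Integer label matrix of the same size; 0 is background.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4:5, 4:5] <- TRUE
#' max(connected_components(m))  # 2
#' @export
connected_components <- function(mask, min_size = 1) {
  if (!is.logical(mask)) mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0, H, W)
  lab[mask] <- which(mask)
  if (!any(mask)) return(matrix(0L, H, W))
  repeat {
    new <- lab
    pad <- matrix(0, H + 2L, W + 2L)
    pad[2:(H + 1L), 2:(W + 1L)] <- lab
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      new <- pmax(new, pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)])
    }
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  lin <- which(lab > 0)
  provisional <- lab[lin]
  sizes <- table(provisional)
  small <- as.numeric(names(sizes)[sizes < min_size])
  if (length(small)) {
    drop <- provisional %in% small
    lab[lin[drop]] <- 0
    lin <- lin[!drop]
    provisional <- provisional[!drop]
  }
  out <- matrix(0L, H, W)
  if (length(lin)) {
    first <- tapply(lin, provisional, min)
    ord <- names(sort(first))
    relab <- stats::setNames(seq_along(ord), ord)
    out[lin] <- as.integer(relab[as.character(provisional)])
  }
  out
}

#' Link per-layer components into 3D nuclei
#'
#' Components in adjacent layers are merged into one nucleus when their
#' pixel overlap exceeds 0.5 of the smaller component. Each linked nucleus
#' is then quality-controlled: it is discarded (with a reason) when any of
#' its pixels touches the image border (`"border"`), when its projected 2D
#' footprint overlaps another nucleus (`"overlap"`), or when its volume lies
#' outside `config$nucleus_volume_um3` (`"size"`). All other nuclei are
#' `"clear"` and eligible for signal counting.
#'
#' @param labeled_layers list of integer label matrices, one per layer,
#'   sharing extents (e.g. from [connected_components()]).
#' @param config a [fish_config()].
#' @return List of `nucleus3d` objects (class `nucleus_set`). Each has per-
#'   layer masks, the 0-based layer span, per-layer pixel areas, the
#'   volume-weighted centroid in um, and QC status.
#' @export
link_3d <- function(labeled_layers, config = fish_config()) {
  validate_config(config)
  L <- length(labeled_layers)
  dims <- dim(labeled_layers[[1]])
  if (!all(vapply(labeled_layers, function(m) identical(dim(m), dims), TRUE))) {
    stop("all layers must share extents")
  }
  H <- dims[1]; W <- dims[2]

  # global node ids for (layer, label)
  nlab <- vapply(labeled_layers, max, 0L)
  offs <- cumsum(c(0L, nlab))[seq_len(L)]
  n_nodes <- sum(nlab)
  if (n_nodes == 0) return(structure(list(), class = "nucleus_set",
                                     dims = dims, n_layers = L))
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  areas <- lapply(labeled_layers, function(m) tabulate(m[m > 0]))
  for (l in seq_len(L - 1)) {
    a <- labeled_layers[[l]]; b <- labeled_layers[[l + 1]]
    sel <- a > 0 & b > 0
    if (!any(sel)) next
    la <- a[sel]; lb <- b[sel]
    key <- paste(la, lb)
    counts <- table(key)
    uk <- strsplit(names(counts), " ", fixed = TRUE)
    for (i in seq_along(counts)) {
      ia <- as.integer(uk[[i]][1]); ib <- as.integer(uk[[i]][2])
      smaller <- min(areas[[l]][ia], areas[[l + 1]][ib])
      if (counts[[i]] / smaller > 0.5) {
        union(offs[l] + ia, offs[l + 1] + ib)
      }
    }
  }
  roots <- vapply(seq_len(n_nodes), find, 1L)

  groups <- split(seq_len(n_nodes), roots)
  # deterministic ordering: by earliest layer, then first pixel in that layer
  ginfo <- lapply(groups, function(g) {
    layers <- findInterval(g - 1L, offs)
    l0 <- min(layers)
    lab0 <- min(g[layers == l0] - offs[l0])
    fp <- min(which(labeled_layers[[l0]] == lab0))
    c(l0, fp)
  })
  ord <- order(vapply(ginfo, `[`, 1, 1), vapply(ginfo, `[`, 1, 2))
  groups <- groups[ord]

  px <- config$pixel_size_xy; zi <- config$z_interval
  nuclei <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    layers <- findInterval(g - 1L, offs)
    masks <- vector("list", L)
    area_per_layer <- integer(L)
    sx <- sy <- sz <- 0; nvox <- 0
    border <- FALSE
    for (l in sort(unique(layers))) {
      labs_here <- g[layers == l] - offs[l]
      mk <- matrix(labeled_layers[[l]] %in% labs_here, H, W)
      masks[[l]] <- mk
      area_per_layer[l] <- sum(mk)
      idx <- which(mk, arr.ind = TRUE)
      sx <- sx + sum(idx[, 2] - 1); sy <- sy + sum(idx[, 1] - 1)
      sz <- sz + nrow(idx) * (l - 1)
      nvox <- nvox + nrow(idx)
      if (any(idx[, 1] %in% c(1L, H)) || any(idx[, 2] %in% c(1L, W))) {
        border <- TRUE
      }
    }
    span <- range(which(area_per_layer > 0)) - 1L  # 0-based
    nuc <- list(
      id = gi,
      masks = masks,
      layer_span = span,
      area_per_layer = area_per_layer,
      n_voxels = nvox,
      volume_um3 = nvox * px^2 * zi,
      centroid_um = c(x = sx / nvox * px, y = sy / nvox * px,
                      z = sz / nvox * zi),
      qc = "clear",
      discard_reason = NA_character_
    )
    if (border) {
      nuc$qc <- "discarded"; nuc$discard_reason <- "border"
    }
    class(nuc) <- "nucleus3d"
    nuclei[[gi]] <- nuc
  }

  # pairwise projected-footprint overlap
  fps <- lapply(nuclei, function(nc) {
    fp <- matrix(FALSE, H, W)
    for (mk in nc$masks) if (!is.null(mk)) fp <- fp | mk
    fp
  })
  for (i in seq_along(nuclei)) {
    for (j in seq_len(i - 1L)) {
      if (any(fps[[i]] & fps[[j]])) {
        for (k in c(i, j)) {
          if (nuclei[[k]]$qc == "clear") {
            nuclei[[k]]$qc <- "discarded"
            nuclei[[k]]$discard_reason <- "overlap"
          }
        }
      }
    }
  }
  for (i in seq_along(nuclei)) {
    if (nuclei[[i]]$qc == "clear" &&
        (nuclei[[i]]$volume_um3 < config$nucleus_volume_um3[1] ||
         nuclei[[i]]$volume_um3 > config$nucleus_volume_um3[2])) {
      nuclei[[i]]$qc <- "discarded"
      nuclei[[i]]$discard_reason <- "size"
    }
  }
  structure(nuclei, class = "nucleus_set", dims = dims, n_layers = L)
}

#' @export
print.nucleus_set <- function(x, ...) {
  n_clear <- sum(vapply(x, function(nc) nc$qc == "clear", TRUE))
  cat(sprintf("<nucleus_set> %d nuclei (%d clear, %d discarded)\n",
              length(x), n_clear, length(x) - n_clear))
  invisible(x)
}

#' @export
print.nucleus3d <- function(x, ...) {
  cat(sprintf(
    "<nucleus3d> id %d, layers %d-%d, %.1f um^3, centroid (%.2f, %.2f, %.2f) um, %s%s\n",
    x$id, x$layer_span[1], x$layer_span[2], x$volume_um3,
    x$centroid_um[1], x$centroid_um[2], x$centroid_um[3], x$qc,
    if (is.na(x$discard_reason)) "" else paste0(" (", x$discard_reason, ")")))
  invisible(x)
}

# integer label volume [row, col, layer] with nucleus ids painted in
label_volume <- function(nuclei) {
  dims <- attr(nuclei, "dims"); L <- attr(nuclei, "n_layers")
  vol <- array(0L, dim = c(dims[1], dims[2], L))
  for (nc in nuclei) {
    for (l in seq_len(L)) {
      if (!is.null(nc$masks[[l]])) {
        layer <- vol[, , l]
        layer[nc$masks[[l]]] <- nc$id
        vol[, , l] <- layer
      }
    }
  }
  vol
}
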