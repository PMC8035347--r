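#' Detect gene-signal candidate maxima inside a nucleus
#'
#' A pixel is a candidate when its intensity is greater than or equal to all
#' of its up-to-24 in-plane neighbours (the 5 x 5 window minus the centre;
#' fewer near the nucleus mask edge, where only neighbours inside the mask
#' are compared) and strictly exceeds the intensity floor
#' `mean + spot_floor_k * sd` of the channel inside the nucleus. Plateau
#' ties yield multiple candidates; [merge_3d()] collapses them.
#'
#' @param channel_stack list of per-layer matrices for one channel (FITC or
#'   TRITC), e.g. from [preprocess_stack()].
#' @param nucleus a clear `nucleus3d` from [link_3d()].
#' @param config a [fish_config()].
#' @return Data frame of candidates with 0-based `x_px`, `y_px`, `layer`,
#'   plus `intensity` and um-space `x_um`, `y_um`, `z_um`.
#' @export
detect_candidates <- function(channel_stack, nucleus, config = fish_config()) {
  stopifnot(inherits(nucleus, "nucleus3d"))
  validate_config(config)
  if (nucleus$qc != "clear") stop("candidates are only detected in clear nuclei")
  px <- config$pixel_size_xy; zi <- config$z_interval

  vals <- unlist(lapply(seq_along(nucleus$masks), function(l) {
    mk <- nucleus$masks[[l]]
    if (is.null(mk)) return(numeric(0))
    channel_stack[[l]][mk]
  }))
  s <- if (length(vals) > 1) stats::sd(vals) else 0
  floor_thr <- mean(vals) + config$spot_floor_k * s

  out <- list()
  for (l in seq_along(nucleus$masks)) {
    mk <- nucleus$masks[[l]]
    if (is.null(mk) || !any(mk)) next
    v <- channel_stack[[l]]
    ok <- mk & (v > floor_thr)
    if (!any(ok)) next
    H <- nrow(v); W <- ncol(v)
    vpad <- matrix(-Inf, H + 4L, W + 4L)
    vpad[3:(H + 2L), 3:(W + 2L)] <- v
    mpad <- matrix(FALSE, H + 4L, W + 4L)
    mpad[3:(H + 2L), 3:(W + 2L)] <- mk
    for (di in -2:2) for (dj in -2:2) {
      if (di == 0 && dj == 0) next
      nb_v <- vpad[(3 + di):(H + 2 + di), (3 + dj):(W + 2 + dj)]
      nb_in <- mpad[(3 + di):(H + 2 + di), (3 + dj):(W + 2 + dj)]
      ok <- ok & (!nb_in | v >= nb_v)
      if (!any(ok)) break
    }
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[length(out) + 1L]] <- data.frame(
        x_px = idx[, 2] - 1L, y_px = idx[, 1] - 1L, layer = l - 1L,
        intensity = v[idx])
    }
  }
  cands <- if (length(out)) do.call(rbind, out) else {
    data.frame(x_px = integer(), y_px = integer(), layer = integer(),
               intensity = numeric())
  }
  cands$x_um <- cands$x_px * px
  cands$y_um <- cands$y_px * px
  cands$z_um <- cands$layer * zi
  cands
}

#' Merge candidate maxima into 3D spots
#'
#' Candidates within `config$spot_diameter_um` of each other in um space
#' (single-linkage, across layers) form one group; each group is reduced to
#' the single highest-intensity candidate, with ties broken by lowest
#' `(layer, y_px, x_px)`.
#'
#' @param candidates data frame from [detect_candidates()].
#' @param config a [fish_config()].
#' @return Data frame of spots (one row per physical signal), columns as in
#'   the candidate table.
#' @export
merge_3d <- function(candidates, config = fish_config()) {
  validate_config(config)
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  pos <- as.matrix(candidates[, c("x_um", "y_um", "z_um")])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  d <- as.matrix(stats::dist(pos))
  # tiny tolerance so grid-arithmetic round-off cannot split an
  # exactly-one-layer-apart candidate pair at the 0.6 um boundary
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] <= config$spot_diameter_um + 1e-9) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  picks <- vapply(split(seq_len(n), roots), function(g) {
    g[order(-candidates$intensity[g], candidates$layer[g],
            candidates$y_px[g], candidates$x_px[g])][1]
  }, 1L)
  out <- candidates[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect FITC and TRITC spots for every clear nucleus
#'
#' Runs [detect_candidates()] and [merge_3d()] per clear nucleus and channel
#' and assembles the case-level spot table.
#'
#' @param channels preprocessed channels from [preprocess_stack()].
#' @param nuclei a `nucleus_set` from [link_3d()].
#' @param config a [fish_config()].
#' @return Spot table: `spot_id`, `nucleus_id`, `channel`, 0-based `x_px`,
#'   `y_px`, `layer`, `x_um`, `y_um`, `z_um`, `intensity`.
#' @export
detect_spots <- function(channels, nuclei, config = fish_config()) {
  out <- list()
  for (nc in nuclei) {
    if (nc$qc != "clear") next
    for (ch in c("FITC", "TRITC")) {
      sp <- merge_3d(detect_candidates(channels[[ch]], nc, config), config)
      if (nrow(sp)) {
        sp$nucleus_id <- nc$id
        sp$channel <- ch
        out[[length(out) + 1L]] <- sp
      }
    }
  }
  if (!length(out)) {
    return(data.frame(spot_id = integer(), nucleus_id = integer(),
                      channel = character(), x_px = integer(),
                      y_px = integer(), layer = integer(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      intensity = numeric()))
  }
  spots <- do.call(rbind, out)
  spots <- spots[order(spots$nucleus_id, spots$channel, spots$layer,
                       spots$y_px, spots$x_px), , drop = FALSE]
  spots$spot_id <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  spots[, c("spot_id", "nucleus_id", "channel", "x_px", "y_px", "layer",
            "x_um", "y_um", "z_um", "intensity")]
}
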