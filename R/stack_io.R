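#' Calibrated multi-channel z-stack
#'
#' Container for a 3-channel confocal z-stack. Voxels are stored as a 4D
#' numeric array indexed `[row, column, layer, channel]` with intensities in
#' `[0, 1]`; calibration records the physical voxel size.
#'
#' @param voxels 4D numeric array `[row, column, layer, channel]`,
#'   non-negative.
#' @param pixel_size_xy in-plane pixel size, um/pixel (> 0).
#' @param z_interval layer spacing, um (> 0).
#' @param channel_names character vector naming the 4th dimension; the
#'   scoring pipeline requires `"DAPI"`, `"FITC"` and `"TRITC"` to be
#'   present.
#' @return An object of class `zstack`.
#' @examples
#' v <- array(0, dim = c(16, 16, 2, 3))
#' s <- zstack(v, 0.16, 0.6, c("DAPI", "FITC", "TRITC"))
#' s$n_layers
#' @export
zstack <- function(voxels, pixel_size_xy = 0.16, z_interval = 0.6,
                   channel_names = c("DAPI", "FITC", "TRITC")) {
  if (length(dim(voxels)) != 4) {
    stop("voxels must be a 4D array [row, column, layer, channel]")
  }
  if (dim(voxels)[4] != length(channel_names)) {
    stop("channel_names length must match the 4th voxel dimension")
  }
  if (anyDuplicated(channel_names)) stop("channel_names must be unique")
  if (pixel_size_xy <= 0 || z_interval <= 0) {
    stop("pixel_size_xy and z_interval must be > 0")
  }
  if (any(voxels < 0)) stop("voxels must be non-negative")
  dimnames(voxels) <- list(NULL, NULL, NULL, channel_names)
  obj <- list(
    voxels = voxels,
    n_layers = dim(voxels)[3],
    pixel_size_xy = pixel_size_xy,
    z_interval = z_interval,
    channel_names = channel_names
  )
  class(obj) <- "zstack"
  obj
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<zstack> %d x %d px, %d layer(s), %d channel(s) [%s]\n",
    d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  calibration: %.4g um/px, z-interval %.4g um\n",
              x$pixel_size_xy, x$z_interval))
  invisible(x)
}

# one channel as a list of layer matrices
channel_layers <- function(stack, channel) {
  ch <- match(channel, stack$channel_names)
  if (is.na(ch)) stop("channel not present in stack: ", channel)
  lapply(seq_len(stack$n_layers), function(l) stack$voxels[, , l, ch])
}

stack_meta <- function(stack, page_order) {
  list(
    pixel_size_xy = stack$pixel_size_xy,
    z_interval = stack$z_interval,
    n_layers = stack$n_layers,
    channels = as.list(stack$channel_names),
    page_order = page_order
  )
}

#' Read a calibrated z-stack from a multi-page TIFF
#'
#' The TIFF must hold one page per (layer, channel) combination. The default
#' page order is layer-major (L0/DAPI, L0/FITC, L0/TRITC, L1/DAPI, ...);
#' channel-major files are read with `config$page_order = "channel_major"`.
#' Calibration is taken from embedded description metadata or a
#' `<path>.meta.json` sidecar when present; on conflict the configuration
#' wins, with a warning.
#'
#' @param path TIFF file path.
#' @param config a [fish_config()]; supplies calibration, channel names and
#'   page order.
#' @return A [zstack()].
#' @export
read_stack <- function(path, config = fish_config()) {
  validate_config(config)
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_chan <- length(config$channel_names)
  if (length(pages) %% n_chan != 0) {
    stop(sprintf(
      "page count (%d) is not divisible by the channel count (%d)",
      length(pages), n_chan))
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) stop("inconsistent page dimensions in ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # collapse gray-stored-as-RGB
  })

  meta <- read_stack_meta(path, pages)
  pixel_size <- config$pixel_size_xy
  z_int <- config$z_interval
  page_order <- config$page_order
  if (!is.null(meta)) {
    for (field in c("pixel_size_xy", "z_interval")) {
      m <- meta[[field]]
      if (!is.null(m) && is.finite(m) &&
          abs(m - config[[field]]) > 1e-12) {
        warning(sprintf(
          "%s: embedded %s (%g) differs from config (%g); using config",
          basename(path), field, m, config[[field]]))
      }
    }
    if (!is.null(meta$page_order) && meta$page_order != page_order) {
      warning(sprintf(
        "%s: embedded page order (%s) differs from config (%s); using config",
        basename(path), meta$page_order, page_order))
    }
  }

  n_layers <- length(pages) %/% n_chan
  h <- dims[[1]][1]; w <- dims[[1]][2]
  vox <- array(0, dim = c(h, w, n_layers, n_chan))
  for (i in seq_along(pages)) {
    if (page_order == "layer_major") {
      l <- (i - 1) %/% n_chan + 1
      ch <- (i - 1) %% n_chan + 1
    } else {
      ch <- (i - 1) %/% n_layers + 1
      l <- (i - 1) %% n_layers + 1
    }
    vox[, , l, ch] <- pages[[i]]
  }
  zstack(vox, pixel_size, z_int, config$channel_names)
}

read_stack_meta <- function(path, pages) {
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (!is.null(meta)) return(meta)
  }
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    return(tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                    error = function(e) NULL))
  }
  NULL
}

#' Write a z-stack to a multi-page TIFF
#'
#' Pages are written in the order given by `page_order` as 16-bit grayscale.
#' Calibration is stored alongside the image in a `<path>.meta.json` sidecar
#' so that a round trip preserves it; voxel values that are multiples of
#' 1/65535 (e.g. anything produced by [generate_case()]) round-trip
#' bit-exactly.
#'
#' @param stack a [zstack()].
#' @param path output TIFF path.
#' @param page_order `"layer_major"` (default) or `"channel_major"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, page_order = "layer_major") {
  stopifnot(inherits(stack, "zstack"))
  page_order <- match.arg(page_order, c("layer_major", "channel_major"))
  if (!dir.exists(dirname(path))) {
    stop("output directory does not exist: ", dirname(path))
  }
  n_chan <- length(stack$channel_names)
  pages <- vector("list", stack$n_layers * n_chan)
  i <- 1
  if (page_order == "layer_major") {
    for (l in seq_len(stack$n_layers)) {
      for (ch in seq_len(n_chan)) {
        pages[[i]] <- stack$voxels[, , l, ch]; i <- i + 1
      }
    }
  } else {
    for (ch in seq_len(n_chan)) {
      for (l in seq_len(stack$n_layers)) {
        pages[[i]] <- stack$voxels[, , l, ch]; i <- i + 1
      }
    }
  }
  pages <- lapply(pages, function(p) pmin(pmax(p, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(stack_meta(stack, page_order),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
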