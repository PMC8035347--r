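#' Parameters for the synthetic FISH z-stack generator
#'
#' Defaults emulate the acquisition geometry the scorer targets: 7 layers at
#' 0.6 um interval, 0.16 um/pixel in-plane, ellipsoidal DAPI-stained nuclei
#' and sub-resolution FITC/TRITC gene signals rendered as isotropic (in um)
#' Gaussian blobs of sigma = half the 0.6 um nominal spot diameter. Spot
#' positions are snapped to the voxel grid so that noise-free recovery by
#' the pipeline is exact.
#'
#' @param image_size `(rows, columns)` in pixels.
#' @param n_layers number of z-layers.
#' @param pixel_size_xy um per pixel in-plane.
#' @param z_interval um between layers.
#' @param n_nuclei nuclei per case.
#' @param nucleus_radii_um `(min, max)` of the in-plane semi-axis range, um.
#' @param nucleus_z_semi_um axial (z) semi-axis, um.
#' @param nucleus_intensity DAPI fill level of a nucleus (0-1).
#' @param spot_sigma_um Gaussian PSF sigma of a rendered spot, um.
#' @param spot_intensity peak spot level (0-1).
#' @param background_level additive offset on all channels (0-1).
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd standard deviation of Gaussian noise (intensity units).
#' @param pattern_mix named proportions over the five patterns
#'   (`normal`, `multiple_copy`, `typical_break`, `nontypical_break`,
#'   `other`); must sum to 1.
#' @param include_unclear if `TRUE`, two additional deliberately-overlapping
#'   nuclei are placed (at under one semi-axis separation) to exercise the
#'   segmentation QC; they are excluded from the expected scoring.
#' @param seed integer seed; identical parameters give bit-identical output.
#' @param max_attempts rejection-sampling bound for nucleus placement.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(image_size = c(192, 192),
                         n_layers = 7,
                         pixel_size_xy = 0.16,
                         z_interval = 0.6,
                         n_nuclei = 4,
                         nucleus_radii_um = c(3.2, 4.2),
                         nucleus_z_semi_um = 1.6,
                         nucleus_intensity = 0.7,
                         spot_sigma_um = 0.3,
                         spot_intensity = 0.85,
                         background_level = 0.05,
                         noise_model = c("none", "gaussian", "poisson"),
                         noise_sd = 0.01,
                         pattern_mix = c(normal = 0.55, multiple_copy = 0.15,
                                         typical_break = 0.10,
                                         nontypical_break = 0.10,
                                         other = 0.10),
                         include_unclear = FALSE,
                         seed = 1L,
                         max_attempts = 500) {
  noise_model <- match.arg(noise_model)
  p <- list(image_size = as.integer(image_size), n_layers = as.integer(n_layers),
            pixel_size_xy = pixel_size_xy, z_interval = z_interval,
            n_nuclei = as.integer(n_nuclei),
            nucleus_radii_um = nucleus_radii_um,
            nucleus_z_semi_um = nucleus_z_semi_um,
            nucleus_intensity = nucleus_intensity,
            spot_sigma_um = spot_sigma_um, spot_intensity = spot_intensity,
            background_level = background_level, noise_model = noise_model,
            noise_sd = noise_sd, pattern_mix = pattern_mix,
            include_unclear = isTRUE(include_unclear),
            seed = as.integer(seed), max_attempts = max_attempts)
  class(p) <- "synth_params"
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  if (abs(sum(p$pattern_mix) - 1) > 1e-8) stop("pattern_mix must sum to 1")
  bad <- setdiff(names(p$pattern_mix), pattern_levels)
  if (length(bad)) stop("unknown pattern(s) in pattern_mix: ",
                        paste(bad, collapse = ", "))
  if (any(p$image_size < 8) || p$n_layers < 1) stop("image too small")
  if (p$pixel_size_xy <= 0 || p$z_interval <= 0) stop("voxel sizes must be > 0")
  if (p$n_nuclei < 0) stop("n_nuclei must be >= 0")
  if (diff(p$nucleus_radii_um) < 0 || p$nucleus_radii_um[1] <= 0) {
    stop("nucleus_radii_um must be a positive (min, max) range")
  }
  invisible(p)
}

#' Sample nucleus pattern labels from a pattern mix
#'
#' @param n number of labels.
#' @param params a [synth_params()] (only `pattern_mix` is used).
#' @return Character vector of pattern labels.
#' @export
sample_patterns <- function(n, params = synth_params()) {
  mix <- params$pattern_mix
  sample(names(mix), n, replace = TRUE, prob = mix)
}

snap <- function(x, step) round(x / step) * step

#' Place the gene signals realizing one nucleus pattern
#'
#' Emits the FITC/TRITC spot positions whose detected counts satisfy the
#' classifier's defining predicate for `pattern`. Signal sites ("anchors")
#' are equally spaced on a circle of radius `0.55 * min(a, b)` inside the
#' nucleus, which keeps same-channel spots more than two spot diameters
#' apart and separated opposite-channel signals well beyond the 1.2 um
#' cutoff; co-localized partners are offset in-plane by a distance drawn
#' uniformly from `[0, 0.6]` um (half the cutoff). Positions are snapped to
#' the voxel grid. Uses the current RNG state.
#'
#' @param pattern one of `normal`, `multiple_copy`, `typical_break`,
#'   `nontypical_break`, `other`.
#' @param nucleus list with `center_um` (x, y, z), `semi_um` (a, b, c) and
#'   `theta` (radians).
#' @param params a [synth_params()].
#' @return Data frame with `channel`, `x_um`, `y_um`, `z_um`.
#' @export
place_pattern <- function(pattern, nucleus, params = synth_params()) {
  if (!pattern %in% pattern_levels) stop("unknown pattern: ", pattern)
  a <- nucleus$semi_um[1]; b <- nucleus$semi_um[2]; cz <- nucleus$semi_um[3]
  ctr <- nucleus$center_um
  k <- switch(pattern,
              normal = 2L, multiple_copy = sample(3:4, 1L),
              typical_break = 3L, nontypical_break = 4L, other = 3L)
  rad <- 0.55 * min(a, b)
  chord <- 2 * rad * sin(pi / k)
  if (!is.finite(chord) || chord < 2.2) {
    stop("nucleus too small to hold the required spots for pattern ", pattern)
  }
  phase <- runif(1, 0, 2 * pi)
  ang <- phase + 2 * pi * (seq_len(k) - 1) / k
  zoff <- sample(c(-1, 0, 1), k, replace = TRUE,
                 prob = c(0.25, 0.5, 0.25)) * params$z_interval
  anchors <- data.frame(x = ctr[1] + rad * cos(ang),
                        y = ctr[2] + rad * sin(ang),
                        z = ctr[3] + zoff)
  # keep every anchor (plus partner slack) inside the ellipsoid
  for (i in seq_len(k)) {
    if (ellipsoid_q(anchors$x[i], anchors$y[i], anchors$z[i],
                    ctr, c(a, b, cz), nucleus$theta, slack = 0.7) > 0.81) {
      anchors$z[i] <- ctr[3]
    }
  }

  coloc_at <- function(i) {
    d <- runif(1, 0, 0.6)
    th <- runif(1, 0, 2 * pi)
    rbind(
      data.frame(channel = "FITC", x_um = anchors$x[i], y_um = anchors$y[i],
                 z_um = anchors$z[i]),
      data.frame(channel = "TRITC", x_um = anchors$x[i] + d * cos(th),
                 y_um = anchors$y[i] + d * sin(th), z_um = anchors$z[i]))
  }
  single_at <- function(i, channel) {
    data.frame(channel = channel, x_um = anchors$x[i], y_um = anchors$y[i],
               z_um = anchors$z[i])
  }
  spots <- switch(pattern,
    normal = rbind(coloc_at(1), coloc_at(2)),
    multiple_copy = do.call(rbind, lapply(seq_len(k), coloc_at)),
    typical_break = rbind(coloc_at(1), single_at(2, "FITC"),
                          single_at(3, "TRITC")),
    nontypical_break = rbind(coloc_at(1), single_at(2, "FITC"),
                             single_at(3, "FITC"), single_at(4, "TRITC")),
    other = rbind(coloc_at(1), single_at(2, "FITC"), single_at(3, "FITC")))
  spots$x_um <- snap(spots$x_um, params$pixel_size_xy)
  spots$y_um <- snap(spots$y_um, params$pixel_size_xy)
  spots$z_um <- snap(spots$z_um, params$z_interval)
  rownames(spots) <- NULL
  spots
}

# quadratic form of a point relative to a rotated ellipsoid;
# `slack` adds in-plane headroom (um) for a co-localized partner offset
ellipsoid_q <- function(x, y, z, ctr, semi, theta, slack = 0) {
  dx <- x - ctr[1]; dy <- y - ctr[2]; dz <- z - ctr[3]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  r <- sqrt(u^2 + v^2)
  if (r > 0 && slack > 0) {
    u <- u * (r + slack) / r
    v <- v * (r + slack) / r
  }
  (u / semi[1])^2 + (v / semi[2])^2 + (dz / semi[3])^2
}

#' Generate a synthetic FISH case with ground truth
#'
#' Places non-overlapping ellipsoidal nuclei fully inside the field by
#' rejection sampling, assigns each a signal pattern drawn from
#' `pattern_mix`, places the corresponding FITC/TRITC signals
#' ([place_pattern()]), renders the three channels and returns the stack
#' together with the exact ground truth (nucleus geometry, spot positions,
#' expected signal pairs and the expected case diagnosis). Identical
#' parameters (including the seed) give bit-identical output; voxel values
#' are quantized to the 16-bit grid so a TIFF round trip is exact.
#'
#' @param params a [synth_params()].
#' @return List with `stack` (a [zstack()]) and `truth` (class
#'   `fish_ground_truth`: data frames `nuclei`, `spots`, `pairs`, plus
#'   `expected_diagnosis`).
#' @examples
#' case <- generate_case(synth_params(n_nuclei = 1, seed = 7,
#'   pattern_mix = c(normal = 1)))
#' table(case$truth$spots$channel)  # 2 FITC + 2 TRITC
#' @export
generate_case <- function(params = synth_params()) {
  validate_synth_params(params)
  with_seed(params$seed, generate_case_impl(params))
}

generate_case_impl <- function(params) {
  H <- params$image_size[1]; W <- params$image_size[2]
  px <- params$pixel_size_xy; zi <- params$z_interval
  L <- params$n_layers
  w_um <- (W - 1) * px; h_um <- (H - 1) * px
  cz <- (L - 1) / 2 * zi

  n_total <- params$n_nuclei + if (params$include_unclear) 2L else 0L
  nuclei <- data.frame()
  attempts <- 0
  stalled <- 0
  while (nrow(nuclei) < params$n_nuclei) {
    attempts <- attempts + 1
    if (attempts > params$max_attempts) {
      stop("infeasible placement: could not fit ", params$n_nuclei,
           " nuclei in the field after ", params$max_attempts, " attempts")
    }
    if (stalled > 50) {  # dead-end configuration: restart the arrangement
      nuclei <- data.frame()
      stalled <- 0
    }
    ax <- runif(1, params$nucleus_radii_um[1], params$nucleus_radii_um[2])
    ay <- runif(1, params$nucleus_radii_um[1], params$nucleus_radii_um[2])
    th <- runif(1, 0, pi)
    m <- max(ax, ay) + 0.8
    if (2 * m >= min(w_um, h_um)) stop("nucleus too large for the field")
    x <- runif(1, m, w_um - m); y <- runif(1, m, h_um - m)
    ok <- TRUE
    if (nrow(nuclei)) {
      dd <- sqrt((nuclei$x_um - x)^2 + (nuclei$y_um - y)^2)
      ok <- all(dd >= pmax(nuclei$ax_um, nuclei$ay_um) + max(ax, ay) + 2.0)
    }
    if (ok) {
      stalled <- 0
      nuclei <- rbind(nuclei, data.frame(
        id = nrow(nuclei) + 1L, x_um = x, y_um = y, z_um = cz,
        ax_um = ax, ay_um = ay, az_um = params$nucleus_z_semi_um,
        theta = th, pattern = NA_character_))
    } else {
      stalled <- stalled + 1
    }
  }
  if (nrow(nuclei)) {
    nuclei$pattern <- sample_patterns(nrow(nuclei), params)
  }

  unclear_ids <- integer(0)
  if (params$include_unclear && nrow(nuclei)) {
    # a second nucleus overlapping the first: the merged blob is not a
    # "clear individual" nucleus and must be discarded by QC
    twin <- nuclei[1, ]
    twin$id <- nrow(nuclei) + 1L
    twin$pattern <- "unclear"
    # offset direction chosen away from the other nuclei and the border
    d <- 1.2 * twin$ax_um
    cands <- rbind(c(d, 0), c(-d, 0), c(0, d), c(0, -d))
    best <- NULL; best_score <- -Inf
    for (ci in seq_len(nrow(cands))) {
      tx <- nuclei$x_um[1] + cands[ci, 1]; ty <- nuclei$y_um[1] + cands[ci, 2]
      m <- max(twin$ax_um, twin$ay_um) + 0.5
      if (tx < m || tx > w_um - m || ty < m || ty > h_um - m) next
      others <- nuclei[-1, , drop = FALSE]
      sc <- if (nrow(others)) min(sqrt((others$x_um - tx)^2 +
                                       (others$y_um - ty)^2)) else Inf
      if (sc > best_score) { best_score <- sc; best <- c(tx, ty) }
    }
    if (!is.null(best)) {
      twin$x_um <- best[1]; twin$y_um <- best[2]
      nuclei <- rbind(nuclei, twin)
      unclear_ids <- twin$id
    }
  }

  spots <- data.frame(nucleus_id = integer(), channel = character(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric())
  for (i in seq_len(nrow(nuclei))) {
    if (nuclei$pattern[i] %in% pattern_levels) {
      sp <- place_pattern(nuclei$pattern[i],
                          list(center_um = c(nuclei$x_um[i], nuclei$y_um[i],
                                             nuclei$z_um[i]),
                               semi_um = c(nuclei$ax_um[i], nuclei$ay_um[i],
                                           nuclei$az_um[i]),
                               theta = nuclei$theta[i]),
                          params)
      sp <- cbind(nucleus_id = nuclei$id[i], sp)
      spots <- rbind(spots, sp)
    }
  }
  rownames(spots) <- NULL

  pairs <- gt_pairs(spots, cutoff = 1.2)
  scored <- setdiff(nuclei$id, unclear_ids)
  labels <- nuclei$pattern[match(scored, nuclei$id)]
  frac_break <- if (length(labels)) {
    100 * mean(labels %in% c("typical_break", "nontypical_break"))
  } else 0
  truth <- list(
    nuclei = nuclei,
    spots = spots,
    pairs = pairs,
    unclear_ids = unclear_ids,
    expected_diagnosis = if (length(labels) == 0) NA_character_
                         else if (frac_break <= 10) "negative" else "positive",
    params = params
  )
  class(truth) <- "fish_ground_truth"

  stack <- render_stack(nuclei, spots, params)
  list(stack = stack, truth = truth)
}

# ranked non-repetitive pairing on the true positions; definitional for the
# ground truth (the pipeline's matcher is tested against a separate oracle)
gt_pairs <- function(spots, cutoff = 1.2) {
  out <- data.frame(nucleus_id = integer(), fitc_row = integer(),
                    tritc_row = integer(), distance_um = numeric(),
                    coloc = logical())
  for (nid in unique(spots$nucleus_id)) {
    f <- which(spots$nucleus_id == nid & spots$channel == "FITC")
    t <- which(spots$nucleus_id == nid & spots$channel == "TRITC")
    if (!length(f) || !length(t)) next
    cand <- expand.grid(fi = f, ti = t)
    cand$d <- sqrt((spots$x_um[cand$fi] - spots$x_um[cand$ti])^2 +
                   (spots$y_um[cand$fi] - spots$y_um[cand$ti])^2 +
                   (spots$z_um[cand$fi] - spots$z_um[cand$ti])^2)
    cand <- cand[order(cand$d, cand$fi, cand$ti), ]
    used_f <- used_t <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (cand$fi[r] %in% used_f || cand$ti[r] %in% used_t) next
      out <- rbind(out, data.frame(
        nucleus_id = nid, fitc_row = cand$fi[r], tritc_row = cand$ti[r],
        distance_um = cand$d[r], coloc = cand$d[r] < cutoff))
      used_f <- c(used_f, cand$fi[r]); used_t <- c(used_t, cand$ti[r])
    }
  }
  rownames(out) <- NULL
  out
}

render_stack <- function(nuclei, spots, params) {
  H <- params$image_size[1]; W <- params$image_size[2]
  px <- params$pixel_size_xy; zi <- params$z_interval
  L <- params$n_layers
  vox <- array(params$background_level, dim = c(H, W, L, 3))

  for (i in seq_len(nrow(nuclei))) {
    nc <- nuclei[i, ]
    for (l in seq_len(L)) {
      dz <- (l - 1) * zi - nc$z_um
      if (abs(dz) >= nc$az_um) next
      f <- sqrt(1 - (dz / nc$az_um)^2)
      a <- nc$ax_um * f / px; b <- nc$ay_um * f / px
      c0 <- nc$x_um / px + 1; r0 <- nc$y_um / px + 1  # 1-based centre
      rr <- max(1L, floor(r0 - max(a, b))):min(H, ceiling(r0 + max(a, b)))
      cc <- max(1L, floor(c0 - max(a, b))):min(W, ceiling(c0 + max(a, b)))
      xo <- matrix(rep(cc - c0, each = length(rr)), length(rr))
      yo <- matrix(rep(rr - r0, times = length(cc)), length(rr))
      u <- xo * cos(nc$theta) + yo * sin(nc$theta)
      v <- -xo * sin(nc$theta) + yo * cos(nc$theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      patch <- vox[rr, cc, l, 1]
      patch[inside] <- pmax(patch[inside], params$nucleus_intensity)
      vox[rr, cc, l, 1] <- patch
    }
  }

  sig <- params$spot_sigma_um
  hw <- ceiling(3 * sig / px)
  for (i in seq_len(nrow(spots))) {
    sp <- spots[i, ]
    ch <- if (sp$channel == "FITC") 2L else 3L
    c0 <- sp$x_um / px + 1; r0 <- sp$y_um / px + 1
    rr <- max(1L, round(r0) - hw):min(H, round(r0) + hw)
    cc <- max(1L, round(c0) - hw):min(W, round(c0) + hw)
    xo <- matrix(rep((cc - c0) * px, each = length(rr)), length(rr))
    yo <- matrix(rep((rr - r0) * px, times = length(cc)), length(rr))
    g2d <- exp(-(xo^2 + yo^2) / (2 * sig^2))
    for (l in seq_len(L)) {
      dz <- (l - 1) * zi - sp$z_um
      gz <- exp(-dz^2 / (2 * sig^2))
      if (gz < 1e-4) next
      vox[rr, cc, l, ch] <- vox[rr, cc, l, ch] +
        params$spot_intensity * gz * g2d
    }
  }

  if (params$noise_model == "gaussian") {
    vox <- vox + rnorm(length(vox), 0, params$noise_sd)
  } else if (params$noise_model == "poisson") {
    vox <- rpois(length(vox), pmax(vox, 0) * 255) / 255
  }
  vox <- pmin(pmax(vox, 0), 1)
  vox <- round(vox * 65535) / 65535
  dim(vox) <- c(H, W, L, 3)
  zstack(vox, px, zi, c("DAPI", "FITC", "TRITC"))
}

#' @export
print.fish_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<fish_ground_truth> %d nuclei, %d spots, %d expected pairs, diagnosis %s\n",
    nrow(x$nuclei), nrow(x$spots), nrow(x$pairs), x$expected_diagnosis))
  invisible(x)
}

#' Write / read ground truth as JSON (um coordinates)
#'
#' @param truth a `fish_ground_truth` from [generate_case()].
#' @param path output JSON path.
#' @return `path` (write) or a `fish_ground_truth` (read), invisibly/plainly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "fish_ground_truth"))
  obj <- list(nuclei = truth$nuclei, spots = truth$spots, pairs = truth$pairs,
              unclear_ids = truth$unclear_ids,
              expected_diagnosis = truth$expected_diagnosis)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("nuclei", "spots", "pairs")) {
    obj[[f]] <- as.data.frame(obj[[f]])
  }
  obj$unclear_ids <- as.integer(unlist(obj$unclear_ids))
  class(obj) <- "fish_ground_truth"
  obj
}
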