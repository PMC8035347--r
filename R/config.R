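#' Run configuration for the FISH scoring pipeline
#'
#' Builds the configuration object used by every pipeline stage. All defaults
#' correspond to the study conditions the scorer was designed for: 0.16 um/px
#' in-plane resolution, 0.6 um z-interval, 0.6 um gene-signal spot diameter,
#' a 1.2 um break-apart cutoff (twice the spot diameter) and a 10% abnormal
#' fraction cutoff for a negative diagnosis.
#'
#' @param pixel_size_xy in-plane pixel size in micrometres (um/pixel).
#' @param z_interval distance between consecutive z-layers in um.
#' @param n_layers expected number of z-layers in an input stack.
#' @param channel_names ordered channel labels; must contain
#'   `"DAPI"`, `"FITC"` and `"TRITC"`.
#' @param page_order page layout of multi-page TIFF stacks: `"layer_major"`
#'   (L0/DAPI, L0/FITC, L0/TRITC, L1/DAPI, ...) or `"channel_major"`
#'   (DAPI/L0..L6, FITC/L0..L6, ...).
#' @param spot_diameter_um nominal gene-signal spot diameter in um; also the
#'   3D grouping radius used when candidate maxima are merged into spots.
#' @param breakapart_cutoff_um 3D distance (um) at and beyond which a matched
#'   FITC-TRITC pair is called break-apart.
#' @param abnormal_fraction_cutoff percentage of counted nuclei with abnormal
#'   (break-apart) patterns at or below which the case is diagnosed negative.
#' @param abnormal_includes_other if `TRUE`, nuclei with the "other" pattern
#'   also count towards the abnormal fraction used for the diagnosis.
#' @param gaussian_sigma standard deviation (pixels) of the Gaussian
#'   noise-reduction filter.
#' @param gaussian_truncation kernel half-width in units of sigma.
#' @param morphology_shape structuring element shape, `"disk"` or `"square"`.
#' @param morphology_radius structuring element radius in pixels.
#' @param match_method template matching score; one of `"SD"`, `"NSD"`,
#'   `"C"`, `"NC"`, `"CC"`, `"NcC"`.
#' @param match_threshold acceptance threshold for template-match peaks
#'   (`>=` for similarity scores C/NC/CC/NcC, `<=` for SD/NSD).
#' @param nms_overlap greedy non-maximum suppression cap: a peak is dropped
#'   when its footprint overlaps an accepted footprint by more than this
#'   fraction (intersection over the smaller footprint).
#' @param footprint_scale factor applied to the matched template's ellipse
#'   semi-axes when its footprint is painted into the layer mask; overshoot
#'   is clipped by the Otsu foreground.
#' @param template_radii_um semi-major axis grid (um) of the parametric
#'   ellipse template bank.
#' @param template_aspects aspect ratios (major/minor) of the template bank.
#' @param template_angle_step orientation step in degrees for elongated
#'   templates.
#' @param templates optional list of user-supplied template matrices; when
#'   given it overrides the parametric bank.
#' @param min_component_px minimum in-plane component size in pixels; smaller
#'   components ("isolated vertices") are erased. Default: area of a disk of
#'   radius 2 um at `pixel_size_xy`.
#' @param nucleus_volume_um3 length-2 numeric, accepted nucleus volume range
#'   in cubic um; nuclei outside the range are discarded by QC.
#' @param spot_floor_k spot candidates must exceed
#'   `mean + spot_floor_k * sd` of the channel intensity inside the nucleus.
#' @param seed integer seed used by any stochastic step.
#'
#' @return An object of class `fish_config` (a validated named list).
#' @examples
#' cfg <- fish_config()
#' cfg$breakapart_cutoff_um
#' @export
fish_config <- function(pixel_size_xy = 0.16,
                        z_interval = 0.6,
                        n_layers = 7,
                        channel_names = c("DAPI", "FITC", "TRITC"),
                        page_order = c("layer_major", "channel_major"),
                        spot_diameter_um = 0.6,
                        breakapart_cutoff_um = 1.2,
                        abnormal_fraction_cutoff = 10.0,
                        abnormal_includes_other = FALSE,
                        gaussian_sigma = 1.0,
                        gaussian_truncation = 3,
                        morphology_shape = c("disk", "square"),
                        morphology_radius = 2,
                        match_method = "NcC",
                        match_threshold = 0.6,
                        nms_overlap = 0.3,
                        footprint_scale = 1.3,
                        template_radii_um = c(3, 4, 5, 6.5, 8),
                        template_aspects = c(1, 1.5),
                        template_angle_step = 30,
                        templates = NULL,
                        min_component_px = NULL,
                        nucleus_volume_um3 = c(15, 130),
                        spot_floor_k = 3,
                        seed = 1L) {
  page_order <- match.arg(page_order)
  morphology_shape <- match.arg(morphology_shape)
  if (is.null(min_component_px)) {
    min_component_px <- round(pi * (2 / pixel_size_xy)^2)
  }
  cfg <- list(
    pixel_size_xy = pixel_size_xy,
    z_interval = z_interval,
    n_layers = as.integer(n_layers),
    channel_names = channel_names,
    page_order = page_order,
    spot_diameter_um = spot_diameter_um,
    breakapart_cutoff_um = breakapart_cutoff_um,
    abnormal_fraction_cutoff = abnormal_fraction_cutoff,
    abnormal_includes_other = isTRUE(abnormal_includes_other),
    gaussian_sigma = gaussian_sigma,
    gaussian_truncation = gaussian_truncation,
    morphology_shape = morphology_shape,
    morphology_radius = as.integer(morphology_radius),
    match_method = match_method,
    match_threshold = match_threshold,
    nms_overlap = nms_overlap,
    footprint_scale = footprint_scale,
    template_radii_um = template_radii_um,
    template_aspects = template_aspects,
    template_angle_step = template_angle_step,
    templates = templates,
    min_component_px = as.integer(min_component_px),
    nucleus_volume_um3 = nucleus_volume_um3,
    spot_floor_k = spot_floor_k,
    seed = as.integer(seed)
  )
  class(cfg) <- "fish_config"
  validate_config(cfg)
  cfg
}

#' @export
print.fish_config <- function(x, ...) {
  cat("<fish_config>\n")
  cat(sprintf("  calibration: %.3g um/px, z-interval %.3g um, %d layers\n",
              x$pixel_size_xy, x$z_interval, x$n_layers))
  cat(sprintf("  spot diameter %.3g um | break-apart cutoff %.3g um | abnormal cutoff %.3g%%\n",
              x$spot_diameter_um, x$breakapart_cutoff_um,
              x$abnormal_fraction_cutoff))
  cat(sprintf("  matching: %s >= %.3g (template bank: %d radii x %d aspects)\n",
              x$match_method, x$match_threshold,
              length(x$template_radii_um), length(x$template_aspects)))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "fish_config"))
  if (!(cfg$pixel_size_xy > 0)) stop("pixel_size_xy must be > 0")
  if (!(cfg$z_interval > 0)) stop("z_interval must be > 0")
  if (!(cfg$n_layers >= 1)) stop("n_layers must be >= 1")
  if (!all(c("DAPI", "FITC", "TRITC") %in% cfg$channel_names)) {
    stop("channel_names must include DAPI, FITC and TRITC")
  }
  if (!(cfg$spot_diameter_um > 0)) stop("spot_diameter_um must be > 0")
  if (!(cfg$breakapart_cutoff_um > 0)) stop("breakapart_cutoff_um must be > 0")
  if (cfg$abnormal_fraction_cutoff < 0 || cfg$abnormal_fraction_cutoff > 100) {
    stop("abnormal_fraction_cutoff must lie in [0, 100]")
  }
  if (!cfg$match_method %in% c("SD", "NSD", "C", "NC", "CC", "NcC")) {
    stop("match_method must be one of SD, NSD, C, NC, CC, NcC")
  }
  if (cfg$gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  if (cfg$morphology_radius < 1) stop("morphology_radius must be >= 1")
  if (length(cfg$nucleus_volume_um3) != 2 ||
      cfg$nucleus_volume_um3[1] >= cfg$nucleus_volume_um3[2]) {
    stop("nucleus_volume_um3 must be an increasing length-2 range")
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds any subset of the [fish_config()] fields; missing fields
#' keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `fish_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be YAML or JSON: ", path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(fish_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(fish_config, vals)
}

# restore RNG state on exit; used by every seeded entry point
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}
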