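#' Score a z-stack in memory
#'
#' Runs the full scoring chain on a [zstack()]: preprocess, per-layer
#' template-matching segmentation, component labeling, 3D linking with QC,
#' spot detection and 3D merging, greedy FITC-TRITC pairing, pair calling,
#' per-nucleus classification and case aggregation.
#'
#' @param stack a [zstack()].
#' @param config a [fish_config()].
#' @return Object of class `fish_case`: `report` (a `fish_report`),
#'   `nuclei` (the `nucleus_set`), `spots` and `pairs` tables, the label
#'   volume and a stage log.
#' @export
score_stack <- function(stack, config = fish_config()) {
  stopifnot(inherits(stack, "zstack"))
  validate_config(config)
  log <- list()
  tick <- function(stage, n_in, n_out, t0) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out,
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }

  t0 <- as.numeric(Sys.time())
  missing <- setdiff(c("DAPI", "FITC", "TRITC"), stack$channel_names)
  if (length(missing)) {
    stop("input: required channel(s) missing from stack: ",
         paste(missing, collapse = ", "))
  }
  channels <- preprocess_stack(stack, config)
  tick("preprocess", stack$n_layers * 3L, stack$n_layers * 3L, t0)

  t0 <- as.numeric(Sys.time())
  templates <- template_bank(config)
  masks <- lapply(channels$DAPI, segment_layer, templates = templates,
                  config = config)
  tick("segment", stack$n_layers, sum(vapply(masks, sum, 1)), t0)

  t0 <- as.numeric(Sys.time())
  labeled <- lapply(masks, connected_components,
                    min_size = config$min_component_px)
  nuclei <- link_3d(labeled, config)
  n_clear <- sum(vapply(nuclei, function(nc) nc$qc == "clear", TRUE))
  tick("link_3d", length(labeled), length(nuclei), t0)

  t0 <- as.numeric(Sys.time())
  spots <- detect_spots(channels, nuclei, config)
  tick("spots", n_clear, nrow(spots), t0)

  t0 <- as.numeric(Sys.time())
  pairs_list <- list()
  score_rows <- list()
  for (nc in nuclei) {
    if (nc$qc != "clear") {
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        nucleus_id = nc$id, n_coloc = 0L, n_break_pairs = 0L,
        n_unpaired_fitc = 0L, n_unpaired_tritc = 0L, qc = "discarded",
        discard_reason = nc$discard_reason)
      next
    }
    f <- spots[spots$nucleus_id == nc$id & spots$channel == "FITC", ,
               drop = FALSE]
    t <- spots[spots$nucleus_id == nc$id & spots$channel == "TRITC", ,
               drop = FALSE]
    gm <- greedy_match(f, t)
    pr <- call_pairs(gm$pairs, config)
    if (nrow(pr)) {
      pairs_list[[length(pairs_list) + 1L]] <- cbind(nucleus_id = nc$id, pr)
    }
    score_rows[[length(score_rows) + 1L]] <- data.frame(
      nucleus_id = nc$id,
      n_coloc = sum(pr$call == "colocalized"),
      n_break_pairs = sum(pr$call == "breakapart"),
      n_unpaired_fitc = length(gm$unpaired_fitc),
      n_unpaired_tritc = length(gm$unpaired_tritc),
      qc = "clear", discard_reason = NA_character_)
  }
  pairs <- if (length(pairs_list)) do.call(rbind, pairs_list) else {
    data.frame(nucleus_id = integer(), fitc_id = integer(),
               tritc_id = integer(), distance_um = numeric(),
               call = character())
  }
  rownames(pairs) <- NULL
  tick("pairing", nrow(spots), nrow(pairs), t0)

  t0 <- as.numeric(Sys.time())
  scores <- if (length(score_rows)) do.call(rbind, score_rows) else {
    data.frame(nucleus_id = integer(), n_coloc = integer(),
               n_break_pairs = integer(), n_unpaired_fitc = integer(),
               n_unpaired_tritc = integer(), qc = character(),
               discard_reason = character())
  }
  report <- score_case(scores, config)
  tick("score", nrow(scores), report$total_counted, t0)

  out <- list(report = report, nuclei = nuclei, spots = spots, pairs = pairs,
              labels = label_volume(nuclei), log = do.call(rbind, log),
              config = config)
  class(out) <- "fish_case"
  out
}

#' @export
print.fish_case <- function(x, ...) {
  cat(sprintf("<fish_case> %d nuclei, %d spots, %d pairs\n",
              length(x$nuclei), nrow(x$spots), nrow(x$pairs)))
  print(x$report)
  invisible(x)
}

#' Run the scoring pipeline on a TIFF stack and write all artifacts
#'
#' Reads the stack, scores it ([score_stack()]) and writes `spots.csv`,
#' `pairs.csv`, `nuclei.csv`, `report.json`, `report.csv`, `labels.tiff`
#' and `run.log` to `out_dir`. Outputs other than the log are byte-identical
#' across repeated runs on identical inputs.
#'
#' @param stack_path path to a multi-page TIFF, or a [zstack()] directly.
#' @param config a [fish_config()].
#' @param out_dir output directory (created if absent); `NULL` skips
#'   writing.
#' @return A `fish_case`, invisibly.
#' @export
run_pipeline <- function(stack_path, config = fish_config(), out_dir = NULL) {
  stack <- if (inherits(stack_path, "zstack")) stack_path else {
    read_stack(stack_path, config)
  }
  case <- score_stack(stack, config)
  if (!is.null(out_dir)) write_case(case, out_dir)
  invisible(case)
}

#' Write a scored case's artifact files
#'
#' @param case a `fish_case` from [score_stack()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_case <- function(case, out_dir) {
  stopifnot(inherits(case, "fish_case"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(case$spots, file.path(out_dir, "spots.csv"), row.names = FALSE)
  write.csv(case$pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  write.csv(case$report$nuclei, file.path(out_dir, "nuclei.csv"),
            row.names = FALSE)
  write_report(case$report, out_dir)
  lab <- case$labels / 65535
  tiff::writeTIFF(lapply(seq_len(dim(lab)[3]), function(l) lab[, , l]),
                  file.path(out_dir, "labels.tiff"),
                  bits.per.sample = 16L, compression = "none", reduce = FALSE)
  log_lines <- apply(case$log, 1, function(r) {
    sprintf("stage=%s n_in=%s n_out=%s seconds=%s",
            r[["stage"]], r[["n_in"]], r[["n_out"]], r[["seconds"]])
  })
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

report_as_list <- function(report) {
  list(
    total_counted = report$total_counted,
    discarded = report$discarded,
    pattern_counts = as.list(report$pattern_counts),
    pattern_pct = lapply(as.list(report$pattern_pct),
                         function(v) round(v, 1)),
    breakapart_ratio = round(report$breakapart_ratio, 1),
    normal_multiple_ratio = round(report$normal_multiple_ratio, 1),
    abnormal_ratio = round(report$abnormal_ratio, 1),
    abnormal_fraction_cutoff = report$abnormal_fraction_cutoff,
    abnormal_includes_other = report$abnormal_includes_other,
    diagnosis = report$diagnosis
  )
}

#' Write / read the clinical-style case report
#'
#' `write_report` emits `report.json` (all case-level fields) and
#' `report.csv` (the per-nucleus table); `read_report` reconstructs the
#' `fish_report` from a directory written by [write_case()], so a nucleus
#' can be removed and the diagnosis recomputed offline.
#'
#' @param report a `fish_report`.
#' @param out_dir directory for `report.json` / `report.csv`.
#' @return `out_dir` invisibly (write); a `fish_report` (read).
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "fish_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_as_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(report$nuclei, file.path(out_dir, "report.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' @rdname write_report
#' @param dir directory holding `report.json` and `report.csv`.
#' @export
read_report <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  nuclei <- read.csv(file.path(dir, "report.csv"),
                     stringsAsFactors = FALSE)
  cfg <- fish_config(
    abnormal_fraction_cutoff = meta$abnormal_fraction_cutoff,
    abnormal_includes_other = isTRUE(meta$abnormal_includes_other))
  score_case(nuclei[, c("nucleus_id", "n_coloc", "n_break_pairs",
                        "n_unpaired_fitc", "n_unpaired_tritc", "qc",
                        "discard_reason")], cfg)
}
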