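#' Classify a nucleus signal pattern
#'
#' Patterns are a total function of `(C, G, R)`: the number of co-localized
#' (fusion) pairs `C`, and the counts of separated FITC (`G`) and TRITC
#' (`R`) signals. A break-apart-called matched pair contributes one
#' separated signal to each of `G` and `R`.
#'
#' \describe{
#'   \item{normal}{exactly 2 co-localizations, no separated signals}
#'   \item{multiple_copy}{more than 2 co-localizations, no separated signals}
#'   \item{typical_break}{one co-localization plus one separated FITC and
#'     one separated TRITC signal}
#'   \item{nontypical_break}{at least one separated signal in each channel,
#'     in any other combination}
#'   \item{other}{any remaining combination with at least one signal (e.g.
#'     a single co-localization and nothing else, or separated signals in
#'     only one channel)}
#'   \item{discarded}{no signals at all; excluded from counting}
#' }
#'
#' @param C number of co-localized pairs (vectorized).
#' @param G number of separated FITC signals.
#' @param R number of separated TRITC signals.
#' @return Character vector of pattern labels.
#' @examples
#' classify_nucleus(2, 0, 0)  # normal
#' classify_nucleus(1, 1, 1)  # typical_break
#' classify_nucleus(1, 2, 0)  # other
#' @export
classify_nucleus <- function(C, G, R) {
  if (any(C < 0 | G < 0 | R < 0)) stop("counts must be >= 0")
  n <- max(length(C), length(G), length(R))
  C <- rep_len(C, n); G <- rep_len(G, n); R <- rep_len(R, n)
  out <- rep("other", n)
  out[C + G + R == 0] <- "discarded"
  out[C == 2 & G == 0 & R == 0] <- "normal"
  out[C > 2 & G == 0 & R == 0] <- "multiple_copy"
  out[G >= 1 & R >= 1] <- "nontypical_break"
  out[C == 1 & G == 1 & R == 1] <- "typical_break"
  out
}

pattern_levels <- c("normal", "multiple_copy", "typical_break",
                    "nontypical_break", "other")

#' Per-nucleus score table constructor
#'
#' Convenience builder for the nucleus score table consumed by
#' [score_case()]; arguments are recycled to a common length.
#'
#' @param n_coloc co-localized pair count per nucleus.
#' @param n_break_pairs break-apart-called matched pair count.
#' @param n_unpaired_fitc,n_unpaired_tritc unpaired spot counts.
#' @param nucleus_id optional ids (default `1..n`).
#' @param qc optional QC status (`"clear"`/`"discarded"`).
#' @return Data frame of nucleus scores.
#' @export
nucleus_scores <- function(n_coloc, n_break_pairs = 0, n_unpaired_fitc = 0,
                           n_unpaired_tritc = 0, nucleus_id = NULL,
                           qc = "clear") {
  n <- max(length(n_coloc), length(n_break_pairs), length(n_unpaired_fitc),
           length(n_unpaired_tritc))
  if (is.null(nucleus_id)) nucleus_id <- seq_len(n)
  data.frame(
    nucleus_id = nucleus_id,
    n_coloc = rep_len(n_coloc, n),
    n_break_pairs = rep_len(n_break_pairs, n),
    n_unpaired_fitc = rep_len(n_unpaired_fitc, n),
    n_unpaired_tritc = rep_len(n_unpaired_tritc, n),
    qc = rep_len(qc, n),
    discard_reason = NA_character_
  )
}

#' Aggregate nucleus scores into a case report
#'
#' Computes per-pattern counts and percentages over the counted (clear,
#' non-empty) nuclei, the break-apart ratio and the positive/negative
#' diagnosis: negative if and only if the abnormal fraction is at most
#' `config$abnormal_fraction_cutoff` percent. By default "abnormal" means
#' the break-apart patterns (typical + non-typical);
#' `config$abnormal_includes_other` also counts the "other" pattern.
#'
#' @param scores data frame as built by [nucleus_scores()] (columns
#'   `nucleus_id`, `n_coloc`, `n_break_pairs`, `n_unpaired_fitc`,
#'   `n_unpaired_tritc`, optional `qc`, `discard_reason`).
#' @param config a [fish_config()].
#' @return Object of class `fish_report`: the per-nucleus table (with `C`,
#'   `G`, `R` and `pattern`), pattern counts and percentages,
#'   `breakapart_ratio`, `normal_multiple_ratio`, `total_counted`,
#'   `discarded` and `diagnosis`.
#' @export
score_case <- function(scores, config = fish_config()) {
  validate_config(config)
  req <- c("nucleus_id", "n_coloc", "n_break_pairs", "n_unpaired_fitc",
           "n_unpaired_tritc")
  if (!all(req %in% names(scores))) {
    stop("scores must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(scores$nucleus_id)) stop("nucleus_id must be unique")
  if (is.null(scores$qc)) scores$qc <- "clear"
  if (is.null(scores$discard_reason)) scores$discard_reason <- NA_character_

  scores$C <- scores$n_coloc
  scores$G <- scores$n_unpaired_fitc + scores$n_break_pairs
  scores$R <- scores$n_unpaired_tritc + scores$n_break_pairs
  scores$pattern <- classify_nucleus(scores$C, scores$G, scores$R)
  scores$pattern[scores$qc == "discarded"] <- "discarded"
  empty <- scores$qc != "discarded" & scores$pattern == "discarded"
  scores$qc[empty] <- "discarded"
  scores$discard_reason[empty] <- "no_signals"

  counted <- scores[scores$qc == "clear", , drop = FALSE]
  if (nrow(counted) == 0) stop("no scoreable nuclei")
  counts <- vapply(pattern_levels,
                   function(p) sum(counted$pattern == p), 1L)
  pct <- 100 * counts / nrow(counted)
  breakapart_ratio <- unname(pct["typical_break"] + pct["nontypical_break"])
  normal_multiple_ratio <- unname(pct["normal"] + pct["multiple_copy"])
  abnormal_ratio <- breakapart_ratio +
    if (config$abnormal_includes_other) unname(pct["other"]) else 0
  report <- list(
    nuclei = scores,
    total_counted = nrow(counted),
    discarded = sum(scores$qc == "discarded"),
    pattern_counts = counts,
    pattern_pct = pct,
    breakapart_ratio = breakapart_ratio,
    normal_multiple_ratio = normal_multiple_ratio,
    abnormal_ratio = abnormal_ratio,
    abnormal_fraction_cutoff = config$abnormal_fraction_cutoff,
    abnormal_includes_other = config$abnormal_includes_other,
    diagnosis = if (abnormal_ratio <= config$abnormal_fraction_cutoff)
      "negative" else "positive"
  )
  class(report) <- "fish_report"
  report
}

#' Remove a nucleus from a case report and recompute
#'
#' Moves the nucleus to the discarded set (reason `"manual"`) and recomputes
#' all ratios and the diagnosis. Removing an already-removed nucleus is a
#' no-op; an unknown id is an error.
#'
#' @param report a `fish_report` from [score_case()].
#' @param nucleus_id id of the nucleus to discard.
#' @return Updated `fish_report`.
#' @export
remove_nucleus <- function(report, nucleus_id) {
  stopifnot(inherits(report, "fish_report"))
  i <- match(nucleus_id, report$nuclei$nucleus_id)
  if (is.na(i)) stop("unknown nucleus_id: ", nucleus_id)
  scores <- report$nuclei
  if (scores$qc[i] != "discarded") {
    scores$qc[i] <- "discarded"
    scores$discard_reason[i] <- "manual"
  }
  cfg <- fish_config(
    abnormal_fraction_cutoff = report$abnormal_fraction_cutoff,
    abnormal_includes_other = report$abnormal_includes_other)
  score_case(scores[, c("nucleus_id", "n_coloc", "n_break_pairs",
                        "n_unpaired_fitc", "n_unpaired_tritc", "qc",
                        "discard_reason")], cfg)
}

#' @export
print.fish_report <- function(x, ...) {
  cat("<fish_report>\n")
  cat(sprintf("  counted nuclei: %d | discarded: %d\n",
              x$total_counted, x$discarded))
  for (p in pattern_levels) {
    cat(sprintf("  %-17s %4d (%5.1f%%)\n", p, x$pattern_counts[p],
                x$pattern_pct[p]))
  }
  cat(sprintf("  break-apart ratio: %.1f%% | normal+multiple: %.1f%%\n",
              x$breakapart_ratio, x$normal_multiple_ratio))
  cat(sprintf("  diagnosis: %s (abnormal %.1f%% vs cutoff %.1f%%)\n",
              toupper(x$diagnosis), x$abnormal_ratio,
              x$abnormal_fraction_cutoff))
  invisible(x)
}
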