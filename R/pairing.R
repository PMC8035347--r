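#' 3D Euclidean distance between two spots
#'
#' `sqrt((X_a - X_b)^2 + (Y_a - Y_b)^2 + (Z_a - Z_b)^2)` in micrometres.
#'
#' @param a,b spots: one-row data frames (or named lists) carrying `x_um`,
#'   `y_um`, `z_um`.
#' @return Distance in um.
#' @examples
#' distance_3d(list(x_um = 0, y_um = 0, z_um = 0),
#'             list(x_um = 3, y_um = 4, z_um = 0))  # 5
#' @export
distance_3d <- function(a, b) {
  sqrt((a$x_um[1] - b$x_um[1])^2 +
       (a$y_um[1] - b$y_um[1])^2 +
       (a$z_um[1] - b$z_um[1])^2)
}

#' Greedy ranked pairing of FITC and TRITC spots
#'
#' Forms every FITC x TRITC pair candidate inside one nucleus, weights it by
#' its 3D vector length, sorts all candidates by increasing distance (ties
#' broken by FITC then TRITC spot id) and repeatedly accepts the shortest
#' remaining candidate, removing every candidate that shares either of its
#' spots ("non-repetitive signals"), until none remain. This is the ranked
#' greedy rule, not minimum-total assignment.
#'
#' @param fitc,tritc data frames of spots from one nucleus (`spot_id`,
#'   `x_um`, `y_um`, `z_um`).
#' @return List with `pairs` (data frame `fitc_id`, `tritc_id`,
#'   `distance_um`), `unpaired_fitc` and `unpaired_tritc` (spot id vectors).
#'   The number of pairs always equals `min(nrow(fitc), nrow(tritc))`.
#' @export
greedy_match <- function(fitc, tritc) {
  nf <- nrow(fitc); nt <- nrow(tritc)
  empty <- data.frame(fitc_id = integer(), tritc_id = integer(),
                      distance_um = numeric())
  if (nf == 0 || nt == 0) {
    return(list(pairs = empty,
                unpaired_fitc = fitc$spot_id,
                unpaired_tritc = tritc$spot_id))
  }
  cand <- expand.grid(i = seq_len(nf), j = seq_len(nt))
  cand$distance_um <- sqrt(
    (fitc$x_um[cand$i] - tritc$x_um[cand$j])^2 +
    (fitc$y_um[cand$i] - tritc$y_um[cand$j])^2 +
    (fitc$z_um[cand$i] - tritc$z_um[cand$j])^2)
  cand$fitc_id <- fitc$spot_id[cand$i]
  cand$tritc_id <- tritc$spot_id[cand$j]
  cand <- cand[order(cand$distance_um, cand$fitc_id, cand$tritc_id), ,
               drop = FALSE]
  used_f <- logical(nf); used_t <- logical(nt)
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_f[i] && !used_t[j]) {
      keep <- c(keep, r)
      used_f[i] <- TRUE; used_t[j] <- TRUE
    }
  }
  pairs <- cand[keep, c("fitc_id", "tritc_id", "distance_um"), drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unpaired_fitc = fitc$spot_id[!used_f],
       unpaired_tritc = tritc$spot_id[!used_t])
}

#' Call matched pairs co-localized or break-apart
#'
#' A pair is break-apart when its 3D distance is at least
#' `config$breakapart_cutoff_um` (the cutoff is defined as twice *or more*
#' the gene-signal spot diameter, so the boundary itself is break-apart);
#' shorter pairs are co-localized (fusion) signals.
#'
#' @param pairs data frame with a `distance_um` column (e.g. the `pairs`
#'   element of [greedy_match()]).
#' @param config a [fish_config()].
#' @return `pairs` with an added `call` column
#'   (`"colocalized"`/`"breakapart"`).
#' @export
call_pairs <- function(pairs, config = fish_config()) {
  validate_config(config)
  pairs$call <- ifelse(pairs$distance_um >= config$breakapart_cutoff_um,
                       "breakapart", "colocalized")
  pairs
}
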