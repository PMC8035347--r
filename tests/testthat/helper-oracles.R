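# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# template matching by direct summation over all window positions
oracle_match <- function(I, T, method) {
  H <- nrow(I); W <- ncol(I); h <- nrow(T); w <- ncol(T)
  R <- matrix(0, H - h + 1, W - w + 1)
  for (y in seq_len(H - h + 1)) for (x in seq_len(W - w + 1)) {
    Iw <- I[y:(y + h - 1), x:(x + w - 1)]
    R[y, x] <- switch(method,
      SD = sum((T - Iw)^2),
      NSD = sum((T - Iw)^2) / sqrt(sum(T^2) * sum(Iw^2)),
      C = sum(T * Iw),
      NC = sum(T * Iw) / sqrt(sum(T^2) * sum(Iw^2)),
      CC = sum((T - mean(T)) * (Iw - mean(Iw))),
      NcC = sum((T - mean(T)) * (Iw - mean(Iw))) /
        sqrt(sum((T - mean(T))^2) * sum((Iw - mean(Iw))^2)))
  }
  R
}

# 8-connected components by recursive-free flood fill (explicit stack)
oracle_components <- function(mask, min_size = 1) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {   # column-major scan order
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  out <- matrix(0L, H, W)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# morphological erosion/dilation straight from the min/max definitions
oracle_morph <- function(src, element, op) {
  H <- nrow(src); W <- ncol(src)
  r <- (dim(element) - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) {
      if (!element[di + r[1] + 1L, dj + r[2] + 1L]) next
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W) {
        vals <- c(vals, src[ni, nj])
      }
    }
    out[i, j] <- if (op == "erode") min(vals) else max(vals)
  }
  out
}

# ranked sort-and-prune pairing by repeated scan of the distance matrix
oracle_greedy <- function(fitc, tritc) {
  nf <- nrow(fitc); nt <- nrow(tritc)
  pairs <- data.frame(fitc_id = integer(), tritc_id = integer(),
                      distance_um = numeric())
  if (nf == 0 || nt == 0) {
    return(list(pairs = pairs, unpaired_fitc = fitc$spot_id,
                unpaired_tritc = tritc$spot_id))
  }
  D <- outer(seq_len(nf), seq_len(nt), Vectorize(function(i, j) {
    sqrt((fitc$x_um[i] - tritc$x_um[j])^2 +
         (fitc$y_um[i] - tritc$y_um[j])^2 +
         (fitc$z_um[i] - tritc$z_um[j])^2)
  }))
  alive_f <- rep(TRUE, nf); alive_t <- rep(TRUE, nt)
  while (any(alive_f) && any(alive_t)) {
    best <- NULL; bd <- Inf
    for (i in which(alive_f)) for (j in which(alive_t)) {
      better <- D[i, j] < bd ||
        (D[i, j] == bd &&
           (fitc$spot_id[i] < fitc$spot_id[best[1]] ||
            (fitc$spot_id[i] == fitc$spot_id[best[1]] &&
             tritc$spot_id[j] < tritc$spot_id[best[2]])))
      if (better) { bd <- D[i, j]; best <- c(i, j) }
    }
    pairs <- rbind(pairs, data.frame(fitc_id = fitc$spot_id[best[1]],
                                     tritc_id = tritc$spot_id[best[2]],
                                     distance_um = bd))
    alive_f[best[1]] <- FALSE; alive_t[best[2]] <- FALSE
  }
  list(pairs = pairs, unpaired_fitc = fitc$spot_id[alive_f],
       unpaired_tritc = tritc$spot_id[alive_t])
}

# minimum-total assignment by exhaustive permutation (small instances only)
oracle_assignment <- function(fitc, tritc) {
  nf <- nrow(fitc); nt <- nrow(tritc)
  stopifnot(nf <= nt, nf <= 5)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  D <- outer(seq_len(nf), seq_len(nt), Vectorize(function(i, j) {
    sqrt((fitc$x_um[i] - tritc$x_um[j])^2 +
         (fitc$y_um[i] - tritc$y_um[j])^2 +
         (fitc$z_um[i] - tritc$z_um[j])^2)
  }))
  best <- NULL; bc <- Inf
  for (sub in utils::combn(seq_len(nt), nf, simplify = FALSE)) {
    for (p in perms(sub)) {
      cost <- sum(D[cbind(seq_len(nf), p)])
      if (cost < bc) { bc <- cost; best <- p }
    }
  }
  data.frame(fitc_id = fitc$spot_id, tritc_id = tritc$spot_id[best],
             distance_um = D[cbind(seq_len(nf), best)])
}

random_spots <- function(n, ids = seq_len(n), box = 10) {
  data.frame(spot_id = ids,
             x_um = runif(n, 0, box), y_um = runif(n, 0, box),
             z_um = runif(n, 0, 3.6))
}

# match recovered clear nuclei to ground-truth nuclei by centroid
match_truth <- function(case_res, truth) {
  clear <- Filter(function(nc) nc$qc == "clear", case_res$nuclei)
  map <- data.frame(nucleus_id = integer(), gt_id = integer())
  for (nc in clear) {
    d <- sqrt((truth$nuclei$x_um - nc$centroid_um[1])^2 +
              (truth$nuclei$y_um - nc$centroid_um[2])^2)
    map <- rbind(map, data.frame(nucleus_id = nc$id,
                                 gt_id = truth$nuclei$id[which.min(d)]))
  }
  map
}

half_voxel_diag <- function() sqrt(2 * 0.16^2 + 0.6^2) / 2

# small fast synthetic case used by several module tests
small_case <- function(seed = 1, ...) {
  generate_case(synth_params(image_size = c(128, 128), n_nuclei = 2,
                             seed = seed, ...))
}
small_config <- function(...) fish_config(...)
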