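# builds a minimal clear nucleus covering a rectangle on selected layers
rect_nucleus <- function(H, W, rows, cols, layers, L = 7) {
  masks <- vector("list", L)
  area <- integer(L)
  for (l in layers) {
    mk <- matrix(FALSE, H, W); mk[rows, cols] <- TRUE
    masks[[l]] <- mk; area[l] <- sum(mk)
  }
  nuc <- list(id = 1L, masks = masks, layer_span = range(layers) - 1L,
              area_per_layer = area, n_voxels = sum(area),
              volume_um3 = sum(area) * 0.16^2 * 0.6,
              centroid_um = c(x = 0, y = 0, z = 0),
              qc = "clear", discard_reason = NA_character_)
  class(nuc) <- "nucleus3d"
  nuc
}

blank_channel <- function(H, W, L = 7, level = 0) {
  replicate(L, matrix(level, H, W), simplify = FALSE)
}

test_that("uniform intensity inside a nucleus yields no candidates", {
  nuc <- rect_nucleus(32, 32, 5:25, 5:25, 2:6)
  ch <- blank_channel(32, 32, level = 0.2)
  cands <- detect_candidates(ch, nuc, fish_config())
  expect_equal(nrow(cands), 0)
})

test_that("candidates equal the exhaustive neighborhood-comparison oracle", {
  set.seed(53)
  cfg <- fish_config()
  for (rep in 1:5) {
    H <- 28; W <- 26
    nuc <- rect_nucleus(H, W, 4:24, 4:22, 2:6)
    ch <- lapply(1:7, function(l) matrix(runif(H * W, 0, 0.2), H, W))
    # plant two bright maxima well inside
    ch[[4]][10, 10] <- 0.95
    ch[[4]][20, 16] <- 0.9
    cands <- detect_candidates(ch, nuc, cfg)

    # oracle: scan every in-mask voxel, compare with its in-mask 5x5 ring
    vals <- unlist(lapply(2:6, function(l) ch[[l]][nuc$masks[[l]]]))
    floor_thr <- mean(vals) + cfg$spot_floor_k * sd(vals)
    want <- data.frame()
    for (l in 2:6) {
      mk <- nuc$masks[[l]]; v <- ch[[l]]
      for (j in seq_len(W)) for (i in seq_len(H)) {
        if (!mk[i, j] || v[i, j] <= floor_thr) next
        is_max <- TRUE
        for (di in -2:2) for (dj in -2:2) {
          if (di == 0 && dj == 0) next
          ni <- i + di; nj <- j + dj
          if (ni >= 1 && ni <= H && nj >= 1 && nj <= W && mk[ni, nj] &&
              v[ni, nj] > v[i, j]) is_max <- FALSE
        }
        if (is_max) want <- rbind(want, data.frame(
          x_px = j - 1L, y_px = i - 1L, layer = l - 1L))
      }
    }
    got <- cands[order(cands$layer, cands$y_px, cands$x_px),
                 c("x_px", "y_px", "layer")]
    want <- want[order(want$layer, want$y_px, want$x_px), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("merge_3d groups across layers and keeps the intensity argmax", {
  cfg <- fish_config()
  # same (x, y) on layers 2, 3, 4 with intensities 50, 90, 60 -> layer 3
  cands <- data.frame(x_px = 10, y_px = 10, layer = c(2, 3, 4),
                      intensity = c(50, 90, 60))
  cands$x_um <- cands$x_px * 0.16; cands$y_um <- cands$y_px * 0.16
  cands$z_um <- cands$layer * 0.6
  merged <- merge_3d(cands, cfg)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$layer, 3)

  # two candidates 2 um apart stay separate (beyond the 0.6 um radius)
  two <- data.frame(x_px = c(0, 13), y_px = 0, layer = 0,
                    intensity = c(1, 1))
  two$x_um <- two$x_px * 0.16; two$y_um <- 0; two$z_um <- 0
  expect_equal(nrow(merge_3d(two, cfg)), 2)

  expect_equal(nrow(merge_3d(cands[0, ], cfg)), 0)
})

test_that("plateau ties collapse deterministically to the lowest index", {
  cfg <- fish_config()
  cands <- data.frame(x_px = c(10, 11), y_px = c(10, 10), layer = 3,
                      intensity = c(0.5, 0.5))
  cands$x_um <- cands$x_px * 0.16; cands$y_um <- cands$y_px * 0.16
  cands$z_um <- cands$layer * 0.6
  merged <- merge_3d(cands, cfg)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$x_px, 10)
})

test_that("spot recovery on synthetic nuclei is exact and scale-invariant", {
  case <- small_case(seed = 61)
  cfg <- fish_config()
  res <- score_stack(case$stack, cfg)
  map <- match_truth(res, case$truth)
  for (i in seq_len(nrow(map))) {
    got <- res$spots[res$spots$nucleus_id == map$nucleus_id[i], ]
    want <- case$truth$spots[case$truth$spots$nucleus_id == map$gt_id[i], ]
    expect_equal(table(factor(got$channel, c("FITC", "TRITC"))),
                 table(factor(want$channel, c("FITC", "TRITC"))))
    for (r in seq_len(nrow(want))) {
      ofch <- got[got$channel == want$channel[r], ]
      dd <- sqrt((ofch$x_um - want$x_um[r])^2 + (ofch$y_um - want$y_um[r])^2 +
                 (ofch$z_um - want$z_um[r])^2)
      expect_lte(min(dd), half_voxel_diag())
    }
  }

  # multiplying a channel by a positive constant moves no spot coordinates
  stack2 <- case$stack
  fitc_ix <- match("FITC", stack2$channel_names)
  stack2$voxels[, , , fitc_ix] <- pmin(stack2$voxels[, , , fitc_ix] * 1.4, 1)
  res2 <- score_stack(stack2, cfg)
  cols <- c("nucleus_id", "channel", "x_px", "y_px", "layer")
  expect_equal(res2$spots[, cols], res$spots[, cols])
})

test_that("every detected spot lies inside its nucleus mask", {
  case <- small_case(seed = 67)
  res <- score_stack(case$stack, fish_config())
  by_id <- setNames(res$nuclei, vapply(res$nuclei, function(n) n$id, 1L))
  for (r in seq_len(nrow(res$spots))) {
    sp <- res$spots[r, ]
    mk <- by_id[[as.character(sp$nucleus_id)]]$masks[[sp$layer + 1L]]
    expect_true(mk[sp$y_px + 1L, sp$x_px + 1L])
  }
})
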