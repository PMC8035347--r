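# -- local fixtures ----------------------------------------------------------

ellipse_mask_test <- function(k, a, b) {
  c0 <- (k + 1) / 2
  x <- matrix(rep(seq_len(k) - c0, each = k), k, k)
  (x / a)^2 + (t(x) / b)^2 <= 1
}

ellipse_at <- function(n, ctr, a, b) {
  x <- matrix(rep(seq_len(n) - ctr[2], each = n), n, n)
  y <- matrix(rep(seq_len(n) - ctr[1], times = n), n, n)
  (x / a)^2 + (y / b)^2 <= 1
}

test_that("match_template reproduces the hand-computed 2x2 scores", {
  I <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(as.numeric(match_template(I, I, "SD")), 0)
  expect_equal(as.numeric(match_template(I, I, "C")), 30)
  expect_equal(as.numeric(match_template(I, I, "NC")), 1)
  # mean 2.5 -> T' = I' = [-1.5, -0.5; 0.5, 1.5], sum of squares = 5
  expect_equal(as.numeric(match_template(I, I, "CC")), 5)
  expect_equal(as.numeric(match_template(I, I, "NcC")), 1)
  expect_equal(dim(match_template(matrix(0, 5, 6), matrix(1, 2, 3), "SD")),
               c(4, 4))
  expect_error(match_template(matrix(0, 2, 2), matrix(0, 3, 3)), "larger")
})

test_that("all six scores match the direct-summation oracle on random inputs", {
  set.seed(19)
  methods <- c("SD", "NSD", "C", "NC", "CC", "NcC")
  for (i in 1:20) {
    I <- matrix(runif(12 * 11) + 0.05, 12, 11)
    T <- matrix(runif(4 * 5) + 0.05, 4, 5)
    for (m in methods) {
      got <- match_template(I, T, m)
      want <- oracle_match(I, T, m)
      expect_lt(max(abs(got - want) / pmax(abs(want), 1e-10)), 1e-9)
    }
  }
})

test_that("score ranges hold for non-negative inputs", {
  set.seed(23)
  for (i in 1:10) {
    I <- matrix(runif(10 * 10), 10, 10)
    T <- matrix(runif(9), 3, 3)
    expect_true(all(match_template(I, T, "SD") >= -1e-12))
    nc <- match_template(I, T, "NC")
    expect_true(all(nc >= -1e-9 & nc <= 1 + 1e-9))
    ncc <- match_template(I, T, "NcC")
    expect_true(all(ncc >= -1 - 1e-9 & ncc <= 1 + 1e-9))
  }
})

test_that("the six methods agree on the peak at an exact-template fixture", {
  # an ellipse embedded in a larger empty field: every score must place its
  # best value at the true offset
  img <- matrix(0, 40, 40)
  el <- matrix(0, 15, 15)
  el[ellipse_mask_test(15, 6, 4)] <- 1
  img[11:25, 13:27] <- el
  best <- sapply(c("SD", "NSD", "C", "NC", "CC", "NcC"), function(m) {
    R <- match_template(img, el, m)
    pick <- if (m %in% c("SD", "NSD")) which.min(R) else which.max(R)
    pick
  })
  expect_true(all(best == best[1]))
  R <- match_template(img, el, "NcC")
  expect_equal(max(R), 1, tolerance = 1e-9)
  expect_equal(which(R == max(R)), (13 - 1) * nrow(R) + 11)  # column-major
})

test_that("segment_layer finds synthetic nuclei and ignores blank layers", {
  cfg <- fish_config()
  templates <- template_bank(cfg)
  blank <- matrix(0.05, 96, 96)
  expect_false(any(segment_layer(blank, templates, cfg)))

  # two disjoint circular nuclei
  img <- matrix(0.05, 160, 160)
  for (ctr in list(c(45, 45), c(115, 115))) {
    img[ellipse_at(160, ctr, 22, 20)] <- 0.7
  }
  mask <- segment_layer(img, templates, cfg)
  labs <- connected_components(mask, cfg$min_component_px)
  expect_equal(max(labs), 2)
  # each region covers its nucleus centre
  expect_true(labs[45, 45] > 0 && labs[115, 115] > 0)
  expect_true(labs[45, 45] != labs[115, 115])
})

test_that("connected components match the flood-fill oracle", {
  set.seed(31)
  for (i in 1:8) {
    mask <- matrix(runif(18 * 15) > 0.6, 18, 15)
    got <- connected_components(mask, min_size = 1)
    want <- oracle_components(mask, min_size = 1)
    expect_identical(got, want)
  }
  # and with the isolated-vertex (min size) filter
  for (i in 1:4) {
    mask <- matrix(runif(20 * 20) > 0.7, 20, 20)
    expect_identical(connected_components(mask, min_size = 3),
                     oracle_components(mask, min_size = 3))
  }
})

test_that("component labeling handles the stated base cases", {
  expect_equal(max(connected_components(matrix(FALSE, 5, 5))), 0)
  m <- matrix(FALSE, 12, 12); m[2:6, 2:6] <- TRUE; m[8:12, 8:12] <- TRUE
  labs <- connected_components(m, 1)
  expect_equal(sort(unique(labs[labs > 0])), c(1L, 2L))
  lone <- matrix(FALSE, 5, 5); lone[3, 3] <- TRUE
  expect_equal(max(connected_components(lone, min_size = 2)), 0)
})

test_that("link_3d merges aligned components and applies the QC rules", {
  cfg <- fish_config(min_component_px = 1, nucleus_volume_um3 = c(0.001, 1e6))
  disc <- matrix(0L, 40, 40); disc[ellipse_at(40, c(20, 20), 8, 8)] <- 1L
  layers <- replicate(7, disc, simplify = FALSE)
  nuclei <- link_3d(layers, cfg)
  expect_length(nuclei, 1)
  expect_equal(nuclei[[1]]$layer_span, c(0, 6))
  expect_equal(nuclei[[1]]$qc, "clear")

  # zero overlap across layers -> two distinct nuclei
  a <- matrix(0L, 40, 40); a[5:10, 5:10] <- 1L
  b <- matrix(0L, 40, 40); b[30:35, 30:35] <- 1L
  two <- link_3d(list(a, b), cfg)
  expect_length(two, 2)

  # border contact -> discarded with reason
  edge <- matrix(0L, 40, 40); edge[1:6, 10:15] <- 1L
  res <- link_3d(list(edge), cfg)
  expect_equal(res[[1]]$qc, "discarded")
  expect_equal(res[[1]]$discard_reason, "border")

  # volume bounds -> size discard
  tiny_cfg <- fish_config(min_component_px = 1,
                          nucleus_volume_um3 = c(50, 100))
  res2 <- link_3d(list(disc), tiny_cfg)
  expect_equal(res2[[1]]$discard_reason, "size")
})

test_that("segmentation recovers exactly the ground-truth nuclei", {
  case <- small_case(seed = 41)
  res <- score_stack(case$stack, fish_config())
  clear <- Filter(function(nc) nc$qc == "clear", res$nuclei)
  expect_length(clear, nrow(case$truth$nuclei))
  map <- match_truth(res, case$truth)
  expect_equal(sort(unique(map$gt_id)), sort(case$truth$nuclei$id))
  for (i in seq_len(nrow(map))) {
    nc <- Filter(function(n) n$id == map$nucleus_id[i], clear)[[1]]
    gt <- case$truth$nuclei[case$truth$nuclei$id == map$gt_id[i], ]
    expect_lt(sqrt((nc$centroid_um[1] - gt$x_um)^2 +
                   (nc$centroid_um[2] - gt$y_um)^2), 1.0)
  }
})
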