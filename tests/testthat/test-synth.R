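test_that("synth parameters are validated", {
  expect_error(synth_params(pattern_mix = c(normal = 0.5)), "sum to 1")
  expect_error(synth_params(pattern_mix = c(weird = 1)), "unknown pattern")
  expect_error(synth_params(n_nuclei = -1), ">= 0")
  expect_error(synth_params(nucleus_radii_um = c(4, 3)), "range")
})

test_that("a zero-nucleus case is background only, with empty ground truth", {
  case <- generate_case(synth_params(image_size = c(48, 48), n_nuclei = 0,
                                     seed = 1))
  expect_equal(nrow(case$truth$nuclei), 0)
  expect_equal(nrow(case$truth$spots), 0)
  bg <- round(0.05 * 65535) / 65535
  expect_true(all(case$stack$voxels == bg))
})

test_that("identical parameters give bit-identical stacks and truth", {
  p <- synth_params(image_size = c(96, 96), n_nuclei = 1, seed = 33)
  a <- generate_case(p); b <- generate_case(p)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$truth$spots, b$truth$spots)
  c <- generate_case(synth_params(image_size = c(96, 96), n_nuclei = 1,
                                  seed = 34))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("normal and typical-break patterns build the stated signal sets", {
  nrm <- generate_case(synth_params(n_nuclei = 1, seed = 5,
                                    pattern_mix = c(normal = 1)))
  expect_equal(sum(nrm$truth$spots$channel == "FITC"), 2)
  expect_equal(sum(nrm$truth$spots$channel == "TRITC"), 2)
  expect_equal(nrow(nrm$truth$pairs), 2)
  expect_true(all(nrm$truth$pairs$distance_um < 1.2))
  expect_true(all(nrm$truth$pairs$coloc))

  tb <- generate_case(synth_params(n_nuclei = 1, seed = 5,
                                   pattern_mix = c(typical_break = 1)))
  expect_equal(nrow(tb$truth$pairs), 2)
  expect_equal(sum(tb$truth$pairs$coloc), 1)
  # every split signal is at least 1.2 um from every opposite-channel spot
  sp <- tb$truth$spots
  f <- sp[sp$channel == "FITC", ]; t <- sp[sp$channel == "TRITC", ]
  d <- outer(seq_len(nrow(f)), seq_len(nrow(t)), Vectorize(function(i, j) {
    sqrt((f$x_um[i] - t$x_um[j])^2 + (f$y_um[i] - t$y_um[j])^2 +
         (f$z_um[i] - t$z_um[j])^2)
  }))
  expect_equal(sum(d < 1.2), 1)  # exactly the one fusion
})

test_that("place_pattern satisfies each pattern's classifier predicate", {
  set.seed(91)
  nucleus <- list(center_um = c(10, 10, 1.8), semi_um = c(4, 4, 1.6),
                  theta = 0)
  p <- synth_params()
  counts <- function(sp) {
    pr <- fish3d:::gt_pairs(cbind(nucleus_id = 1L, sp), cutoff = 1.2)
    C <- sum(pr$coloc)
    nb <- sum(!pr$coloc)
    G <- sum(sp$channel == "FITC") - C
    R <- sum(sp$channel == "TRITC") - C
    c(C = C, G = G, R = R)
  }
  for (rep in 1:10) {
    expect_equal(unname(counts(place_pattern("normal", nucleus, p))),
                 c(2, 0, 0))
    mc <- counts(place_pattern("multiple_copy", nucleus, p))
    expect_gte(mc["C"], 3); expect_equal(unname(mc["G"] + mc["R"]), 0)
    expect_equal(unname(counts(place_pattern("typical_break", nucleus, p))),
                 c(1, 1, 1))
    nt <- counts(place_pattern("nontypical_break", nucleus, p))
    expect_gte(nt["G"], 1); expect_gte(nt["R"], 1)
    expect_false(all(nt == c(1, 1, 1)))
    ot <- counts(place_pattern("other", nucleus, p))
    expect_equal(classify_nucleus(ot["C"], ot["G"], ot["R"]), "other")
  }
  # every spot lies inside the nucleus ellipsoid
  sp <- place_pattern("multiple_copy", nucleus, p)
  q <- mapply(function(x, y, z) {
    fish3d:::ellipsoid_q(x, y, z, nucleus$center_um, nucleus$semi_um,
                         nucleus$theta)
  }, sp$x_um, sp$y_um, sp$z_um)
  expect_true(all(q <= 1))
})

test_that("infeasible geometry raises errors", {
  p <- synth_params()
  tiny <- list(center_um = c(5, 5, 1.8), semi_um = c(0, 0, 1.6), theta = 0)
  expect_error(place_pattern("normal", tiny, p), "too small")
  expect_error(place_pattern("sideways", tiny, p), "unknown pattern")
  # too many nuclei for the field
  expect_error(
    generate_case(synth_params(image_size = c(96, 96), n_nuclei = 12,
                               max_attempts = 60, seed = 1)),
    "infeasible placement")
})

test_that("pattern frequencies follow the requested mix", {
  p <- synth_params(seed = 97)
  set.seed(97)
  lab <- sample_patterns(4000, p)
  tab <- table(factor(lab, names(p$pattern_mix)))
  chi <- suppressWarnings(
    chisq.test(tab, p = unname(p$pattern_mix)))
  expect_gt(chi$p.value, 1e-3)
})

test_that("ground truth serializes to JSON and back", {
  case <- generate_case(synth_params(image_size = c(96, 96), n_nuclei = 1,
                                     seed = 13))
  path <- file.path(tempdir(), "gt.json")
  write_ground_truth(case$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$spots$x_um, case$truth$spots$x_um)
  expect_equal(back$expected_diagnosis, case$truth$expected_diagnosis)
  expect_equal(nrow(back$pairs), nrow(case$truth$pairs))
})
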