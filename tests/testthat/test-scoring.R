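test_that("the pattern classifier reproduces the defining examples", {
  expect_equal(classify_nucleus(2, 0, 0), "normal")
  expect_equal(classify_nucleus(3, 0, 0), "multiple_copy")
  expect_equal(classify_nucleus(1, 1, 1), "typical_break")
  expect_equal(classify_nucleus(1, 2, 1), "nontypical_break")
  expect_equal(classify_nucleus(0, 1, 1), "nontypical_break")
  expect_equal(classify_nucleus(1, 2, 0), "other")
  expect_equal(classify_nucleus(1, 0, 0), "other")
  expect_equal(classify_nucleus(0, 0, 0), "discarded")
  expect_error(classify_nucleus(-1, 0, 0), ">= 0")
})

test_that("classification is a total function over the count grid", {
  grid <- expand.grid(C = 0:5, G = 0:5, R = 0:5)
  lab <- classify_nucleus(grid$C, grid$G, grid$R)
  expect_true(all(lab %in% c("normal", "multiple_copy", "typical_break",
                             "nontypical_break", "other", "discarded")))
  # each rule holds pointwise
  expect_true(all((lab == "normal") ==
                  (grid$C == 2 & grid$G == 0 & grid$R == 0)))
  expect_true(all((lab == "multiple_copy") ==
                  (grid$C > 2 & grid$G == 0 & grid$R == 0)))
  expect_true(all((lab == "typical_break") ==
                  (grid$C == 1 & grid$G == 1 & grid$R == 1)))
  expect_true(all((lab == "nontypical_break") ==
                  (grid$G >= 1 & grid$R >= 1 &
                   !(grid$C == 1 & grid$G == 1 & grid$R == 1))))
  expect_true(all((lab == "discarded") ==
                  (grid$C + grid$G + grid$R == 0)))
})

test_that("a break-called matched pair contributes one split signal per channel", {
  # one fusion plus one matched-but-distant pair is the classic one-allele
  # split: must classify typical_break
  scores <- nucleus_scores(n_coloc = 1, n_break_pairs = 1)
  rep <- score_case(scores, fish_config())
  expect_equal(rep$nuclei$pattern, "typical_break")
  expect_equal(rep$nuclei$G, 1)
  expect_equal(rep$nuclei$R, 1)
})

test_that("score_case applies the 10% diagnosis rule over counted nuclei", {
  cfg <- fish_config()
  all_normal <- nucleus_scores(n_coloc = rep(2, 100))
  expect_equal(score_case(all_normal, cfg)$diagnosis, "negative")

  ten <- nucleus_scores(n_coloc = c(rep(2, 90), rep(1, 10)),
                        n_break_pairs = c(rep(0, 90), rep(1, 10)))
  r10 <- score_case(ten, cfg)
  expect_equal(r10$breakapart_ratio, 10)
  expect_equal(r10$diagnosis, "negative")  # 10% or less is negative

  fifteen <- nucleus_scores(n_coloc = c(rep(2, 85), rep(1, 15)),
                            n_break_pairs = c(rep(0, 85), rep(1, 15)))
  expect_equal(score_case(fifteen, cfg)$diagnosis, "positive")
})

test_that("report counts are conserved and percentages sum to 100", {
  scores <- nucleus_scores(
    n_coloc = c(2, 2, 3, 1, 1, 0, 1),
    n_break_pairs = c(0, 0, 0, 1, 0, 0, 0),
    n_unpaired_fitc = c(0, 0, 0, 0, 2, 0, 0),
    n_unpaired_tritc = c(0, 0, 0, 0, 1, 0, 0))
  rep <- score_case(scores, fish_config())
  expect_equal(sum(rep$pattern_counts) + rep$discarded, nrow(scores))
  expect_equal(sum(rep$pattern_pct), 100, tolerance = 1e-9)
  expect_equal(rep$discarded, 1)  # the zero-signal nucleus
  expect_equal(rep$total_counted, 6)
})

test_that("the other pattern joins the abnormal fraction only on request", {
  scores <- nucleus_scores(
    n_coloc = c(rep(2, 80), rep(1, 20)),
    n_unpaired_fitc = c(rep(0, 80), rep(2, 20)))  # 20% "other"
  neg <- score_case(scores, fish_config())
  expect_equal(neg$diagnosis, "negative")
  pos <- score_case(scores, fish_config(abnormal_includes_other = TRUE))
  expect_equal(pos$diagnosis, "positive")
  expect_equal(pos$breakapart_ratio, neg$breakapart_ratio)  # unchanged
})

test_that("score_case refuses a case with no scoreable nuclei", {
  none <- nucleus_scores(n_coloc = c(0, 0))
  expect_error(score_case(none, fish_config()), "no scoreable nuclei")
})

test_that("remove_nucleus recomputes, is idempotent, rejects unknown ids", {
  scores <- nucleus_scores(
    n_coloc = c(rep(2, 10), 1),
    n_break_pairs = c(rep(0, 10), 1))
  rep <- score_case(scores, fish_config())
  expect_equal(rep$diagnosis, "negative")  # 1/11 = 9.1%
  expect_equal(round(rep$breakapart_ratio, 1), 9.1)

  rep2 <- remove_nucleus(rep, 11)
  expect_equal(rep2$breakapart_ratio, 0)
  expect_equal(rep2$diagnosis, "negative")
  expect_equal(rep2$total_counted, 10)
  expect_equal(rep2$discarded, 1)

  rep3 <- remove_nucleus(rep2, 11)
  expect_equal(rep3$nuclei, rep2$nuclei)
  expect_equal(rep3$diagnosis, rep2$diagnosis)

  expect_error(remove_nucleus(rep2, 99), "unknown nucleus_id")
})
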