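test_that("detection-limit capping replaces and flags exactly the censored entries", {
  ctm <- make_ct(matrix(c(36.2, 34.999, 35, 20, 30, 28), nrow = 3,
                        ncol = 2))
  capped <- cap_detection_limit(ctm)
  expect_equal(capped$ct[, 1], c(`miR-0001` = 35, `miR-0002` = 34.999,
                                 `miR-0003` = 35))
  expect_equal(unname(capped$censored[, 1]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(capped$censored[, 2]), c(FALSE, FALSE, FALSE))
  # all-censored column
  ctm2 <- make_ct(matrix(c(36, 37, 20, 21), nrow = 2, ncol = 2))
  capped2 <- cap_detection_limit(ctm2)
  expect_true(all(capped2$ct[, 1] == 35) && all(capped2$censored[, 1]))
})

test_that("mean-centered normalization uses the non-censored plate mean for all entries", {
  # plate raw (20, 30, 35-censored): mean of (20, 30) = 25 -> (5, -5, -10)
  ctm <- make_ct(matrix(c(20, 30, 35, 20, 30, 35), nrow = 3, ncol = 2))
  norm <- mean_center_normalize(cap_detection_limit(ctm))
  expect_equal(unname(norm$values[, 1]), c(5, -5, -10))
  expect_equal(unname(norm$plate_means), 25)
})

test_that("a single non-censored value normalizes to zero and a fully censored plate errors", {
  ctm <- make_ct(matrix(c(27, 36, 37, 38), nrow = 2, ncol = 2))
  norm <- mean_center_normalize(cap_detection_limit(ctm))
  expect_equal(unname(norm$values[1, 1]), 0)
  all_cens <- make_ct(matrix(36 + seq_len(4), nrow = 2, ncol = 2))
  expect_error(mean_center_normalize(cap_detection_limit(all_cens)),
               "fully censored")
})

test_that("per-plate non-censored mean of normalized values is zero for random censored matrices", {
  for (s in 1:25) {
    cfg <- ct_sim_config(n_mirnas = 40, baseline_mean_ct = 31,
                         baseline_sd_between_mirnas = 3, replicate_sd = 1,
                         treatments = data.frame(
                           name = c("a", "b"),
                           n_paired_replicates = c(3L, 2L)),
                         seed = s)
    norm <- mean_center_normalize(cap_detection_limit(gen_ct_matrix(cfg)))
    for (p in unique(norm$samples$plate)) {
      cols <- norm$samples$sample[norm$samples$plate == p]
      v <- norm$values[, cols]
      keep <- !norm$censored[, cols]
      expect_lt(abs(mean(v[keep])), 1e-9)
    }
  }
})

test_that("fold change follows the 2^delta convention and round-trips generator spikes", {
  # delta = +1 cycle-equivalent -> FC 2; delta = 0 -> FC 1
  ctm <- make_ct(matrix(c(24, 26, 25, 26), nrow = 2, ncol = 2))
  norm <- mean_center_normalize(cap_detection_limit(ctm))
  fc <- fold_change(norm, "t1")
  expect_equal(unname(fc), c(2, 1))
  # spiked -2 under zero noise -> FC exactly 0.25
  cfg <- ct_sim_config(n_mirnas = 8, baseline_sd_between_mirnas = 0,
                       replicate_sd = 0, plate_shift_sd = 0,
                       spikes = data.frame(mirna_index = 3L,
                                           treatment = "treatment",
                                           log2_effect = -2), seed = 1)
  norm2 <- mean_center_normalize(cap_detection_limit(gen_ct_matrix(cfg)))
  expect_equal(unname(fold_change(norm2, "treatment")[3]), 0.25)
})

test_that("paired t matches the closed-form t tail and handles degenerate rows", {
  # differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, df 2, p ~ 0.0742
  d <- c(1, 2, 3)
  control <- matrix(25, 1, 3)
  treated <- control - rbind(d)  # lower Ct = higher expression
  vals <- cbind(treated, control)
  ctm <- make_ct(vals)
  tt <- paired_t(mean_center_normalize(cap_detection_limit(ctm)), "t1")
  expect_equal(tt$t_stat, 2 * sqrt(3), tolerance = 1e-8)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 0.07417990, tolerance = 1e-6)

  # differences (-1, 0, 1) -> t = 0, p = 1
  vals2 <- cbind(matrix(25, 1, 3) - rbind(c(-1, 0, 1)), matrix(25, 1, 3))
  tt2 <- paired_t(mean_center_normalize(cap_detection_limit(make_ct(vals2))),
                  "t1")
  expect_equal(tt2$t_stat, 0)
  expect_equal(tt2$p, 1)

  # constant nonzero difference -> degenerate flag, smallest positive p
  vals3 <- cbind(matrix(24, 1, 3), matrix(25, 1, 3))
  tt3 <- paired_t(mean_center_normalize(cap_detection_limit(make_ct(vals3))),
                  "t1")
  expect_true(tt3$degenerate)
  expect_equal(tt3$p, .Machine$double.xmin)

  # a single pair is rejected
  vals4 <- cbind(matrix(24, 2, 1), matrix(25, 2, 1))
  expect_error(paired_t(mean_center_normalize(
    cap_detection_limit(make_ct(vals4))), "t1"), ">= 2 pairs")
})

test_that("BH step-up adjustment matches the hand-applied formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(4)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), NULL)
})

test_that("Storey q-values reduce to BH at pi0 = 1 and estimate pi0 near 1 under the null", {
  set.seed(7)
  p <- runif(200)
  expect_equal(storey_q(p, pi0 = 1), bh_adjust(p))
  expect_equal(storey_q(rep(1, 20)), rep(1, 20))
  pi0s <- vapply(1:20, function(s) {
    set.seed(s)
    p <- runif(1000)
    min(1, sum(p > 0.5) / (0.5 * 1000))
  }, numeric(1))
  expect_lt(abs(mean(pi0s) - 1), 0.05)
  # q monotone in p
  q <- storey_q(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("the joint significance filter applies the printed thresholds exactly", {
  rec <- data.frame(fold_change = c(1.5, 1.49, 0.5, 0.67, 2.0),
                    p = c(0.009, 0.0001, 0.02, 0.0099, 0.01))
  out <- select_significant(rec)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("annotation mapping classifies every name and excludes non-mapped ones", {
  mirnas <- sprintf("miR-%04d", 1:41)
  ann <- gen_mirna_annotation(mirnas, n_nonhuman = 2L)
  res <- map_annotations(mirnas, ann)
  expect_equal(length(res$retained), 39L)
  expect_equal(sum(res$map$status == "non-human"), 2L)
  # unknown name -> unmapped, excluded
  res2 <- map_annotations(c("miR-0001", "miR-9999"), ann)
  expect_equal(res2$map$status, c("mapped", "unmapped"))
  expect_equal(res2$retained, "miR-0001")
  expect_match(res2$map$reason[2], "absent")
  # all mapped -> unchanged
  res3 <- map_annotations(mirnas[1:10], ann)
  expect_equal(res3$retained, mirnas[1:10])
  # duplicate assay names are an error
  expect_error(map_annotations(mirnas, rbind(ann, ann[1, ])), "duplicate")
})
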