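# Pool where potency strictly decreases with id order, so the top-k set is
# the first k ids by construction.
ranked_pool <- function(n) {
  tibble::tibble(id = sprintf("r%05d", seq_len(n)),
                 potency = seq(10, 1, length.out = n))
}

test_that("top_k_count reproduces the benchmark pools' active-set sizes", {
  expect_identical(top_k_count(9997, 0.05), 500L)
  expect_identical(top_k_count(9997, 0.02), 200L)
  expect_identical(top_k_count(4535, 0.05), 227L)
  expect_identical(top_k_count(2502, 0.05), 125L)
  expect_identical(top_k_count(2502, 0.02), 50L)
  expect_identical(top_k_count(665, 0.05), 33L)
  expect_identical(top_k_count(665, 0.02), 13L)
  expect_identical(top_k_count(100, 0.05), 5L)
  # 0.02 * 4535 = 90.7 rounds up to 91 under half-up (a printed table that
  # mixes conventions cannot be matched cell-for-cell; ours is documented)
  expect_identical(top_k_count(4535, 0.02), 91L)
  expect_identical(top_k_count(10, 0.01), 1L) # never below 1
  expect_error(top_k_count(100, 1.2), "fraction")
})

test_that("top_k_spec picks the k most potent ids with stable tie-breaks", {
  pool <- ranked_pool(100)
  spec <- top_k_spec(pool, 0.05)
  expect_equal(spec$k, 5L)
  expect_identical(spec$active_ids, pool$id[1:5])
  # ties at the boundary resolve by ascending id
  tied <- tibble::tibble(id = c("b", "a", "c"), potency = c(1, 1, 1))
  expect_identical(top_k_spec(tied, 0.5)$active_ids, c("a", "b"))
})

test_that("recall and F1 match their confusion-count definitions", {
  pool <- ranked_pool(10000)
  spec <- top_k_spec(pool, 0.02) # k = 200
  expect_equal(spec$k, 200L)
  # acquired superset of the active set
  expect_equal(recall_topk(pool$id[1:300], spec), 1)
  # disjoint from the active set
  expect_equal(recall_topk(pool$id[300:400], spec), 0)
  # TP = 40 of k = 200
  acq <- c(pool$id[1:40], pool$id[1000:1319])
  expect_equal(recall_topk(acq, spec), 0.2)
  # F1 from N_acq = TP + FP and k = TP + FN: TP=50, N_acq=360 -> 100/560
  acq2 <- c(pool$id[1:50], pool$id[2000:2309])
  expect_equal(f1_topk(acq2, spec), 100 / 560)
  expect_equal(f1_topk(pool$id[1:200], spec), 1) # acquired = active set
  expect_equal(f1_topk(pool$id[5000:5100], spec), 0) # TP = 0
})

test_that("recall and F1 agree with a brute-force confusion matrix", {
  withr::with_seed(14, {
    for (rep in 1:15) {
      n <- sample(50:200, 1)
      pool <- tibble::tibble(id = sprintf("p%04d", sample(5000, n)),
                             potency = rnorm(n))
      r <- sample(c(0.02, 0.05, 0.1), 1)
      spec <- top_k_spec(pool, r)
      acq <- sample(pool$id, sample(1:n, 1))
      # brute force: label every compound, count the confusion cells
      active <- pool$id %in% spec$active_ids
      acquired <- pool$id %in% acq
      tp <- sum(active & acquired); fp <- sum(!active & acquired)
      fn <- sum(active & !acquired)
      expect_equal(tp + fp, length(acq))
      expect_equal(tp + fn, spec$k)
      expect_equal(recall_topk(acq, spec), tp / (tp + fn))
      expect_equal(f1_topk(acq, spec), 2 * tp / (2 * tp + fp + fn))
      # range and consistency bounds
      expect_gte(recall_topk(acq, spec), 0)
      expect_lte(recall_topk(acq, spec), 1)
      expect_lte(f1_topk(acq, spec),
                 recall_topk(acq, spec) * 2 * spec$k / (length(acq) + spec$k) + 1e-12)
    }
  })
})

test_that("random acquisition yields r * N_acq true positives in expectation", {
  expect_equal(random_baseline_tp(0.05, 0), 0)
  expect_equal(random_baseline_tp(0.05, 100), 5)
  expect_equal(random_baseline_tp(0.02, 360), 7.2)
  # simulation: mean TP over 1000 uniform draws is within 3 SE of r * N_acq
  pool <- ranked_pool(1000)
  spec <- top_k_spec(pool, 0.05)
  n_acq <- 80
  withr::with_seed(31, {
    tps <- vapply(1:1000, function(i) {
      sum(sample(pool$id, n_acq) %in% spec$active_ids)
    }, numeric(1))
  })
  se <- sd(tps) / sqrt(length(tps))
  expect_lt(abs(mean(tps) - random_baseline_tp(0.05, n_acq)), 3 * se)
})

test_that("regression metrics match direct formula evaluation", {
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$spearman_rho, 1)
  expect_equal(perfect$rmse, 0)

  obs <- c(1.1, 1.9, 3.2, 3.8)
  const <- regression_metrics(rep(mean(obs), 4), obs)
  expect_equal(const$r2, 0) # SS_res = SS_tot by definition
  expect_true(is.na(const$spearman_rho))

  m <- regression_metrics(c(1, 2, 3, 4), obs)
  expect_equal(m$r2, 1 - 0.10 / 4.50)
  expect_equal(m$spearman_rho, 1)
  expect_equal(m$rmse, sqrt(0.025))

  expect_warning(out <- regression_metrics(c(1, 2), c(3, 3)), "undefined")
  expect_true(is.na(out$r2))
  expect_equal(out$rmse, sqrt(mean(c(4, 1))))
  expect_error(regression_metrics(1, c(1, 2)), "equal length")
})
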