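# Beta/M-value computation, detection p-values, summaries, DMP calling.

test_that("beta formula and detection ranks behave as specified", {
  M <- matrix(c(0, 900, 50), 3, 1, dimnames = list(c("p1", "p2", "p3"), "s1"))
  U <- matrix(c(0, 0, 50), 3, 1, dimnames = dimnames(M))
  bm <- compute_beta(list(M = M, U = U))
  expect_equal(unname(bm$beta[, 1]), c(0, 0.9, 0.25))
  expect_null(bm$detection_p)

  # controls: totals 1:100 -> probe dimmer than all controls has p = 1,
  # brighter than all has the floor 1/(n+1)
  ctrl <- list(M = matrix(1:100, 100, 1), U = matrix(0, 100, 1))
  M2 <- matrix(c(0, 1e6), 2, 1, dimnames = list(c("lo", "hi"), "s1"))
  U2 <- matrix(0, 2, 1, dimnames = dimnames(M2))
  bm2 <- compute_beta(list(M = M2, U = U2), ctrl)
  expect_equal(unname(bm2$detection_p[, 1]), c(1, 1 / 101))
  # beta strictly below 1 and monotone in M holding U fixed
  expect_true(all(bm2$beta < 1))
  expect_error(compute_beta(list(M = -M2, U = U2)), class = "epicqc_format_error")
})

test_that("M-value transform is the capped logit2", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.999), log2(99))
  expect_equal(beta_to_m(0), log2(0.01 / 0.99))
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b)
})

test_that("distribution summaries are normalised histograms", {
  beta <- matrix(0.5, 100, 1, dimnames = list(paste0("p", 1:100), "s1"))
  d <- distribution_summary(beta, binwidth = 0.02)
  expect_equal(sum(d$density > 0), 1L)
  expect_equal(sum(d$density) * 0.02, 1)
  # bimodal truth shows two modes at the planted locations (+/- one bin)
  set.seed(1)
  v <- c(rnorm(600, 0.1, 0.02), rnorm(400, 0.85, 0.02))
  beta2 <- matrix(pmin(pmax(v, 0), 1), ncol = 1,
                  dimnames = list(paste0("p", seq_along(v)), "s1"))
  d2 <- distribution_summary(beta2)
  lo <- d2[d2$bin_mid < 0.5, ]
  hi <- d2[d2$bin_mid > 0.5, ]
  expect_lte(abs(lo$bin_mid[which.max(lo$density)] - 0.1), 0.03)
  expect_lte(abs(hi$bin_mid[which.max(hi$density)] - 0.85), 0.03)
  expect_equal(sum(d2$density) * 0.02, 1)
  expect_warning(distribution_summary(beta, probe_subsets = list(none = "zz")),
                 "empty")
})

test_that("platform correlation handles pairing and masking", {
  set.seed(2)
  b <- matrix(runif(600), 200, 3,
              dimnames = list(paste0("p", 1:200), c("s1", "s2", "s3")))
  ba <- make_beta_matrix(b)
  ident <- platform_correlation(ba, ba, data.frame(sample_a = "s1", sample_b = "s1"))
  expect_equal(unname(ident), 1)
  rev_b <- make_beta_matrix(matrix(rank(-b[, 1]) / 200, 200, 1,
                                   dimnames = list(rownames(b), "s1")))
  expect_equal(unname(platform_correlation(ba, rev_b,
                                           data.frame(sample_a = "s1", sample_b = "s1"))),
               -1)
  expect_error(platform_correlation(make_beta_matrix(b[1:2, , drop = FALSE]),
                                    ba, data.frame(sample_a = "s1", sample_b = "s1")),
               class = "epicqc_integrity_error")
})

test_that("DMP calling is exact on degenerate inputs and order-invariant", {
  set.seed(3)
  b <- matrix(runif(100 * 6, 0.2, 0.8), 100, 6,
              dimnames = list(paste0("p", 1:100), paste0("s", 1:6)))
  b[, 4:6] <- b[, 1:3]   # identical groups
  bm <- make_beta_matrix(b, groups = rep(c("a", "b"), each = 3))
  res <- call_dmps(bm, detection_threshold = NULL)
  expect_true(all(res$delta_beta == 0))
  expect_false(any(res$is_dmp))

  b2 <- matrix(runif(100 * 6, 0.2, 0.8), 100, 6,
               dimnames = list(paste0("p", 1:100), paste0("s", 1:6)))
  bm2 <- make_beta_matrix(b2, groups = rep(c("a", "b"), each = 3))
  res2 <- call_dmps(bm2, detection_threshold = NULL)
  perm <- c(2, 3, 1, 6, 4, 5)   # permute samples within groups
  bm3 <- make_beta_matrix(b2[, perm], groups = rep(c("a", "b"), each = 3))
  res3 <- call_dmps(bm3, detection_threshold = NULL)
  expect_equal(res3, res2)

  expect_error(call_dmps(make_beta_matrix(b2[, 1:3], groups = c("a", "a", "b")),
                         detection_threshold = NULL),
               class = "epicqc_integrity_error")
  expect_error(call_dmps(bm2), class = "epicqc_integrity_error")  # no detection p
})

test_that("zero prior df reduces the moderated t to the ordinary t", {
  set.seed(4)
  b <- matrix(runif(50 * 6, 0.2, 0.8), 50, 6,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:6)))
  bm <- make_beta_matrix(b, groups = rep(c("a", "b"), each = 3))
  res <- call_dmps(bm, detection_threshold = NULL, df_prior = 0)
  m <- beta_to_m(b)
  for (i in c(1, 17, 42)) {
    tt <- t.test(m[i, 4:6], m[i, 1:3], var.equal = TRUE)
    expect_equal(res$moderated_t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # fixed-prior posterior variance formula; infinite prior pins s2_post
  mv <- moderate_variances(c(1, 2, 4), df = 4, df_prior = 4, s2_prior = 2)
  expect_equal(mv$s2_post, (4 * 2 + 4 * c(1, 2, 4)) / 8)
  mv_inf <- moderate_variances(c(1, 2, 4), df = 4, df_prior = Inf, s2_prior = 3)
  expect_equal(mv_inf$s2_post, rep(3, 3))
})

test_that("DMP agreement counts are nested and monotone in the relaxed cutoff", {
  set.seed(5)
  b <- matrix(runif(300 * 6, 0.1, 0.9), 300, 6,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:6)))
  b[1:40, 4:6] <- pmin(b[1:40, 4:6] + 0.4, 0.99)
  bm <- make_beta_matrix(b, groups = rep(c("a", "b"), each = 3))
  res_a <- call_dmps(bm, detection_threshold = NULL)
  agree_self <- dmp_agreement(res_a, res_a)
  expect_equal(agree_self$n_confirmed_at_primary_threshold, agree_self$n_dmps_a)

  res_b <- res_a
  res_b$p_value <- pmin(res_a$p_value * 5, 1)   # inflated p-values
  res_b$is_dmp <- res_b$p_value < 0.001 & abs(res_b$delta_beta) > 0.1
  a1 <- dmp_agreement(res_a, res_b, relaxed_p = 0.01)
  a2 <- dmp_agreement(res_a, res_b, relaxed_p = 0.05)
  expect_gte(a1$n_confirmed_at_relaxed_threshold,
             a1$n_confirmed_at_primary_threshold)
  expect_gte(a2$n_confirmed_at_relaxed_threshold,
             a1$n_confirmed_at_relaxed_threshold)
  expect_true(a1$n_confirmed_at_primary_threshold <= a1$n_a_probes_on_b)
  expect_error(dmp_agreement(res_a, res_a[0, ]), class = "epicqc_integrity_error")
})

test_that("planted DMPs are recovered in the seeded world", {
  w <- world1()
  bm <- compute_beta(w$intensities)
  res <- call_dmps(bm)
  called <- res$probe_id[res$is_dmp]
  expect_setequal(called, w$ground_truth$true_dmp_ids)
})
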