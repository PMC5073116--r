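test_that("covariance matrix is the inverse Gram matrix", {
  expect_equal(crlb_covariance(diag(3)), diag(3), ignore_attr = TRUE)
  a <- dki_design_matrix(dki_protocol(c(0, 0.75, 2)), dki_params(d = 1, k = 1.5))
  q <- crlb_covariance(a)
  expect_equal(q, t(q))
  expect_equal(q %*% crossprod(a$a), diag(3), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("singular designs are rejected with the offending protocol named", {
  p <- dki_params(d = 1, k = 1.5)
  expect_error(dki_crlb(dki_protocol(c(0, 0, 0)), p), "singular design")
  err <- tryCatch(dki_crlb(dki_protocol(c(0, 2, 2)), p), error = identity)
  expect_match(conditionMessage(err), "singular design")
  expect_match(conditionMessage(err), "0, 2, 2")
  expect_error(crlb_covariance(matrix(1, 2, 3)), "at least 3 rows")
})

test_that("coefficients of variation normalise by the target values", {
  p <- dki_params(s0 = 2, d = 0.5, k = 0.3)
  cv <- crlb_covs(diag(c(4, 0.25, 0.09)), p)
  expect_equal(unname(cv$cov), c(1, 1, 1))
  expect_equal(cv$mse, 4.34)
  # k = 0 has no defined CoV: flagged as Inf, not an error
  cv0 <- crlb_covs(diag(c(1, 1, 1)), dki_params(d = 1, k = 0))
  expect_identical(cv0$cov[["k"]], Inf)
})

test_that("a reference optimized design reproduces its published errors", {
  res <- dki_crlb(dki_protocol(c(0, 0.75, 2), snr = 20), dki_params(d = 1, k = 1.5))
  expect_equal(res$cov[["s0"]], 0.05, tolerance = 0.02)
  expect_equal(res$cov[["d"]], 0.220, tolerance = 0.02)
  expect_equal(res$cov[["k"]], 0.145, tolerance = 0.02)
  expect_equal(res$mse, sum(diag(res$q)))
})

test_that("evaluation agrees with a finite-difference oracle design matrix", {
  p <- dki_params(s0 = 1.3, d = 0.86, k = 1.5)
  prot <- dki_protocol(c(0, 0.6, 1.1, 2), snr = 30)
  res <- dki_crlb(prot, p)
  a_fd <- fd_sensitivity(prot$b, p, sigma0 = p$s0 / prot$snr)
  q_fd <- solve(crossprod(a_fd))
  expect_equal(unname(res$q), q_fd, tolerance = 1e-5)
})

test_that("CoV scales exactly as 1/SNR and via rescale_cov", {
  p <- dki_params(d = 1, k = 1.5)
  r20 <- dki_crlb(dki_protocol(c(0, 0.75, 2), snr = 20), p)
  r30 <- dki_crlb(dki_protocol(c(0, 0.75, 2), snr = 30), p)
  expect_equal(r30$cov, r20$cov * 20 / 30)
  expect_equal(rescale_cov(r20, snr_to = 30)$cov, r30$cov)
  expect_equal(rescale_cov(r20, snr_to = 30)$q, r30$q)
})

test_that("echo-time rescaling multiplies by exp(te/t2)", {
  p <- dki_params(d = 1, k = 1.5, t2 = 80)
  r <- dki_crlb(dki_protocol(c(0, 0.75, 2)), p)
  expect_equal(rescale_cov(r, snr_to = 20, te = 0)$cov, r$cov)
  expect_equal(rescale_cov(r, snr_to = 20, te = 80)$cov, r$cov * exp(1))
  expect_equal(rescale_cov(r, snr_to = 20, te = 40, t2 = 80)$cov,
               r$cov * exp(0.5))
  expect_error(rescale_cov(dki_crlb(dki_protocol(c(0, 1, 2)),
                                    dki_params(d = 1, k = 1)),
                           snr_to = 20, te = 40), "'t2'")
})

test_that("errors depend on b and D only through bD (scale invariance)", {
  set.seed(7)
  for (i in 1:10) {
    d <- runif(1, 0.3, 3)
    k <- runif(1, 0.2, 2)
    bd <- sort(c(0, runif(3, 0.1, 3 / k)))
    b <- bd / (d * 1e-3)            # physical b realising these bD values
    c0 <- runif(1, 0.2, 5)
    r1 <- dki_crlb(dki_protocol(b, unit = "s_mm2"), dki_params(d = d, k = k))
    r2 <- dki_crlb(dki_protocol(b * c0, unit = "s_mm2"),
                   dki_params(d = d / c0, k = k))
    expect_equal(r1$cov, r2$cov, tolerance = 1e-9)
  }
})

test_that("adding an acquisition never inflates any parameter variance", {
  set.seed(21)
  p <- dki_params(d = 1, k = 1.2)
  for (i in 1:25) {
    b <- sort(runif(sample(3:6, 1), 0, 2.5))
    extra <- runif(1, 0, 2.5)
    q1 <- tryCatch(dki_crlb(dki_protocol(b), p)$q, error = function(e) NULL)
    if (is.null(q1)) next
    q2 <- dki_crlb(dki_protocol(c(b, extra)), p)$q
    expect_true(all(diag(q2) <= diag(q1) + 1e-12))
  }
})
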