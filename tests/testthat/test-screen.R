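test_that("mismatch assay enumeration is all ordered pairs", {
  m7 <- paste0("Pcdh", c(1, 7, 9, 10, 17, 19, "11x"))
  pairs <- enumerate_mismatch_pairs(m7)
  expect_equal(nrow(pairs), 42)
  expect_true(all(pairs$single != pairs$partner))
  expect_equal(nrow(enumerate_mismatch_pairs(c("a", "b"))), 2)
  expect_equal(nrow(enumerate_mismatch_pairs("a")), 0)
  expect_error(enumerate_mismatch_pairs(c("a", "a")), "duplicate")
  # count formula n(n-1) by brute force
  for (n in 2:10) {
    members <- paste0("m", seq_len(n))
    got <- enumerate_mismatch_pairs(members)
    brute <- sum(outer(members, members, "!="))
    expect_equal(nrow(got), brute)
    expect_equal(nrow(got), n * (n - 1))
    expect_false(anyDuplicated(paste(got$single, got$partner)) > 0)
  }
})

test_that("screen matrices reproduce planted means and structure", {
  eff <- c(P1 = 0.10, P7 = 0.04, P9 = -0.06, P17 = -0.08)
  scr <- make_screen_matrix(names(eff), effects = eff, base = 0.3,
                            noise_sd = 0, n_replicates = 2, seed = 1)
  M <- build_coag_matrix(scr$assays, members = names(eff))
  expect_equal(M$M, scr$truth$expected_mean)
  expect_true(all(is.na(diag(M$M))))
  expect_true(all(M$n_replicates[row(M$M) != col(M$M)] == 2))

  # symmetric effects give a symmetric matrix
  sym <- make_screen_matrix(c("x", "y", "z"), noise_sd = 0, seed = 2)
  Ms <- build_coag_matrix(sym$assays)$M
  expect_equal(Ms, t(Ms))

  # out-of-range values are refused
  bad <- scr$assays; bad$coag[1] <- 1.7
  expect_error(build_coag_matrix(bad), "\\[0, 1\\]")
})

test_that("matrix assembly is permutation-equivariant in member order", {
  scr <- make_screen_matrix(c("a", "b", "c", "d"),
                            effects = c(a = 0.05, b = 0, c = -0.02,
                                        d = 0.01),
                            noise_sd = 0.01, seed = 3)
  M1 <- build_coag_matrix(scr$assays, members = c("a", "b", "c", "d"))$M
  M2 <- build_coag_matrix(scr$assays, members = c("d", "b", "a", "c"))$M
  expect_equal(M2[rownames(M1), colnames(M1)], M1)
})

test_that("net mismatch scores are antisymmetric and recover hierarchies", {
  # symmetric screen: all scores exactly zero
  sym <- make_screen_matrix(c("x", "y", "z", "w"), noise_sd = 0, seed = 1)
  sc <- net_mismatch_score(build_coag_matrix(sym$assays))
  expect_true(all(sc$scores == 0))

  # planted hierarchy, noise-free: ranking equals the planted order and
  # scores sum to zero on the complete matrix
  eff <- c(Pcdh7 = 0.12, Pcdh17 = 0.06, Pcdh1 = 0.02, Pcdh10 = -0.03,
           Pcdh9 = -0.09)
  scr <- make_screen_matrix(names(eff), effects = eff, base = 0.3,
                            noise_sd = 0, seed = 4)
  ns <- net_mismatch_score(build_coag_matrix(scr$assays))
  expect_equal(names(ns$scores), scr$truth$ranking)
  expect_equal(sum(ns$scores), 0)

  # adding a constant to every entry leaves scores unchanged
  M <- build_coag_matrix(scr$assays)$M
  expect_equal(net_mismatch_score(M + 0.1)$scores, ns$scores)

  # gaps: pairwise-complete averaging, missing member flagged
  M2 <- M
  M2["Pcdh9", ] <- NA; M2[, "Pcdh9"] <- NA
  expect_warning(ns2 <- net_mismatch_score(M2), "Pcdh9")
  expect_true(is.na(ns2$scores["Pcdh9"]))
  expect_equal(length(ns2$undefined), 1)
})

test_that("CoAg regression matches hand-computed least squares", {
  fit <- regress_coag_vs_n(c(1, 2, 3), c(0.4, 0.3, 0.2))
  expect_equal(fit$slope, -0.1)
  expect_equal(fit$intercept, 0.5)
  expect_equal(fit$r_squared, 1)

  # exact line in general position
  fit2 <- regress_coag_vs_n(1:5, 0.1 + 0.05 * (1:5))
  expect_equal(fit2$r_squared, 1)

  # pure noise: no explanatory power
  set.seed(10)
  fit3 <- regress_coag_vs_n(rep(1:10, 40), runif(400))
  expect_lt(fit3$r_squared, 0.05)

  expect_error(regress_coag_vs_n(c(2, 2, 2), c(0.1, 0.2, 0.3)),
               "degenerate")
  expect_error(regress_coag_vs_n(1:2, c(0.1, 0.2)), "at least 3")
})

test_that("screen generator plants the structure it reports", {
  scr <- make_screen_matrix(paste0("m", 1:7), noise_sd = 0.02,
                            n_replicates = 3, seed = 6)
  expect_equal(nrow(scr$assays), 42 * 3)
  expect_true(all(scr$assays$coag >= 0 & scr$assays$coag <= 1))
  expect_identical(scr$assays,
                   make_screen_matrix(paste0("m", 1:7), noise_sd = 0.02,
                                      n_replicates = 3, seed = 6)$assays)
})
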