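test_that("Cohen's kappa: hand-checked table, perfect agreement, relabeling", {
  # 2x2 hand computation: p_o = 0.75, p_e = 0.5 -> kappa = 0.5
  k <- cohens_kappa(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(k$kappa, 0.5)
  expect_equal(k$p_o, 0.75)
  expect_equal(k$p_e, 0.5)
  expect_true(k$conf_low <= k$kappa && k$kappa <= k$conf_high)
  # perfect non-constant agreement
  expect_equal(cohens_kappa(c(0, 1, 2, 1), c(0, 1, 2, 1))$kappa, 1)
  # invariance under category relabeling
  g1 <- c(0, 1, 2, 2, 1, 0, 0, 2); g2 <- c(0, 1, 1, 2, 1, 0, 2, 2)
  relab <- c(5, 9, 7)
  expect_equal(cohens_kappa(g1, g2)$kappa,
               cohens_kappa(relab[g1 + 1], relab[g2 + 1])$kappa)
  # undefined when chance agreement is 1
  expect_true(cohens_kappa(rep(1, 5), rep(1, 5))$undefined)
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
})

test_that("kappa equals brute-force contingency computation on all small tables", {
  # enumerate all pairs of grade sequences with n <= 6 over 3 categories
  # (sampled exhaustively for n <= 3, randomly for larger n) and compare with
  # a from-scratch contingency-table computation
  brute_kappa <- function(g1, g2) {
    cats <- sort(unique(c(g1, g2)))
    n <- length(g1)
    po <- sum(g1 == g2) / n
    pe <- 0
    for (a in cats) pe <- pe + (sum(g1 == a) / n) * (sum(g2 == a) / n)
    if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  }
  for (n in 2:3) {
    grids <- expand.grid(rep(list(0:2), 2 * n))
    for (r in seq_len(nrow(grids))) {
      g1 <- as.integer(grids[r, 1:n]); g2 <- as.integer(grids[r, n + 1:n])
      expect_equal(cohens_kappa(g1, g2)$kappa, brute_kappa(g1, g2),
                   tolerance = 1e-12)
    }
  }
  withr::with_seed(1, for (i in 1:200) {
    n <- sample(4:6, 1)
    g1 <- sample(0:2, n, replace = TRUE); g2 <- sample(0:2, n, replace = TRUE)
    expect_equal(cohens_kappa(g1, g2)$kappa, brute_kappa(g1, g2),
                 tolerance = 1e-12)
  })
})

test_that("kappa of independent random gradings sits inside its CI of zero", {
  withr::with_seed(99, {
    g1 <- sample(0:3, 1e4, replace = TRUE)
    g2 <- sample(0:3, 1e4, replace = TRUE)
  })
  k <- cohens_kappa(g1, g2)
  expect_lt(abs(k$kappa), 3 * k$se)
})

test_that("grading accuracy identities", {
  expect_equal(grading_accuracy(1:10, 1:10), 1)
  g <- 1:10; g[3] <- 0
  expect_equal(grading_accuracy(g, 1:10), 0.9)
  # pooled accuracy over equal-sized readers equals the mean of per-reader
  withr::with_seed(4, {
    gt <- sample(0:2, 30, replace = TRUE)
    r1 <- ifelse(runif(30) < 0.2, (gt + 1) %% 3, gt)
    r2 <- ifelse(runif(30) < 0.4, (gt + 1) %% 3, gt)
  })
  pooled <- grading_accuracy(c(r1, r2), c(gt, gt))
  expect_equal(pooled, mean(c(grading_accuracy(r1, gt), grading_accuracy(r2, gt))))
  expect_error(grading_accuracy(1:3, 1:4), "equal length")
})

test_that("Wilcoxon signed-rank follows the zero-discard asymptotic convention", {
  a <- c(0.74, 0.43, 0.68, 0.77, 0.52, 0.73)
  b <- c(0.73, 0.35, 0.39, 0.77, 0.47, 0.67)
  w <- wilcoxon_signed_rank(a, b)
  expect_identical(w$n_used, 5L) # the zero difference is discarded
  expect_equal(w$statistic, 15)
  expect_equal(w$z, 7.5 / sqrt(13.75), tolerance = 1e-12)
  expect_equal(round(w$p_value, 3), 0.043)
  # the exact-enumeration oracle documents the convention difference
  we <- wilcoxon_signed_rank(a, b, method = "exact")
  expect_equal(we$p_value, 0.0625, tolerance = 1e-12)
  # antisymmetry: swapping negates z, p unchanged
  ws <- wilcoxon_signed_rank(b, a)
  expect_equal(ws$z, -w$z)
  expect_equal(ws$p_value, w$p_value)
  # all-zero differences flagged undefined
  expect_true(wilcoxon_signed_rank(c(1, 2), c(1, 2))$undefined)
})

test_that("Wilcoxon asymptotic p matches the reference implementation", {
  withr::with_seed(5, for (i in 1:25) {
    n <- sample(6:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    w <- wilcoxon_signed_rank(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                               exact = FALSE, correct = FALSE))
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("exact and asymptotic Wilcoxon agree on rejection decisions", {
  withr::with_seed(6, {
    agree <- vapply(1:100, function(i) {
      n <- sample(8:12, 1)
      a <- rnorm(n, mean = 0.3); b <- rnorm(n)
      pe <- wilcoxon_signed_rank(a, b, method = "exact")$p_value
      pa <- wilcoxon_signed_rank(a, b)$p_value
      (pe < 0.05) == (pa < 0.05)
    }, logical(1))
  })
  expect_gte(mean(agree), 0.95)
})

test_that("McNemar exact p equals binomial tail enumeration for b + c <= 12", {
  make_correct <- function(b, cc, both = 5) {
    list(a = c(rep(TRUE, both), rep(TRUE, b), rep(FALSE, cc)),
         b = c(rep(TRUE, both), rep(FALSE, b), rep(TRUE, cc)))
  }
  for (b in 0:12) for (cc in 0:(12 - b)) {
    v <- make_correct(b, cc)
    m <- mcnemar_test(v$a, v$b)
    if (b + cc == 0) {
      expect_equal(m$p_value, 1)
      expect_true(m$undefined)
    } else {
      nd <- b + cc
      enum <- min(1, sum(dbinom(0:min(b, cc), nd, 0.5)) * 2)
      expect_equal(m$p_value, enum, tolerance = 1e-12)
    }
  }
  # hand-derived case: b = 2, c = 8 -> 112/1024
  v <- make_correct(2, 8)
  expect_equal(mcnemar_test(v$a, v$b)$p_value, 112 / 1024, tolerance = 1e-12)
  # symmetric discordance: exact p = 1
  v <- make_correct(4, 4)
  expect_equal(mcnemar_test(v$a, v$b)$p_value, 1)
})

test_that("large-sample McNemar switches to the corrected chi-square", {
  a <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 20))
  b <- c(rep(FALSE, 40), rep(TRUE, 10), rep(TRUE, 20))
  m <- mcnemar_test(a, b)
  expect_identical(m$method, "chi-square")
  ref <- stats::mcnemar.test(table(a, b), correct = TRUE)
  expect_equal(m$p_value, ref$p.value, tolerance = 1e-12)
})
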