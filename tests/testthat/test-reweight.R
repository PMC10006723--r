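test_that("boost log reader handles canonical and tolerant dialects", {
  path <- withr::local_tempfile(fileext = ".log")
  writeLines(c("# frame dV_dihedral dV_total", "1 0.2 1.1", "2 0.0 0.0",
               "3 0.5 2.5"), path)
  b <- read_boost_log(path)
  expect_s3_class(b, "boost_series")
  expect_equal(b$dV_total, c(1.1, 0.0, 2.5))
  expect_equal(b$dV_dihedral, c(0.2, 0.0, 0.5))

  # amd dialect: banner lines skipped, last two numeric columns taken
  amd <- withr::local_tempfile(fileext = ".log")
  writeLines(c("Accelerated MD log", "ntwx = 1000",
               "1000 12 -5021.3 0.31 1.42", "2000 12 -5019.8 0.08 0.77"), amd)
  b2 <- read_boost_log(amd, dialect = "amd")
  expect_equal(b2$dV_total, c(1.42, 0.77))
  expect_equal(b2$dV_dihedral, c(0.31, 0.08))

  neg <- withr::local_tempfile(fileext = ".log")
  writeLines(c("1 0 -1"), neg)
  expect_error(read_boost_log(neg), "negative total boost")
  empty <- withr::local_tempfile(fileext = ".log")
  writeLines("# only comments", empty)
  expect_error(read_boost_log(empty), "no data lines")
})

test_that("zero boost gives uniform weights under either estimator", {
  b <- boost_series(rep(0, 7))
  for (meth in c("exponential", "maclaurin")) {
    w <- compute_weights(b, method = meth)
    expect_equal(w$w, rep(1 / 7, 7))
  }
})

test_that("reweighting estimators reproduce hand-computed two-frame weights", {
  kT <- 0.59616
  b <- boost_series(c(kT, 0))
  we <- compute_weights(b, method = "exponential", kT = kT)
  expect_equal(we$w, c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_equal(we$w, c(0.73106, 0.26894), tolerance = 1e-5)
  wm <- compute_weights(b, method = "maclaurin", k_order = 2, kT = kT)
  expect_equal(wm$w, c(2.5, 1) / 3.5, tolerance = 1e-12)
  expect_equal(wm$w, c(0.71429, 0.28571), tolerance = 1e-5)
  expect_equal(wm$method, "maclaurin-2")
})

test_that("weights are a probability vector even for extreme boosts", {
  # boosts of hundreds of kT would overflow a naive exponential
  b <- boost_series(c(0, 500, 1000, 250))
  w <- compute_weights(b, method = "exponential")
  expect_true(all(is.finite(w$w)))
  expect_true(all(w$w >= 0))
  expect_equal(sum(w$w), 1, tolerance = 1e-12)
  expect_error(compute_weights(b, k_order = 0), "k_order")
  expect_error(compute_weights(b, kT = 0), "kT")
})

test_that("weighted_histogram bins mass with the right-closed convention", {
  pts <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  g <- weighted_histogram(pts, bins = 2, d = 2)
  expect_equal(as.vector(g$P), rep(0.25, 4))
  g2 <- weighted_histogram(pts, weights = c(0.5, 0.5, 0, 0), bins = 2, d = 2)
  expect_equal(sort(as.vector(g2$P)), c(0, 0, 0.5, 0.5))
  # single frame: degenerate range still puts all mass in one bin
  g3 <- weighted_histogram(matrix(c(2, 3), 1, 2), bins = 2, d = 2)
  expect_equal(sum(g3$P), 1)
  expect_equal(max(g3$P), 1)
  expect_error(weighted_histogram(pts, bins = 1, d = 2), "at least 2 bins")
  expect_error(weighted_histogram(pts, weights = c(1, 1), d = 2),
               "frame counts")
})

test_that("fel_from_density applies mu = -kT ln P with min shift", {
  kT <- 0.59616
  g <- make_grid(c(0.75, 0.25))
  fel <- fel_from_density(g, kT = kT)
  expect_equal(as.vector(fel$mu), c(0, kT * log(3)))
  expect_equal(as.vector(fel$mu)[2L], 0.6549, tolerance = 1e-4)

  # uniform density: flat landscape at zero
  gu <- make_grid(rep(1 / 6, 6))
  expect_equal(as.vector(fel_from_density(gu, kT)$mu), rep(0, 6))

  # empty bins flagged NA in mu, filled above the occupied max for plotting
  gp <- make_grid(c(0.8, 0, 0.2))
  fp <- fel_from_density(gp, kT)
  expect_true(is.na(fp$mu[2L]))
  expect_equal(fp$mu_plot[2L], max(fp$mu, na.rm = TRUE) + kT)
  expect_error(fel_from_density(make_grid(c(0, 0))), "empty")
})

test_that("mu differences are invariant to rescaling the density", {
  set.seed(9)
  p <- runif(20); p <- p / sum(p)
  f1 <- fel_from_density(make_grid(p), kT = 0.59616)
  f2 <- fel_from_density(make_grid(p * 17), kT = 0.59616)  # unnormalised
  expect_equal(as.vector(f1$mu), as.vector(f2$mu), tolerance = 1e-12)
})

test_that("uniform weights reproduce the unweighted pipeline bin-for-bin", {
  set.seed(13)
  pcs <- matrix(rnorm(400), 200, 2)
  un <- weighted_histogram(pcs, bins = 10, d = 2)
  wt <- weighted_histogram(pcs, weights = rep(1 / 200, 200), bins = 10, d = 2)
  expect_equal(wt$P, un$P, tolerance = 1e-12)
  expect_equal(fel_from_density(wt)$mu, fel_from_density(un)$mu,
               tolerance = 1e-12)
})

test_that("exponential reweighting undoes a known two-state bias", {
  # biased sampler: states drawn iid from p_b, boost set so that
  # p_b(s) * exp(dV(s)/kT) is proportional to the target pi
  set.seed(31)
  kT <- kT_kcal()
  n <- 1e5
  p_b <- c(0.5, 0.5)
  pi_target <- c(0.8, 0.2)
  dV <- kT * log(pi_target / p_b)
  dV <- dV - min(dV)
  s <- sample.int(2L, n, replace = TRUE, prob = p_b)
  w <- compute_weights(boost_series(dV[s]), method = "exponential", kT = kT)
  rec <- c(sum(w$w[s == 1L]), sum(w$w[s == 2L]))
  se <- sqrt(pi_target * (1 - pi_target) / n)
  expect_true(all(abs(rec - pi_target) < 3 * se + 1e-12))
})
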