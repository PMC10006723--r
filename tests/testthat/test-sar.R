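test_that("fel_saddle finds the lowest connecting barrier on a 1-D grid", {
  kT <- 0.59616
  # two wells at mu = 0 and kT*ln 3, separated by a bin fixed at 2.0:
  # choose P so that -kT ln P gives exactly those levels after min-shift
  p <- c(1, exp(-2 / kT), 1 / 3)
  g <- make_grid(p / sum(p))
  fel <- fel_from_density(g, kT = kT)
  expect_equal(as.vector(fel$mu), c(0, 2, kT * log(3)), tolerance = 1e-10)
  expect_equal(fel_saddle(fel), 2, tolerance = 1e-10)
})

test_that("fel_saddle handles missing or disconnected second wells", {
  g1 <- make_grid(c(0.2, 0.6, 0.2))  # single well
  expect_true(is.na(fel_saddle(fel_from_density(g1))))
  # two wells separated by an empty (untraversable) bin
  g2 <- make_grid(c(0.6, 0, 0.4))
  expect_true(is.na(fel_saddle(fel_from_density(g2))))
})

test_that("fel_saddle takes the lowest of several connecting paths", {
  # 2-D landscape: two wells connected by a low pass (1.0) and a high
  # pass (3.0); the flood must report the low one
  kT <- 1
  # wells at mid-left (0) and mid-right (0.1); the top pass costs 1.0 and
  # the bottom pass 3.0, the centre and corners are effectively walls
  mu <- matrix(c(
    9.0, 1.0, 9.0,
    0.0, 99,  0.1,
    9.0, 3.0, 9.0), 3, 3, byrow = TRUE)
  P <- exp(-mu / kT)
  fel <- fel_from_density(make_grid(P / sum(P)), kT = kT)
  expect_equal(fel_saddle(fel), 1.0, tolerance = 1e-8)
})

test_that("folding_metrics summarises occupancy, entropy and saddle", {
  asg <- structure(list(cluster = rep(1:2, each = 5), counts = c(5L, 5L),
                        occupancy = c(50, 50), representative = c(1L, 6L),
                        peaks = NULL, total = 10L, d = 2L),
                   class = "fel_clusters")
  fm <- folding_metrics(asg, fel = NULL, name = "toy", group = "A")
  expect_equal(fm$entropy_bits, 1)
  expect_equal(fm$top1, 50); expect_equal(fm$top2, 50)
  expect_true(is.na(fm$top3))
  expect_true(is.na(fm$saddle))

  single <- asg
  single$cluster <- rep(1L, 10L); single$counts <- 10L
  single$occupancy <- 100; single$representative <- 1L
  fs <- folding_metrics(single, fel = NULL)
  expect_equal(fs$entropy_bits, 0)
  expect_equal(fs$top1, 100)
  expect_true(is.na(fs$saddle))
})

test_that("occupancy entropy is maximal iff clusters are equally occupied", {
  mk <- function(counts) {
    structure(list(cluster = rep(seq_along(counts), counts),
                   counts = counts,
                   occupancy = occupancy_percent(counts, sum(counts)),
                   representative = seq_along(counts), peaks = NULL,
                   total = sum(counts), d = 2L),
              class = "fel_clusters")
  }
  even <- folding_metrics(mk(c(25L, 25L, 25L, 25L)))
  expect_equal(even$entropy_bits, 2)  # log2(4)
  skew <- folding_metrics(mk(c(70L, 20L, 9L, 1L)))
  expect_lt(skew$entropy_bits, 2)
})

test_that("build_report aggregates by group and rejects duplicates", {
  mk <- function(name, group, k, top1) {
    data.frame(name = name, group = group, n_clusters = k, top1 = top1,
               top2 = top1 / 2, top3 = top1 / 4, entropy_bits = log2(k),
               saddle = NA_real_)
  }
  rep1 <- build_report(list(mk("p1", "A", 3L, 40), mk("p2", "B", 9L, 12),
                            mk("p3", "B", 7L, 15)))
  expect_s3_class(rep1, "sar_report")
  expect_equal(nrow(rep1$peptides), 3L)
  expect_equal(nrow(rep1$groups), 2L)
  gB <- rep1$groups[rep1$groups$group == "B", ]
  expect_equal(gB$n_clusters_mean, 8)
  expect_equal(gB$top1_min, 12)
  expect_error(build_report(list(mk("p1", "A", 3L, 40),
                                 mk("p1", "A", 3L, 40))), "duplicate")
  # annotations are pass-through
  ann <- data.frame(name = c("p1", "p2", "p3"), mic = c(0.156, 2.5, 1.25))
  rep2 <- build_report(list(mk("p1", "A", 3L, 40), mk("p2", "B", 9L, 12),
                            mk("p3", "B", 7L, 15)), annotations = ann)
  expect_equal(rep2$peptides$mic[rep2$peptides$name == "p1"], 0.156)
})

test_that("report occupancies equal assignment occupancies exactly", {
  set.seed(55)
  sp <- synthetic_spec(n_frames = 5000L)
  sim <- simulate_trajectory(sp, seed = 55L)
  f <- encode_sincos(sim$trajectory)
  pcs <- predict(dpca(f), f, d = 3)
  asg <- assign_frames(pcs, find_peaks(density_map(pcs, d = 3, bins = 24)))
  fm <- folding_metrics(asg, name = "sim", group = "A")
  expect_equal(fm$top1, max(asg$occupancy))
  rep1 <- build_report(list(fm))
  expect_identical(rep1$peptides$top1, fm$top1)
})

test_that("restricted vs dynamic generators rank as expected in the report", {
  # generator A: 3 well-separated states, low noise -> few clusters, high
  # top-1; generator B: 6 states, high noise -> more clusters, lower top-1
  run <- function(templates, noise_sd, seed) {
    sp <- synthetic_spec(n_frames = 20000L, templates = templates,
                         noise_sd = noise_sd)
    sim <- simulate_trajectory(sp, seed = seed)
    f <- encode_sincos(sim$trajectory)
    pcs <- predict(dpca(f), f, d = 3)
    assign_frames(pcs, find_peaks(density_map(pcs, d = 3, bins = 24)))
  }
  t3 <- list(h = state_template("helical"), e = state_template("extended"),
             p = state_template("hairpin"))
  mix <- function(a, b, w) w * state_template(a) + (1 - w) * state_template(b)
  t6 <- c(t3, list(m1 = mix("helical", "extended", 0.5),
                   m2 = mix("helical", "hairpin", 0.5),
                   m3 = mix("extended", "hairpin", 0.5)))
  asgA <- run(t3, noise_sd = 6, seed = 17L)
  asgB <- run(t6, noise_sd = 18, seed = 17L)
  repAB <- build_report(list(folding_metrics(asgA, name = "A-like", group = "A"),
                             folding_metrics(asgB, name = "B-like", group = "B")))
  pep <- repAB$peptides
  expect_lt(pep$n_clusters[pep$group == "A"], pep$n_clusters[pep$group == "B"])
  expect_gt(pep$top1[pep$group == "A"], pep$top1[pep$group == "B"])
})
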