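test_that("participant z-scores have mean 0, SD 1, and are affine invariant", {
  set.seed(21)
  tab <- data.frame(participant = rep(1:5, each = 20),
                    raw = rnorm(100, 50, 12))
  z <- zscore_by_participant(tab)
  for (p in 1:5) {
    expect_lt(abs(mean(z$z[z$participant == p])), 1e-12)
    expect_lt(abs(sd(z$z[z$participant == p]) - 1), 1e-12)
  }
  # rank order preserved
  expect_identical(order(z$raw[z$participant == 1]),
                   order(z$z[z$participant == 1]))
  # affine transform of one participant's scale leaves z unchanged
  tab2 <- tab; tab2$raw[tab2$participant == 2] <-
    3.7 * tab2$raw[tab2$participant == 2] + 11
  z2 <- zscore_by_participant(tab2)
  expect_equal(z2$z, z$z, tolerance = 1e-12)
  # documented convention: (2, 4, 6) with sample SD
  z3 <- zscore_by_participant(data.frame(participant = 1, raw = c(2, 4, 6)))
  expect_equal(z3$z, c(-1, 0, 1))
  z3p <- zscore_by_participant(data.frame(participant = 1, raw = c(2, 4, 6)),
                               sd_convention = "population")
  expect_equal(z3p$z, c(-1, 0, 1) * sqrt(3 / 2))
  expect_error(zscore_by_participant(data.frame(participant = 1,
                                                raw = c(5, 5, 5))),
               "zero rating variance")
})

test_that("CoM judgments convert to complementary half ratings", {
  expect_equal(unname(com_to_half_ratings(5)), cbind(5, 5)[1, , drop = FALSE],
               ignore_attr = TRUE)
  r <- com_to_half_ratings(6.2)
  expect_equal(unname(r[, "half2"]), 6.2)  # CoM in half 2 -> larger rating
  expect_equal(unname(r[, "half1"]), 3.8)
  expect_true(r[, "half2"] > r[, "half1"])
  b <- com_to_half_ratings(0)
  expect_equal(as.numeric(b), c(10, 0))
  # pairs always sum to L
  x <- seq(0, 10, by = 0.25)
  expect_true(all(rowSums(com_to_half_ratings(x)) == 10))
  expect_error(com_to_half_ratings(10.5), "outside")
})

test_that("illusion index signs and antisymmetry behave correctly", {
  tab <- data.frame(
    participant = rep(1:4, each = 8),
    phase = rep(rep(c("pre", "post"), each = 4), 4),
    material = rep(c("granite", "granite", "styrofoam", "styrofoam"), 8),
    z = 0)
  # identical means -> zero index
  idx0 <- illusion_index(tab, "granite", "styrofoam")
  expect_true(all(idx0$pre == 0 & idx0$post == 0))
  # contrast regime: heavy-looking rated lower post-lift -> negative
  tab$z[tab$phase == "post" & tab$material == "granite"] <- -0.5
  tab$z[tab$phase == "post" & tab$material == "styrofoam"] <- 0.5
  idx <- illusion_index(tab, "granite", "styrofoam")
  expect_true(all(idx$post == -1))
  # antisymmetric under swapping the labels
  rev_idx <- illusion_index(tab, "styrofoam", "granite")
  expect_equal(rev_idx$post, -idx$post)
  expect_equal(rev_idx$pre, -idx$pre)
  expect_error(illusion_index(tab, "granite", "oak"), "lacks")
})

test_that("simulated integration observer yields a positive post index", {
  obs <- synthetic_observer(w = 0.3, rating_noise_sd = 0.02)
  obj <- object_spec(0.2, 0.2, appearance = c("styrofoam", "granite"),
                     id = "sg")
  rows <- list()
  for (p in 1:12) {
    rows[[length(rows) + 1L]] <- simulate_ratings(obs, obj, "pre", 1,
                                                  seed = p, participant = p)
    rows[[length(rows) + 1L]] <- simulate_ratings(obs, obj, "post", 10,
                                                  seed = p, participant = p)
  }
  tab <- zscore_by_participant(do.call(rbind, rows))
  idx <- illusion_index(tab, "granite", "styrofoam")
  expect_gt(mean(idx$post), 0)
  expect_gt(mean(idx$pre), mean(idx$post))  # expectation exceeds percept
})

test_that("repeated-measures ANOVA matches the from-scratch SS oracle", {
  set.seed(31)
  # one-way, 3 levels
  d1 <- expand.grid(participant = 1:12, A = c("a1", "a2", "a3"))
  d1$y <- rnorm(36) + 0.4 * (d1$A == "a2")
  r1 <- rm_or_mixed_anova(d1, "y", within = "A")
  Y <- matrix(d1$y[order(d1$A, d1$participant)], 12, 3)
  o1 <- oracle_rm_oneway(Y)
  expect_equal(r1$F[r1$effect == "A"], o1$F, tolerance = 1e-8)
  expect_equal(r1$df1[r1$effect == "A"], o1$df1)
  expect_equal(r1$df2[r1$effect == "A"], o1$df2)

  # two within factors, 3 x 2
  d2 <- expand.grid(participant = 1:10, A = c("a1", "a2", "a3"),
                    B = c("pre", "post"))
  d2$y <- rnorm(60) + 0.5 * (d2$A == "a3") * (d2$B == "post")
  r2 <- rm_or_mixed_anova(d2, "y", within = c("A", "B"))
  o2 <- oracle_rm_twoway(d2)
  for (eff in c("A", "B")) {
    expect_equal(r2$F[r2$effect == eff], o2[[eff]]$F, tolerance = 1e-8)
    expect_equal(r2$df1[r2$effect == eff], o2[[eff]]$df1)
    expect_equal(r2$df2[r2$effect == eff], o2[[eff]]$df2)
  }
  iab <- grepl("A", r2$effect) & grepl("B", r2$effect)
  expect_equal(r2$F[iab], o2$AB$F, tolerance = 1e-8)
  expect_equal(r2$df1[iab], o2$AB$df1)
})

test_that("Greenhouse-Geisser machinery respects its bounds and the 2-level case", {
  set.seed(32)
  d <- expand.grid(participant = 1:10, A = c("a1", "a2", "a3"),
                   B = c("b1", "b2"))
  d$y <- rnorm(60)
  r <- rm_or_mixed_anova(d, "y", within = c("A", "B"), sphericity = "always")
  eA <- r$epsilon[r$effect == "A"]
  expect_gte(eA, 1 / 2); expect_lte(eA, 1)     # k = 3: eps in [1/(k-1), 1]
  # 2-level factor: eps = 1, correction changes nothing
  expect_identical(r$epsilon[r$effect == "B"], 1)
  expect_equal(r$p_gg[r$effect == "B"], r$p[r$effect == "B"])
  rn <- rm_or_mixed_anova(d, "y", within = c("A", "B"), sphericity = "never")
  expect_false(any(rn$corrected))
  expect_equal(rn$p_rep, pmax(rn$p, 1e-16))
})

test_that("mixed design with a between factor runs and is invariant to z-scoring", {
  set.seed(33)
  d <- expand.grid(participant = 1:12, material = c("sty", "oak", "gra"),
                   lift = c("pre", "post"))
  d$task <- ifelse(d$participant <= 6, "numeric", "com")
  d$y <- rnorm(72) + 0.6 * (d$material == "gra")
  r <- rm_or_mixed_anova(d, "y", within = c("material", "lift"),
                         between = "task")
  expect_true(all(c("task", "material", "lift") %in% r$effect))
  expect_true(all(r$p >= 0 & r$p <= 1))
  # per-participant affine transforms wash out after z-scoring
  d2 <- d
  names(d2)[names(d2) == "y"] <- "raw"
  z1 <- zscore_by_participant(d2)
  d3 <- d2
  for (p in unique(d3$participant)) {
    i <- d3$participant == p
    d3$raw[i] <- d3$raw[i] * (1 + p / 5) + 10 * p
  }
  z2 <- zscore_by_participant(d3)
  r1 <- rm_or_mixed_anova(z1, "z", within = c("material", "lift"),
                          between = "task")
  r2 <- rm_or_mixed_anova(z2, "z", within = c("material", "lift"),
                          between = "task")
  # within-subject effects are exactly invariant; the pure between effect
  # is identically null after z-scoring (F ~ 0) in both runs
  w <- r1$effect != "task"
  expect_equal(r1$F[w], r2$F[w], tolerance = 1e-8)
  expect_equal(r1$p[w], r2$p[w], tolerance = 1e-8)
  expect_lt(max(r1$F[!w], r2$F[!w]), 1e-8)
})

test_that("t-test wrapper matches direct formulas and flags degeneracy", {
  # symmetric about zero -> t = 0, p = 1
  r0 <- t_tests(c(-2, -1, 1, 2), kind = "one-sample")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # textbook paired case against the hand formula
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  rp <- t_tests(x, y, kind = "paired")
  dd <- x - y
  expect_equal(rp$statistic, mean(dd) / (sd(dd) / sqrt(4)), tolerance = 1e-10)
  # direct one-sample formula
  v <- c(0.3, 1.2, -0.4, 0.8, 0.1)
  r1 <- t_tests(v, kind = "one-sample")
  expect_equal(r1$statistic, mean(v) / (sd(v) / sqrt(5)), tolerance = 1e-10)
  # Welch df bounds
  set.seed(41)
  for (k in 1:20) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    rw <- t_tests(rnorm(n1), rnorm(n2, 0, runif(1, 0.3, 3)), kind = "welch")
    expect_gte(rw$df, min(n1, n2) - 1)
    expect_lte(rw$df, n1 + n2 - 2)
  }
  # zero-variance one-sample: infinite statistic flag, not an error
  rz <- t_tests(rep(2, 5), kind = "one-sample")
  expect_true(rz$infinite)
  expect_identical(rz$statistic, Inf)
  expect_error(t_tests(1), "n >= 2")
})

test_that("Bonferroni adjustment reproduces the worked examples", {
  expect_equal(bonferroni(0.05, 3), 0.0167)
  expect_equal(bonferroni(0.05, 6), 0.0083)
  expect_equal(bonferroni(0.05, 2), 0.025)
  expect_error(bonferroni(0.05), "comparisons")
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  for (cs in list(c(0, 24), c(0.15, 24), c(1.2, 10), c(2.5, 24),
                  c(3.69, 48), c(-2, 15))) {
    a <- bf01_one_sample(cs[1], cs[2])
    b <- oracle_bf01(cs[1], cs[2])
    expect_lt(abs(a / b - 1), 1e-6)
  }
  # null-favoring at t = 0
  expect_gt(bf01_one_sample(0, 24), 1)
  # strictly decreasing in |t| at fixed n
  ts <- seq(0, 5, by = 0.25)
  bfs <- vapply(ts, bf01_one_sample, 0, n = 24)
  expect_true(all(diff(bfs) < 0))
  # alternative prior scale still matches the oracle
  expect_lt(abs(bf01_one_sample(1.5, 20, r = 1) / oracle_bf01(1.5, 20, 1) - 1),
            1e-6)
  expect_error(bf01_one_sample(Inf, 10), "finite")
})
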