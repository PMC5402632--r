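make_map <- function(d, comps, vs = 0.082) {
  a <- array(0L, d)
  for (i in seq_along(comps)) a[comps[[i]]] <- i
  label_map(a, vs)
}

test_that("identical label maps match completely, disjoint maps not at all", {
  d <- c(12L, 12L, 12L)
  c1 <- 1:30; c2 <- 301:330
  m <- make_map(d, list(c1, c2))
  self <- match_interruptions(m, m, 20L)
  expect_equal(self$n_match, 2L)
  expect_equal(self$n_a, 2L)
  expect_equal(sort(self$pairs$overlap_voxels), c(30L, 30L))
  other <- make_map(d, list(601:630, 901:930))
  none <- match_interruptions(m, other, 20L)
  expect_equal(none$n_match, 0L)
})

test_that("multi-overlap resolves greedily to the largest overlap, one-to-one", {
  d <- c(12L, 12L, 12L)
  # one A component overlapping two B components by 30 and 25 voxels
  a <- make_map(d, list(1:60))
  b <- make_map(d, list(1:30, 36:60))
  m <- match_interruptions(a, b, 20L)
  expect_equal(m$n_match, 1L)
  expect_equal(m$pairs$label_b, 1L)
  expect_equal(m$pairs$overlap_voxels, 30L)
  # exhaustive-assignment check: greedy attains the maximum matched pairs here
  expect_lte(m$n_match, min(m$n_a, m$n_b))
  # symmetry of the match count
  expect_equal(match_interruptions(b, a, 20L)$n_match, m$n_match)
  # below-threshold overlaps never match
  small <- match_interruptions(a, b, 31L)
  expect_equal(small$n_match, 0L)
  # lattice mismatch is a validation error
  expect_error(match_interruptions(a, make_map(c(6L, 6L, 6L), list(1:25))),
               class = "cb_validation_error")
})

test_that("greedy matching attains the exhaustive optimum on random small maps", {
  set.seed(61)
  d <- c(10L, 10L, 10L)
  for (rep in 1:10) {
    n_a <- sample(2:3, 1); n_b <- sample(2:3, 1)
    blocks <- split(sample(1000, 1000), rep(1:10, each = 100))
    a <- make_map(d, blocks[seq_len(n_a)])
    b_blocks <- lapply(seq_len(n_b), function(i)
      unlist(lapply(blocks, function(bl) sample(bl, 40)))[sample(40 * 10, 120)])
    b <- make_map(d, b_blocks)
    m <- match_interruptions(a, b, 20L)
    # exhaustive search over one-to-one assignments maximizing pairs then overlap
    ov <- matrix(0L, n_a, n_b)
    for (i in seq_len(n_a)) for (j in seq_len(n_b))
      ov[i, j] <- sum(a$data == i & b$data == j)
    best <- 0L
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (p in perms(seq_len(n_b))) {
      cnt <- 0L
      for (i in seq_len(min(n_a, n_b)))
        if (ov[i, p[i]] >= 20L) cnt <- cnt + 1L
      best <- max(best, cnt)
    }
    expect_equal(m$n_match, best)
  }
})

test_that("the agreement equations evaluate to their closed-form values", {
  expect_equal(proportion_matching(10, 10, 10), 100)
  expect_equal(proportion_matching(10, 10, 8), 8 / 12 * 100)
  expect_equal(proportion_matching(5, 3, 0), 0)
  expect_equal(proportion_matching(3, 5, 2), proportion_matching(5, 3, 2))
  expect_error(proportion_matching(0, 0, 0), class = "cb_validation_error")

  expect_equal(positive_predictive_value(3, 10), 30)
  expect_equal(positive_predictive_value(7, 7), 100)
  expect_equal(positive_predictive_value(0, 5), 0)
  expect_error(positive_predictive_value(1, 0), class = "cb_validation_error")

  expect_equal(sensitivity(0, 4), 0)
  expect_equal(sensitivity(4, 4), 100)
  expect_equal(sensitivity(3, 4), 75)
  expect_error(sensitivity(1, 0), class = "cb_validation_error")
  # PPV equals sensitivity when both procedures found equally many
  expect_equal(positive_predictive_value(5, 9), sensitivity(5, 9))
})

test_that("ICC(2,1) reproduces reference values, aov mean squares and the identity case", {
  # identical raters
  ident <- icc_two_way_random_absolute(cbind(c(2, 7, 11, 5), c(2, 7, 11, 5)))
  expect_equal(ident$icc, 1)
  # frozen references from an established absolute-agreement ICC implementation
  t1 <- matrix(c(15, 13, 6, 5, 49, 51, 14, 14, 22, 19, 9, 8, 30, 28, 12, 14,
                 41, 45, 18, 16), ncol = 2, byrow = TRUE)
  r1 <- icc_two_way_random_absolute(t1)
  expect_equal(r1$icc, 0.9892713115377788, tolerance = 1e-10)
  expect_equal(round(r1$ci95, 2), c(0.96, 1.00))
  t2 <- matrix(c(1, 2, 3, 3, 4, 5, 5, 6, 4, 7, 8, 9, 2, 1, 3, 9, 9, 8),
               ncol = 3, byrow = TRUE)
  r2 <- icc_two_way_random_absolute(t2)
  expect_equal(r2$icc, 0.8999999999999998, tolerance = 1e-10)
  expect_equal(round(r2$ci95, 2), c(0.67, 0.98))
  # constant-offset table: closed form from the mean squares
  t3 <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2, byrow = TRUE)
  expect_equal(icc_two_way_random_absolute(t3)$icc, 8 / 9, tolerance = 1e-12)
  # mean squares agree with stats::aov
  df <- data.frame(y = as.vector(t2), subj = factor(rep(1:6, 3)),
                   rater = factor(rep(1:3, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  expect_equal(unname(unlist(r2$ms)), ms, tolerance = 1e-10)
  # degenerate inputs
  expect_error(icc_two_way_random_absolute(matrix(1, 3, 2)),
               class = "cb_validation_error")
  expect_error(icc_two_way_random_absolute(matrix(1:2, 1, 2)),
               class = "cb_validation_error")
})

test_that("ICC recovers the simulated variance decomposition at n = 1000", {
  set.seed(62)
  n <- 1000L; k <- 2L
  s_subj <- 4; s_rater <- 0.25; s_err <- 1
  subj <- rnorm(n, sd = sqrt(s_subj))
  rater <- rnorm(k, sd = sqrt(s_rater))
  x <- outer(subj, rep(1, k)) + outer(rep(1, n), rater) +
    matrix(rnorm(n * k, sd = sqrt(s_err)), n, k)
  est <- icc_two_way_random_absolute(x)
  theo <- s_subj / (s_subj + s_rater + s_err)
  expect_lt(abs(est$icc - theo), 0.05)
  expect_true(est$ci95[1] < est$icc && est$icc < est$ci95[2])
  expect_lt(est$ci95[2] - est$ci95[1], 0.25)
  # one rater constant, the other random: near-zero ICC
  y <- cbind(rep(5, n), rnorm(n))
  expect_lt(abs(icc_two_way_random_absolute(y)$icc), 0.08)
})
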