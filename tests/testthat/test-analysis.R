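test_that("group variances match a brute-force double loop on random data", {
  set.seed(3)
  M <- matrix(rnorm(200 * 5), 200, 5)
  lab <- sample(letters[1:8], 200, replace = TRUE)
  gv <- group_variances(M, lab)
  # independent naive evaluation
  grand <- colMeans(M)
  vw <- 0; vb <- 0
  for (g in unique(lab)) {
    rows <- which(lab == g)
    mi <- colMeans(M[rows, , drop = FALSE])
    for (j in rows) vw <- vw + sum((M[j, ] - mi)^2)
    vb <- vb + length(rows) * sum((mi - grand)^2)
  }
  expect_equal(gv$var_within, vw, tolerance = 1e-10)
  expect_equal(gv$var_between, vb, tolerance = 1e-10)
  expect_equal(gv$beta, vb / (vw + vb), tolerance = 1e-12)
})

test_that("sum-of-squares identity and beta bounds hold for arbitrary data", {
  set.seed(8)
  for (rep in 1:5) {
    M <- matrix(rnorm(60 * 3), 60, 3)
    lab <- sample(1:6, 60, replace = TRUE)
    gv <- group_variances(M, lab)
    ss_total <- sum(sweep(M, 2, colMeans(M))^2)
    expect_equal(gv$var_within + gv$var_between, ss_total,
                 tolerance = 1e-9)
    expect_gte(gv$beta, 0); expect_lte(gv$beta, 1)
    # translation invariance
    gv2 <- group_variances(sweep(M, 2, c(5, -3, 100), "+"), lab)
    expect_equal(gv2$beta, gv$beta, tolerance = 1e-9)
  }
})

test_that("perfect separation and single-group edge cases", {
  M <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  gv <- group_variances(M, c("a", "a", "b", "b"))
  expect_equal(gv$var_within, 0)
  expect_equal(gv$beta, 1)
  gv1 <- group_variances(matrix(rnorm(10), 5, 2), rep("a", 5))
  expect_equal(gv1$var_between, 0, tolerance = 1e-12)
  expect_equal(gv1$beta, 0, tolerance = 1e-12)
  expect_error(group_variances(matrix(1, 4, 2), c(1, 1, 2, 2)),
               "degenerate")
})

test_that("F test reproduces the critical-value table and the F ratio", {
  # the 15-single-wall-world analysis: N = 15 groups of 14 -> df (14, 195)
  rep <- list(var_between = 28, var_within = 390,
              n_groups = 15L, n_messages = 210L)
  ft <- f_test(rep, 0.05)
  expect_identical(ft$df1, 14L)
  expect_identical(ft$df2, 195L)
  expect_equal(ft$f_value, (28 / 14) / (390 / 195))   # = 1.0
  expect_equal(round(ft$f_crit, 2), 1.74)
  for (p in c(0.1, 0.01, 0.005, 0.001)) {
    fc <- f_test(rep, p)$f_crit
    expect_equal(round(fc, 2),
                 round(stats::qf(1 - p, 14, 195), 2))
  }
  # degenerate within-variance: infinite F flagged significant
  ft0 <- f_test(list(var_between = 5, var_within = 0, n_groups = 3L,
                     n_messages = 30L))
  expect_true(is.infinite(ft0$f_value) && ft0$significant && ft0$degenerate)
})

test_that("F test type-I error calibrates to the nominal level", {
  # exact for one-dimensional data, where the summed-over-dimensions
  # variance forms reduce to the classical one-way ANOVA
  set.seed(77)
  reps <- 400L
  rejections <- 0L
  for (r in seq_len(reps)) {
    M <- matrix(rnorm(60), 60, 1)              # null: all groups same mean
    lab <- rep(1:6, each = 10)
    ft <- f_test(group_variances(M, lab), 0.05)
    rejections <- rejections + ft$significant
  }
  rate <- rejections / reps
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("task distances follow the weighted displacement form", {
  w <- grid_world(4)
  cfg <- toposim_config()
  t1 <- maze_task(w, c(0, 3)); t2 <- maze_task(w, c(2, 3))
  expect_equal(task_distance(t1, t1, cfg), 0)
  expect_equal(task_distance(t1, t2, cfg), 2)
  w1 <- maze_task(grid_world(4, walls = rbind(c(1, 1))), c(3, 3))
  w2 <- maze_task(grid_world(4, walls = rbind(c(2, 1))), c(3, 3))
  expect_equal(task_distance(w1, w2, cfg), 1)
  # no-wall vs one-wall uses the virtual absent-wall position (-1, -1)
  t0 <- maze_task(w, c(3, 3))
  expect_equal(task_distance(t0, w1, cfg), sqrt(sum((c(1, 1) - c(-1, -1))^2)))
  # weights scale the displacement
  cfg2 <- toposim_config(goal_weight = 2 * diag(2))
  expect_equal(task_distance(t1, t2, cfg2), 4)
})

test_that("topographic similarity slope recovers known mappings", {
  m <- matrix(seq(0, 1, length.out = 10))
  expect_equal(topographic_similarity(m, m)$slope, 1, tolerance = 1e-9)
  const <- matrix(1, 10, 2) + 1e-9 * matrix(rnorm(20), 10, 2)
  expect_equal(topographic_similarity(const, m)$slope, 0, tolerance = 1e-6)
  expect_error(topographic_similarity(m, matrix(1, 10, 1)), "variance")
  # Q-matrix meanings use the Frobenius norm
  qs <- lapply(1:5, function(i) array(i, c(2, 2, 4)))
  msgs <- matrix(1:5)
  ts <- topographic_similarity(msgs, qs)
  expect_equal(ts$meaning_dist, 4 * as.vector(dist(1:5)))
})

test_that("binned entropy behaves like a plug-in Shannon estimator", {
  # all samples identical: 0 bits
  same <- matrix(1, 10, 3)
  expect_equal(binned_entropy(same, 5), 0)
  # 25 equally occupied bins: log2(25) bits; build a 5x5 lattice in 2-D
  g <- as.matrix(expand.grid(seq(-1, 1, length.out = 5),
                             seq(-1, 1, length.out = 5)))
  expect_equal(binned_entropy(g, 5), log2(25), tolerance = 1e-9)
  # entropy bounded by sample count and bin count
  set.seed(4)
  X <- matrix(rnorm(40 * 4), 40, 4)
  for (b in c(2, 6, 15)) {
    e <- binned_entropy(X, b)
    expect_lte(e, log2(b^2) + 1e-12)
    expect_lte(e, log2(40) + 1e-12)
  }
  # rotation invariance (PCA alignment)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Y <- matrix(rnorm(200), 100, 2) %*% diag(c(3, 1))
  expect_equal(binned_entropy(Y, 8), binned_entropy(Y %*% t(R), 8),
               tolerance = 1e-9)
  # refinement of uniform data does not lose entropy
  set.seed(5)
  U <- cbind(runif(400, -1, 1), runif(400, -1, 1))
  es <- vapply(c(2, 4, 8, 16), function(b) binned_entropy(U, b), 1)
  expect_true(all(diff(es) > -1e-9))
})

test_that("entropy ordering report covers all bin sizes with a flag", {
  set.seed(6)
  tq <- lapply(1:30, function(i) array(rnorm(16), c(2, 2, 4)))
  sq <- lapply(1:30, function(i) array(rnorm(16, sd = 0.01), c(2, 2, 4)))
  msgs <- matrix(rnorm(30 * 5, sd = 0.5), 30, 5)
  rep <- entropy_ordering_report(tq, msgs, sq, bin_range = 2:6)
  expect_equal(rep$bins, 2:6)
  expect_true(all(c("teacher", "message", "student", "ordered") %in%
                    names(rep)))
})
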