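test_that("goal patterns exclude the start and cover sensible cells", {
  for (p in 1:7) {
    m <- goal_pattern(p, 4)
    expect_false(m[1, 1])
    expect_gt(sum(m), 0)
  }
  # checkerboard: even x+y cells minus the start
  cb <- goal_pattern(1, 4)
  expect_equal(sum(cb), 7)
  expect_true(cb[2, 2] && cb[1, 3] && !cb[2, 1])
  expect_error(goal_pattern(9), "pattern id")
})

test_that("walker policies are valid and the smart walker avoids bounces", {
  tasks <- fx_training_tasks()
  for (i in c(1, 40, 140)) {
    tk <- tasks[[i]]
    tt <- mazelang:::task_tables(tk)
    for (kind in c("random", "smart_random")) {
      pol <- walker_policy(tk, kind)
      expect_equal(rowSums(pol), rep(1, 16))
    }
    smart <- walker_policy(tk, "smart_random")
    bounce <- tt$nxt == matrix(1:16, 16, 4)
    expect_true(all(smart[bounce] == 0))
  }
})

test_that("smart random walker dominates the plain random walker", {
  tasks <- fx_training_tasks()
  rates <- vapply(tasks, function(tk) {
    c(solve_rate(walker_policy(tk, "random"), tk),
      solve_rate(walker_policy(tk, "smart_random"), tk))
  }, numeric(2))
  expect_true(all(rates[2, ] >= rates[1, ] - 1e-12))
  expect_gt(mean(rates[2, ] - rates[1, ]), 0)
})

test_that("misinformed draws never return the task's own message", {
  for (s in 1:5) {
    mis <- mazelang:::misinform(30, seed = s)
    expect_true(all(mis != seq_len(30)))
    expect_true(all(mis >= 1 & mis <= 30))
  }
  # fixed seed, fixed draw
  expect_identical(mazelang:::misinform(30, 7), mazelang:::misinform(30, 7))
})

test_that("significance tests match the reference t distribution", {
  set.seed(12)
  x <- rnorm(8, mean = 0.6, sd = 0.05)
  y <- rnorm(8, mean = 0.4, sd = 0.05)
  cells <- data.frame(
    language = rep(1:8, 3),
    agent = rep(c("informed", "misinformed", "smart_random"), each = 8),
    solve_rate = c(x, y, y))
  st <- significance_tests(cells, bonferroni = 1)
  expect_equal(st$p_vs_misinformed,
               t.test(x, y, paired = TRUE)$p.value, tolerance = 1e-10)
  expect_equal(st$p_vs_smart_random,
               t.test(x, y, paired = TRUE, alternative = "greater")$p.value,
               tolerance = 1e-10)
  # identical samples: two-sided p = 1
  cells0 <- cells; cells0$solve_rate <- c(x, x, x)
  st0 <- significance_tests(cells0, bonferroni = 1)
  expect_equal(st0$p_vs_misinformed, 1)
  # Bonferroni multiplies and caps
  st7 <- significance_tests(cells, bonferroni = 7)
  expect_equal(st7$p_vs_misinformed,
               min(1, 7 * t.test(x, y, paired = TRUE)$p.value))
})

test_that("language filtering applies the strict retention rule", {
  df <- data.frame(informed = c(0.8, 0.2, 0.3),
                   misinformed = c(0.3, 0.3, 0.3),
                   random = c(0.25, 0.25, 0.25))
  keep <- filter_languages(df)
  expect_identical(keep, c(TRUE, FALSE, FALSE))  # tie is discarded
  # idempotent and order-independent
  expect_identical(filter_languages(df[keep, , drop = FALSE]), TRUE)
  perm <- c(3, 1, 2)
  expect_identical(filter_languages(df[perm, ]), keep[perm])
})

test_that("evaluation grid covers all scenarios, agents and patterns", {
  tasks <- fx_training_tasks()
  test_tasks <- enumerate_test_tasks(4)[1:26]   # two held-out worlds
  set.seed(42)
  # an untrained language exercises the plumbing; students train briefly
  lang <- list(net = language_net(4, 5, seed = 3))
  qs <- lapply(tasks, function(tk) array(rnorm(64, sd = 0.3), c(4, 4, 4)))
  tqs <- lapply(test_tasks, function(tk) array(rnorm(64, sd = 0.3), c(4, 4, 4)))
  rep <- evaluate_grid(list(lang), qs, tasks, patterns = c(1, 6),
                       scenarios = c("trained_goals", "unknown_goals",
                                     "new_mazes_trained",
                                     "new_mazes_unknown"),
                       test_teacher_qs = tqs, test_tasks = test_tasks,
                       student_cfg = student_config(epochs = 20),
                       eval_seed = 4)
  s <- rep$summary
  expect_setequal(unique(s$scenario),
                  c("trained_goals", "unknown_goals", "new_mazes_trained",
                    "new_mazes_unknown"))
  expect_setequal(unique(s$agent),
                  c("informed", "misinformed", "random", "smart_random"))
  expect_setequal(unique(s$pattern), c(1, 6))
  expect_true(all(s$mean >= 0 & s$mean <= 1))
  # single seed: SEM collapses to 0 and p-values are NA
  expect_true(all(s$sem == 0))
  # new-maze scenarios require the held-out inputs
  expect_error(evaluate_grid(list(lang), qs, tasks, patterns = 1,
                             scenarios = "new_mazes_trained"),
               "test_tasks")
})
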