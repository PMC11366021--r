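test_that("autoencoder geometry matches the architecture table", {
  ln <- language_net(4, 5, seed = 1)
  expect_identical(param_count(ln, weights_only = TRUE), 4720L)
  # layer shapes: conv weights 160/400, fully connected 1800 each way
  p <- ln$params
  expect_length(p$k1, 160); expect_length(p$k2, 400)
  expect_length(p$Wm, 1800); expect_length(p$Wd, 1800)
  expect_length(p$k3, 400); expect_length(p$k4, 160)
  # spatial extent grows 4 -> 5 -> 6 through the encoder
  expect_equal(ln$maps$m1$out_h, 5L)
  expect_equal(ln$maps$m2$out_h, 6L)
  # and shrinks back through the decoder
  expect_equal(ln$maps$m3$out_h, 5L)
  expect_equal(ln$maps$m4$out_h, 4L)
})

test_that("encoding is deterministic, linear at the bottleneck, shape-checked", {
  ln <- language_net(4, 5, seed = 2)
  q <- array(rnorm(64), c(4, 4, 4))
  m1 <- encode(ln, q); m2 <- encode(ln, q)
  expect_identical(m1, m2)
  expect_length(m1, 5)
  # zero weights give the zero message (message units have no bias)
  ln0 <- ln
  ln0$params <- lapply(ln0$params, function(p) p * 0)
  expect_equal(encode(ln0, q), rep(0, 5))
  expect_error(encode(ln, array(0, c(3, 3, 4))), "mismatch")
  # batch encoding matches per-item encoding
  qs <- lapply(1:3, function(i) array(rnorm(64), c(4, 4, 4)))
  M <- encode(ln, qs)
  expect_equal(M[2, ], encode(ln, qs[[2]]))
})

test_that("sae loss combines Euclidean reconstruction error and L1 sparsity", {
  q <- array(rnorm(64), c(4, 4, 4))
  expect_equal(sae_loss(q, q, rep(0, 5), kappa = 0.5), 0)
  expect_equal(sae_loss(q, q, c(1, -1, 0, 0, 0), kappa = 1), 2)
  # kappa = 0.5, ||error||_2 = 4, ||m||_1 = 2 -> 3
  qr <- q; qr[1] <- qr[1] + 4
  expect_equal(sae_loss(q, qr, c(2, 0, 0, 0, 0), kappa = 0.5), 3)
})

test_that("compound loss reduces correctly and guards the ablation", {
  expect_equal(compound_loss(0.4, 0.1, goal_term = 0.25, zeta = 2), 1.0)
  # zeta = 0 reduces to the SAE loss exactly
  expect_equal(compound_loss(0.4, 0.1, goal_term = 0.9, zeta = 0),
               compound_loss(0.4, 0.1))
  # ablated: sparsity + zeta * goal only
  expect_equal(compound_loss(0.4, 0.1, goal_term = 0.25, zeta = 2,
                             ablate_reconstruction = TRUE, feedback = TRUE),
               0.6)
  expect_error(compound_loss(0.4, 0.1, ablate_reconstruction = TRUE,
                             feedback = FALSE), "signal")
  expect_error(language_config(feedback = FALSE,
                               ablate_reconstruction = TRUE), "signal")
})

test_that("autoencoder gradients match finite differences", {
  set.seed(9)
  ln <- language_net(4, 5, seed = 3)
  X <- matrix(rnorm(4 * 64), 4, 64)
  cfg <- language_config(kappa = 0.3)
  bg <- mazelang:::lang_batch_grad(ln, X, cfg)
  h <- 1e-6
  for (pn in c("k1", "b2", "Wm", "Wd", "k3", "b4", "b_out")) {
    idx <- 2L
    p2 <- ln$params; p2[[pn]][idx] <- p2[[pn]][idx] + h
    bg2 <- mazelang:::lang_batch_grad(mazelang:::lang_set_params(ln, p2),
                                      X, cfg)
    num <- (bg2$loss - bg$loss) / h
    expect_equal(unname(bg$grads[[pn]][idx]), num, tolerance = 1e-3)
  }
  # with feedback: gradient also flows through the student into the encoder
  tasks <- fx_training_tasks()[1:4]
  st <- student_net(5, 4, seed = 4)
  tts <- lapply(tasks, mazelang:::task_tables)
  kopts <- lapply(tasks, shortest_path_length)
  Xc <- mazelang:::norm_coords(tts[[1]]$states_xy, 4)
  cfgf <- language_config(kappa = 0.3, zeta = 0.8, feedback = TRUE)
  bgf <- mazelang:::lang_batch_grad(ln, X, cfgf, student = st, tts = tts,
                                    kopts = kopts, Xs_coords = Xc)
  p2 <- ln$params; p2$k1[5] <- p2$k1[5] + h
  bg2 <- mazelang:::lang_batch_grad(mazelang:::lang_set_params(ln, p2), X,
                                    cfgf, student = st, tts = tts,
                                    kopts = kopts, Xs_coords = Xc)
  expect_equal(unname(bgf$grads$k1[5]), (bg2$loss - bgf$loss) / h,
               tolerance = 1e-3)
  expect_false(all(bgf$grads$k1 == bg$grads$k1))
})

test_that("short training runs reduce the loss on a small task subset", {
  tasks <- fx_training_tasks()
  idx <- which(vapply(tasks, attr, integer(1), "world_id") <= 2L)  # 2 worlds
  set.seed(31)
  qs <- lapply(idx, function(i) {
    # synthetic Q-matrices standing in for full teacher training: the
    # value-iteration solution plus noise keeps the test fast
    q <- vi_q_oracle(tasks[[i]])
    mazelang:::qtab_to_qmatrix(q + rnorm(64, sd = 0.05), 4)
  })
  lcfg <- language_config(feedback = FALSE, epochs = 120, seed = 5)
  tl <- train_language(qs, tasks[idx], lcfg, trace = 10)
  ls <- tl$history$loss
  expect_lt(mean(tail(ls, 3)), mean(head(ls, 3)))
  expect_equal(dim(tl$messages), c(length(idx), 5L))
  # reproducibility under a fixed seed
  tl2 <- train_language(qs, tasks[idx], lcfg)
  expect_equal(tl2$messages, tl$messages, tolerance = 1e-12)
})
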