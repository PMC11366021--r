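# The language channel: a sparse convolutional autoencoder mapping teacher
# Q-matrices (n x n x 4 images, channels = actions) to K-dimensional real
# messages and back.  Convolutions are realised as structured dense
# matrices built from the shared kernel parameters via precomputed index
# maps, which keeps forward/backward passes as plain matrix products.

# Index maps for a 2x2 convolution as a dense (in_dim x out_dim) matrix.
# mode "full": out = in + 1 per axis (zero padding); "valid": out = in - 1.
# Images are flattened x-fastest, then y, then channel.
conv_maps <- function(in_h, in_w, in_c, n_f, mode = c("full", "valid")) {
  mode <- match.arg(mode)
  k <- 2L
  if (mode == "full") { out_h <- in_h + 1L; out_w <- in_w + 1L; off <- -1L }
  else { out_h <- in_h - 1L; out_w <- in_w - 1L; off <- 0L }
  in_dim <- in_h * in_w * in_c
  out_dim <- out_h * out_w * n_f
  iw <- integer(0); ik <- integer(0)
  for (f in seq_len(n_f)) for (oy in seq_len(out_h)) for (ox in seq_len(out_w)) {
    o <- ox + (oy - 1L) * out_w + (f - 1L) * out_h * out_w
    for (c in seq_len(in_c)) for (dy in 1:k) for (dx in 1:k) {
      ix <- ox + dx - 1L + off; iy <- oy + dy - 1L + off
      if (ix < 1L || iy < 1L || ix > in_w || iy > in_h) next
      i <- ix + (iy - 1L) * in_w + (c - 1L) * in_h * in_w
      iw <- c(iw, i + (o - 1L) * in_dim)
      ik <- c(ik, dx + (dy - 1L) * k + (c - 1L) * k * k +
                (f - 1L) * k * k * in_c)
    }
  }
  # column -> filter map for the per-filter bias
  fcol <- rep(seq_len(n_f), each = out_h * out_w)
  list(in_dim = in_dim, out_dim = out_dim, out_h = out_h, out_w = out_w,
       n_f = n_f, n_k = k * k * in_c * n_f, idx_w = iw, idx_k = ik,
       fcol = fcol)
}

conv_dense <- function(map, kernel) {
  W <- matrix(0, map$in_dim, map$out_dim)
  W[map$idx_w] <- kernel[map$idx_k]
  W
}

conv_kernel_grad <- function(map, gW) {
  g <- numeric(map$n_k)
  acc <- rowsum(gW[map$idx_w], map$idx_k)
  g[as.integer(rownames(acc))] <- acc
  g
}

#' Construct a language autoencoder network
#'
#' Encoder: two 2x2 convolutions (10 filters each, ReLU, spatial extent
#' growing n -> n+1 -> n+2) followed by a linear, bias-free map to the K
#' message units.  Decoder: fully connected layer to 10 (n+2)^2 units
#' (ReLU), two 2x2 convolutions shrinking back to n x n x 4, and a final
#' per-pixel output bias; the reconstruction output is linear.
#'
#' @param n_int maze interior size (default 4).
#' @param K message length (default 5).
#' @param seed integer seed for initialization.
#' @return object of class \code{language_net}.
#' @export
language_net <- function(n_int = 4L, K = 5L, seed = NULL) {
  n_int <- as.integer(n_int); K <- as.integer(K)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  m1 <- conv_maps(n_int, n_int, 4L, 10L, "full")
  m2 <- conv_maps(n_int + 1L, n_int + 1L, 10L, 10L, "full")
  wide <- 10L * (n_int + 2L)^2
  m3 <- conv_maps(n_int + 2L, n_int + 2L, 10L, 10L, "valid")
  m4 <- conv_maps(n_int + 1L, n_int + 1L, 10L, 4L, "valid")
  rn <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))
  net <- list(
    n_int = n_int, K = K,
    maps = list(m1 = m1, m2 = m2, m3 = m3, m4 = m4),
    params = list(
      k1 = rn(m1$n_k, 16), b1 = numeric(10),
      k2 = rn(m2$n_k, 40), b2 = numeric(10),
      Wm = matrix(rn(wide * K, wide), wide, K),
      Wd = matrix(rn(K * wide, K), K, wide), bd = numeric(wide),
      k3 = rn(m3$n_k, 40), b3 = numeric(10),
      k4 = rn(m4$n_k, 40), b4 = numeric(4),
      b_out = numeric(4L * n_int^2)))
  class(net) <- "language_net"
  net
}

#' @export
print.language_net <- function(x, ...) {
  cat(sprintf("<language_net n=%d K=%d, %d weight / %d total parameters>\n",
              x$n_int, x$K, param_count(x, weights_only = TRUE),
              param_count(x)))
  invisible(x)
}

#' @export
param_count.language_net <- function(net, weights_only = FALSE) {
  p <- net$params
  w <- length(p$k1) + length(p$k2) + length(p$Wm) + length(p$Wd) +
    length(p$k3) + length(p$k4)
  if (weights_only) return(as.integer(w))
  as.integer(w + length(p$b1) + length(p$b2) + length(p$bd) +
               length(p$b3) + length(p$b4) + length(p$b_out))
}

# batched encoder forward; X: n_tasks x 4n^2.  Returns cache for backprop.
lang_encode_fwd <- function(net, X) {
  p <- net$params; mp <- net$maps
  relu_bias <- function(Z, b) {
    Z <- Z + rep(b, each = nrow(Z))
    Z * (Z > 0)
  }
  W1 <- conv_dense(mp$m1, p$k1)
  A1 <- relu_bias(X %*% W1, p$b1[mp$m1$fcol])
  W2 <- conv_dense(mp$m2, p$k2)
  A2 <- relu_bias(A1 %*% W2, p$b2[mp$m2$fcol])
  M <- A2 %*% p$Wm
  list(X = X, A1 = A1, A2 = A2, M = M, W1 = W1, W2 = W2)
}

# batched decoder forward from messages M (n_tasks x K)
lang_decode_fwd <- function(net, M) {
  p <- net$params; mp <- net$maps
  relu_bias <- function(Z, b) {
    Z <- Z + rep(b, each = nrow(Z))
    Z * (Z > 0)
  }
  Ad <- relu_bias(M %*% p$Wd, p$bd)
  W3 <- conv_dense(mp$m3, p$k3)
  A3 <- relu_bias(Ad %*% W3, p$b3[mp$m3$fcol])
  W4 <- conv_dense(mp$m4, p$k4)
  R <- A3 %*% W4 + rep(p$b4[mp$m4$fcol], each = nrow(M))
  R <- R + rep(p$b_out, each = nrow(M))
  list(M = M, Ad = Ad, A3 = A3, R = R, W3 = W3, W4 = W4)
}

#' Encode Q-matrices into messages
#'
#' @param net a \code{\link{language_net}}.
#' @param q a single n x n x 4 Q-matrix, or a list of them, or a matrix
#'   with one flattened Q-matrix per row.
#' @return numeric vector of length K for a single input, else a matrix
#'   (one message per row).
#' @export
encode <- function(net, q) {
  single <- FALSE
  if (is.list(q)) X <- do.call(rbind, lapply(q, as.vector))
  else if (length(dim(q)) == 3L) { X <- matrix(as.vector(q), 1L); single <- TRUE }
  else X <- q
  if (ncol(X) != 4L * net$n_int^2) stop("Q-matrix shape mismatch")
  M <- lang_encode_fwd(net, X)$M
  if (single) drop(M) else M
}

#' Decode messages into reconstructed Q-matrices
#'
#' @param net a \code{\link{language_net}}.
#' @param m message vector of length K or matrix of messages (rows).
#' @return reconstruction(s): an n x n x 4 array for a single message, else
#'   a matrix with one flattened reconstruction per row.
#' @export
decode <- function(net, m) {
  single <- is.null(dim(m))
  M <- if (single) matrix(m, 1L) else m
  R <- lang_decode_fwd(net, M)$R
  if (single) array(drop(R), dim = c(net$n_int, net$n_int, 4L)) else R
}

#' Sparse-autoencoder loss for one task
#'
#' \code{(1-kappa) ||Q_recon - Q||_2 + kappa ||m||_1}: Euclidean norm of the
#' reconstruction error plus the L1 norm of the message.
#'
#' @param q true Q-matrix (n x n x 4 or flattened).
#' @param q_recon reconstruction, same shape.
#' @param m message vector.
#' @param kappa sparsity/reconstruction tradeoff in [0, 1].
#' @return scalar loss.
#' @export
sae_loss <- function(q, q_recon, m, kappa) {
  stopifnot(length(q) == length(q_recon), kappa >= 0, kappa <= 1)
  (1 - kappa) * sqrt(sum((as.vector(q_recon) - as.vector(q))^2)) +
    kappa * sum(abs(m))
}

#' Compound autoencoder loss
#'
#' \code{L_SAE + zeta * L_goal_finding}; with
#' \code{ablate_reconstruction = TRUE} the reconstruction term is dropped,
#' leaving sparsity promotion plus student feedback only.
#'
#' @param recon_term reconstruction loss value.
#' @param sparsity_term sparsity loss value.
#' @param goal_term student goal-finding loss value (0 if no feedback).
#' @param zeta feedback weight.
#' @param ablate_reconstruction drop the reconstruction term.
#' @param feedback whether a feedback term is present (required under
#'   ablation, otherwise no training signal remains).
#' @return scalar loss.
#' @export
compound_loss <- function(recon_term, sparsity_term, goal_term = 0,
                          zeta = 1, ablate_reconstruction = FALSE,
                          feedback = goal_term != 0) {
  if (ablate_reconstruction && !feedback)
    stop("ablating the reconstruction without feedback leaves no training signal")
  (if (ablate_reconstruction) 0 else recon_term) + sparsity_term +
    zeta * goal_term
}

#' Language training configuration
#'
#' @param kappa sparsity/reconstruction tradeoff in [0, 1].
#' @param zeta weight of the student-feedback term.
#' @param gamma_reg student-output regularization weight inside the
#'   goal-finding loss.
#' @param feedback include the student goal-finding term and co-train the
#'   student.
#' @param ablate_reconstruction drop the reconstruction term (requires
#'   feedback).
#' @param learning_rate Adam step size.
#' @param epochs full-batch training epochs.
#' @param seed integer seed.
#' @return list of class \code{language_config}.
#' @export
language_config <- function(kappa = 0.3, zeta = 6.0, gamma_reg = 0.1,
                            feedback = FALSE, ablate_reconstruction = FALSE,
                            learning_rate = 2e-3, epochs = 3000L,
                            seed = 1L) {
  stopifnot(kappa >= 0, kappa <= 1, gamma_reg >= 0, gamma_reg <= 1,
            zeta >= 0)
  if (ablate_reconstruction && !feedback)
    stop("ablating the reconstruction without feedback leaves no training signal")
  structure(list(kappa = kappa, zeta = zeta, gamma_reg = gamma_reg,
                 feedback = feedback,
                 ablate_reconstruction = ablate_reconstruction,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "language_config")
}

# flat parameter list helpers for the autoencoder
lang_params <- function(net) net$params
lang_set_params <- function(net, p) { net$params <- p; net }

# Full joint forward/backward pass over a batch of tasks.
# Returns loss components and gradients for language (and student) params.
# student: NULL or an mlp (input 2 + K); tts/kopts precomputed per task.
lang_batch_grad <- function(net, X, cfg, student = NULL, tts = NULL,
                            kopts = NULL, Xs_coords = NULL) {
  enc <- lang_encode_fwd(net, X)
  dec <- lang_decode_fwd(net, enc$M)
  nT <- nrow(X)
  E <- dec$R - X
  enorm <- sqrt(rowSums(E^2))
  recon <- mean(enorm)
  spars <- mean(rowSums(abs(enc$M)))
  kappa <- cfg$kappa

  # dL/dR and dL/dM from the SAE terms (mean over tasks)
  use_recon <- !cfg$ablate_reconstruction
  gR <- if (use_recon)
    (1 - kappa) * E / pmax(enorm, 1e-12) / nT else matrix(0, nT, ncol(X))
  gM <- kappa * sign(enc$M) / nT

  goal <- 0
  student_grads <- NULL
  if (!is.null(student)) {
    K <- net$K
    ns <- nrow(Xs_coords)                      # states per task
    Xs <- do.call(rbind, lapply(seq_len(nT), function(t)
      cbind(Xs_coords, matrix(enc$M[t, ], ns, K, byrow = TRUE))))
    fw <- mlp_forward(student, Xs, cache = TRUE)
    Gq_all <- matrix(0, nrow(Xs), 4L)
    gl <- 0
    for (t in seq_len(nT)) {
      rows <- ((t - 1L) * ns + 1L):(t * ns)
      res <- goal_loss_core(fw$out[rows, , drop = FALSE], tts[[t]],
                            kopts[[t]], cfg$gamma_reg, grad = TRUE)
      gl <- gl + res$loss
      Gq_all[rows, ] <- res$grad
    }
    goal <- gl / nT
    zeta_n <- cfg$zeta / nT
    bk <- mlp_backward(student, fw, Gq_all * zeta_n)
    student_grads <- bk
    # message gradient: sum over the task's state rows
    gXin <- bk$gX[, 3L:(2L + K), drop = FALSE]
    grp <- rep(seq_len(nT), each = ns)
    gM <- gM + rowsum(gXin, grp)
  }

  # decoder backward
  p <- net$params; mp <- net$maps
  G <- gR
  g_bout <- colSums(G)
  g_b4 <- drop(rowsum(colSums(G), mp$m4$fcol))
  gW4 <- crossprod(dec$A3, G)
  g_k4 <- conv_kernel_grad(mp$m4, gW4)
  G <- (G %*% t(dec$W4)) * (dec$A3 > 0)
  g_b3 <- drop(rowsum(colSums(G), mp$m3$fcol))
  gW3 <- crossprod(dec$Ad, G)
  g_k3 <- conv_kernel_grad(mp$m3, gW3)
  G <- (G %*% t(dec$W3)) * (dec$Ad > 0)
  g_bd <- colSums(G)
  g_Wd <- crossprod(enc$M, G)
  gM <- gM + G %*% t(p$Wd)

  # encoder backward
  g_Wm <- crossprod(enc$A2, gM)
  G <- (gM %*% t(p$Wm)) * (enc$A2 > 0)
  g_b2 <- drop(rowsum(colSums(G), mp$m2$fcol))
  gW2 <- crossprod(enc$A1, G)
  g_k2 <- conv_kernel_grad(mp$m2, gW2)
  G <- (G %*% t(enc$W2)) * (enc$A1 > 0)
  g_b1 <- drop(rowsum(colSums(G), mp$m1$fcol))
  gW1 <- crossprod(enc$X, G)
  g_k1 <- conv_kernel_grad(mp$m1, gW1)

  grads <- list(k1 = g_k1, b1 = g_b1, k2 = g_k2, b2 = g_b2, Wm = g_Wm,
                Wd = g_Wd, bd = g_bd, k3 = g_k3, b3 = g_b3, k4 = g_k4,
                b4 = g_b4, b_out = g_bout)
  loss <- compound_loss(if (use_recon) (1 - kappa) * recon else 0,
                        kappa * spars, goal, cfg$zeta,
                        ablate_reconstruction = FALSE, feedback = TRUE)
  list(loss = loss, recon = recon, sparsity = spars, goal = goal,
       grads = grads, student_grads = student_grads, messages = enc$M)
}

#' Train the language autoencoder
#'
#' Without feedback, minimizes the sparse-autoencoder loss over all
#' training tasks by full-batch Adam.  With feedback, the student is
#' co-trained: each epoch takes one joint gradient step on
#' \code{L_SAE + zeta * mean(L_goal_finding)}, with gradients flowing into
#' the encoder through the student's performance (never into teacher
#' parameters, which are fixed inputs here).
#'
#' @param teacher_qs list of n x n x 4 teacher Q-matrices (one per task).
#' @param tasks list of the corresponding \code{\link{maze_task}} objects.
#' @param config a \code{\link{language_config}}.
#' @param student optional initial student \code{\link{mlp}} for feedback
#'   training (default: freshly initialized).
#' @param trace record the loss curve every \code{trace} epochs (0 = off).
#' @return object of class \code{trained_language}: fields \code{net},
#'   \code{student} (co-trained student or NULL), \code{config},
#'   \code{history} (data.frame of loss components), \code{messages}
#'   (final per-task messages).
#' @export
train_language <- function(teacher_qs, tasks, config = language_config(),
                           student = NULL, trace = 0L) {
  stopifnot(length(teacher_qs) == length(tasks))
  n_int <- dim(teacher_qs[[1]])[1]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  net <- language_net(n_int, K = 5L)
  X <- do.call(rbind, lapply(teacher_qs, as.vector))
  tts <- NULL; kopts <- NULL; Xs_coords <- NULL
  if (config$feedback) {
    if (is.null(student)) student <- student_net(K = net$K, n_int = n_int)
    tts <- lapply(tasks, task_tables)
    kopts <- lapply(tasks, shortest_path_length)
    Xs_coords <- norm_coords(tts[[1]]$states_xy, n_int)
    sparams <- mlp_params(student)
    sopt <- adam_init(sparams, lr = config$learning_rate)
  }
  params <- lang_params(net)
  opt <- adam_init(params, lr = config$learning_rate)
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    bg <- lang_batch_grad(net, X, config,
                          student = if (config$feedback) student else NULL,
                          tts = tts, kopts = kopts, Xs_coords = Xs_coords)
    g <- bg$grads[names(params)]
    u <- adam_step(opt, params, g)
    opt <- u$opt; params <- u$params
    net <- lang_set_params(net, params)
    if (config$feedback) {
      sg <- list()
      for (l in seq_along(bg$student_grads$gW))
        sg <- c(sg, list(bg$student_grads$gW[[l]], bg$student_grads$gb[[l]]))
      su <- adam_step(sopt, sparams, sg)
      sopt <- su$opt; sparams <- su$params
      student <- mlp_set_params(student, sparams)
    }
    if (trace > 0L && (ep %% trace == 0L || ep == 1L))
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = ep, loss = bg$loss, recon = bg$recon,
        sparsity = bg$sparsity, goal = bg$goal)
  }
  bg <- lang_batch_grad(net, X, config,
                        student = if (config$feedback) student else NULL,
                        tts = tts, kopts = kopts, Xs_coords = Xs_coords)
  structure(list(net = net,
                 student = if (config$feedback) student else NULL,
                 config = config,
                 history = if (length(hist)) do.call(rbind, hist) else NULL,
                 messages = bg$messages,
                 final = list(loss = bg$loss, recon = bg$recon,
                              sparsity = bg$sparsity, goal = bg$goal)),
            class = "trained_language")
}

#' @export
print.trained_language <- function(x, ...) {
  cat(sprintf(
    "<trained_language: %s%s, final recon %.3f, sparsity %.3f%s>\n",
    if (x$config$feedback) "feedback" else "no-feedback",
    if (x$config$ablate_reconstruction) " (no reconstruction)" else "",
    x$final$recon, x$final$sparsity,
    if (x$config$feedback) sprintf(", goal %.3f", x$final$goal) else ""))
  invisible(x)
}

#' Export messages to CSV
#'
#' @param messages matrix of messages (rows = tasks).
#' @param path output file.
#' @param labels optional data.frame of label columns to prepend.
#' @return path, invisibly.
#' @export
messages_to_csv <- function(messages, path, labels = NULL) {
  df <- as.data.frame(messages)
  names(df) <- paste0("m_", seq_len(ncol(messages)))
  df <- cbind(data.frame(task_id = seq_len(nrow(messages))), labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
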