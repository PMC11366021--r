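# The message-conditioned student: an MLP taking the two (normalized) state
# coordinates plus the K message values and returning four action values.
# The student is trained purely through the differentiable goal-occupancy
# objective -- it never explores the environment itself.

#' Construct a student network
#'
#' Same body as the teacher (hidden 10, 20, 20 ReLU units with biases,
#' linear 4-unit output) but with \code{2 + K} inputs.
#'
#' @param K message length.
#' @param n_int maze interior size (stored for coordinate normalization).
#' @param seed integer seed.
#' @return an \code{\link{mlp}} with subclass \code{student_net}.
#' @export
student_net <- function(K = 5L, n_int = 4L, seed = NULL) {
  net <- mlp(c(2L + as.integer(K), 10L, 20L, 20L, 4L), seed = seed)
  attr(net, "n_int") <- as.integer(n_int)
  attr(net, "K") <- as.integer(K)
  class(net) <- c("student_net", class(net))
  net
}

#' Evaluate a student's Q-matrix for a task
#'
#' Runs the network at every interior state with the given message.
#'
#' @param net a \code{\link{student_net}}.
#' @param m message vector of length K.
#' @param world a \code{\link{grid_world}} (only the interior size is used;
#'   the student observes the maze through the message alone).
#' @return n x n x 4 array of action values.
#' @export
student_q_matrix <- function(net, m, world) {
  n <- world$n_int
  xy <- t(vapply(seq_len(n * n), index_cell, integer(2), n_int = n))
  X <- cbind(norm_coords(xy, n), matrix(m, n * n, length(m), byrow = TRUE))
  qtab_to_qmatrix(mlp_forward(net, X), n)
}

#' Student training configuration
#'
#' @param gamma_reg student-output regularization weight in the
#'   goal-finding loss.
#' @param learning_rate Adam step size.
#' @param epochs full-batch training epochs.
#' @param seed integer seed.
#' @return list of class \code{student_config}.
#' @export
student_config <- function(gamma_reg = 0.1, learning_rate = 1e-3,
                           epochs = 600L, seed = 1L) {
  structure(list(gamma_reg = gamma_reg, learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "student_config")
}

#' Train a student against a fixed set of messages
#'
#' Minimizes the mean goal-finding loss over the given tasks with
#' \code{k = k_opt} per task, by full-batch Adam on the student parameters
#' only ("frozen language": no gradient ever reaches the language).  Joint
#' student/language training is performed by
#' \code{\link{train_language}} with \code{feedback = TRUE}.
#'
#' @param messages matrix, one message per task (row).
#' @param tasks list of \code{\link{maze_task}} (the training subset, e.g.
#'   after applying a goal-pattern mask).
#' @param config a \code{\link{student_config}}.
#' @param net optional initial student network.
#' @return object of class \code{trained_student}: \code{net},
#'   \code{history}, \code{final_loss}.
#' @export
train_student <- function(messages, tasks, config = student_config(),
                          net = NULL) {
  stopifnot(nrow(messages) == length(tasks))
  if (length(tasks) == 0L) stop("empty task set")
  n_int <- tasks[[1]]$world$n_int
  K <- ncol(messages)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (is.null(net)) net <- student_net(K = K, n_int = n_int)
  tts <- lapply(tasks, task_tables)
  kopts <- lapply(tasks, shortest_path_length)
  ns <- tts[[1]]$n_states
  Xc <- norm_coords(tts[[1]]$states_xy, n_int)
  nT <- length(tasks)
  X <- do.call(rbind, lapply(seq_len(nT), function(t)
    cbind(Xc, matrix(messages[t, ], ns, K, byrow = TRUE))))
  params <- mlp_params(net)
  opt <- adam_init(params, lr = config$learning_rate)
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fw <- mlp_forward(net, X, cache = TRUE)
    G <- matrix(0, nrow(X), 4L)
    total <- 0
    for (t in seq_len(nT)) {
      rows <- ((t - 1L) * ns + 1L):(t * ns)
      res <- goal_loss_core(fw$out[rows, , drop = FALSE], tts[[t]],
                            kopts[[t]], config$gamma_reg, grad = TRUE)
      total <- total + res$loss
      G[rows, ] <- res$grad / nT
    }
    hist[ep] <- total / nT
    bk <- mlp_backward(net, fw, G)
    flat <- list()
    for (l in seq_along(bk$gW)) flat <- c(flat, list(bk$gW[[l]], bk$gb[[l]]))
    u <- adam_step(opt, params, flat)
    opt <- u$opt; params <- u$params
    net <- mlp_set_params(net, params)
  }
  structure(list(net = net, history = hist,
                 final_loss = hist[length(hist)], config = config),
            class = "trained_student")
}

#' @export
print.trained_student <- function(x, ...) {
  cat(sprintf("<trained_student: %d epoch(s), final goal loss %.4f>\n",
              length(x$history), x$final_loss))
  invisible(x)
}
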