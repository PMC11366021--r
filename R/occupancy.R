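# Differentiable goal-occupancy machinery.  A per-state action distribution
# induces an absorbing Markov chain over the maze (goal absorbing, walls
# bounce); the probability mass on the goal after k steps is the analytic
# solve probability and is differentiable with respect to the policy.

# Row-stochastic state-transition matrix induced by a policy on a task.
# policy: n_states x 4, rows sum to 1.  Goal row is forced absorbing.
policy_transition_matrix <- function(policy, tt) {
  ns <- tt$n_states
  M <- matrix(0, ns, ns)
  for (a in 1:4) {
    idx <- tt$Midx[[a]]
    M[idx] <- M[idx] + policy[, a]
  }
  M[tt$goal, ] <- 0
  M[tt$goal, tt$goal] <- 1
  M
}

#' Goal-occupancy probability after k steps
#'
#' Propagates a point mass at the start through the Markov chain induced by
#' the policy and the maze dynamics (bounce-back at walls and the boundary,
#' absorbing goal) and returns the probability mass on the goal after
#' exactly \code{k} steps.  Because the goal is absorbing this equals the
#' probability of reaching it within \code{k} steps.
#'
#' @param policy n_states x 4 matrix of per-state action probabilities
#'   (state index is \code{1 + x + y*n}); rows must sum to 1.
#' @param task a \code{\link{maze_task}}.
#' @param k non-negative integer number of steps.
#' @return scalar probability.
#' @export
occupancy_evolution <- function(policy, task, k) {
  tt <- task_tables(task)
  stopifnot(k >= 0, nrow(policy) == tt$n_states, ncol(policy) == 4L)
  if (any(abs(rowSums(policy) - 1) > 1e-8))
    stop("policy rows must sum to 1")
  M <- policy_transition_matrix(policy, tt)
  p <- numeric(tt$n_states); p[tt$start] <- 1
  for (i in seq_len(k)) p <- drop(p %*% M)
  p[tt$goal]
}

# softmax over rows (hot path is the 4-action case)
row_softmax <- function(Z) {
  m <- if (ncol(Z) == 4L) pmax(Z[, 1], Z[, 2], Z[, 3], Z[, 4]) else
    apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

#' Goal-finding loss of a student Q output
#'
#' The student's per-state action values are turned into a stochastic policy
#' by a per-state softmax; the loss is a quartic penalty on the probability
#' of missing the goal within \code{k} steps plus a norm regularizer on the
#' student output:
#' \code{(1-gamma_reg)*(1 - P[s_k = goal])^4 +
#'       gamma_reg*||Q_student||_2/sqrt(4 n^2)}.
#'
#' @param student_q n x n x 4 array (or n_states x 4 matrix) of student
#'   action values.
#' @param task a \code{\link{maze_task}}.
#' @param gamma_reg regularization weight in [0, 1].
#' @param k step budget; defaults to the task's shortest-path length k_opt.
#' @param grad if \code{TRUE}, also return the gradient with respect to
#'   \code{student_q} (same shape as the matrix form).
#' @return scalar loss, or \code{list(loss, grad, p_goal)} when
#'   \code{grad = TRUE}.
#' @export
goal_finding_loss <- function(student_q, task, gamma_reg = 0.1, k = NULL,
                              grad = FALSE) {
  tt <- task_tables(task)
  Q <- if (length(dim(student_q)) == 3L) qmatrix_to_qtab(student_q)
       else student_q
  stopifnot(nrow(Q) == tt$n_states, ncol(Q) == 4L)
  if (is.null(k)) k <- shortest_path_length(task)
  goal_loss_core(Q, tt, k, gamma_reg, grad = grad)
}

# core of the goal-finding loss over a precomputed task table
goal_loss_core <- function(Q, tt, k, gamma_reg, grad = FALSE) {
  P <- row_softmax(Q)
  M <- policy_transition_matrix(P, tt)
  ns <- tt$n_states
  # forward occupancy trajectory
  ps <- matrix(0, k + 1L, ns)
  ps[1L, tt$start] <- 1
  if (k > 0) for (i in seq_len(k)) ps[i + 1L, ] <- ps[i, ] %*% M
  p_goal <- ps[k + 1L, tt$goal]
  qnorm2 <- sqrt(sum(Q^2))
  loss <- (1 - gamma_reg) * (1 - p_goal)^4 +
    gamma_reg * qnorm2 / sqrt(4 * tt$n_states)
  if (!grad) return(loss)

  # adjoint pass: dL/dM = sum_t ps[t]^T a[t+1]^T with a[t] = M a[t+1]
  gM <- matrix(0, ns, ns)
  if (k > 0) {
    a <- numeric(ns); a[tt$goal] <- 1      # d p_goal(k) / d p_k
    for (t in k:1) {
      gM <- gM + outer(ps[t, ], a)
      a <- drop(M %*% a)
    }
  }
  # goal row of M is constant (absorbing): no gradient flows
  gM[tt$goal, ] <- 0
  # dL/dpolicy: M[s, nxt[s,a]] accumulates policy[s,a]
  gP <- matrix(0, ns, 4)
  for (a_i in 1:4) gP[, a_i] <- gM[tt$Midx[[a_i]]]
  dL_dpgoal <- -(1 - gamma_reg) * 4 * (1 - p_goal)^3
  gP <- dL_dpgoal * gP
  # softmax backward (rowwise): gQ = P * (gP - rowSums(gP * P))
  gQ <- P * (gP - rowSums(gP * P))
  # regularizer
  if (qnorm2 > 0)
    gQ <- gQ + gamma_reg * Q / (qnorm2 * sqrt(4 * tt$n_states))
  list(loss = loss, grad = gQ, p_goal = p_goal)
}

#' Analytic task solve rate of a policy
#'
#' Probability that the absorbing-chain walk under the per-state action
#' distribution reaches the goal within \code{2 s_opt} steps (inclusive),
#' where \code{s_opt} is the shortest-path length.
#'
#' @param policy n_states x 4 row-stochastic matrix.
#' @param task a \code{\link{maze_task}}.
#' @param budget_factor multiplier on \code{s_opt} (default 2).
#' @return probability in [0, 1].
#' @export
solve_rate <- function(policy, task, budget_factor = 2) {
  occupancy_evolution(policy, task, budget_factor * shortest_path_length(task))
}

#' Sampled task solve rate
#'
#' Monte-Carlo estimator of \code{\link{solve_rate}}: simulates episodes
#' under the stochastic policy and counts goal arrivals within the budget.
#'
#' @param policy n_states x 4 row-stochastic matrix.
#' @param task a \code{\link{maze_task}}.
#' @param episodes number of simulated episodes.
#' @param budget_factor multiplier on s_opt.
#' @param seed optional seed.
#' @return estimated probability.
#' @export
solve_rate_sampled <- function(policy, task, episodes = 1000L,
                               budget_factor = 2, seed = NULL) {
  tt <- task_tables(task)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  budget <- budget_factor * shortest_path_length(task)
  hits <- 0L
  for (e in seq_len(episodes)) {
    s <- tt$start
    for (step in seq_len(budget)) {
      a <- sample.int(4L, 1L, prob = policy[s, ])
      s <- tt$nxt[s, a]
      if (s == tt$goal) { hits <- hits + 1L; break }
    }
  }
  hits / episodes
}
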