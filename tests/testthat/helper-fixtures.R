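# Shared fixtures, computed lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

fx_training_tasks <- function() fx_get("tasks4", function()
  enumerate_training_tasks(4))

# a handful of trained teachers on assorted tasks (fast; used by several files)
fx_sample_teachers <- function() fx_get("sample_teachers", function() {
  tasks <- fx_training_tasks()
  idx <- c(3L, 40L, 137L, 200L)
  lapply(seq_along(idx), function(j)
    train_teacher(tasks[[idx[j]]], teacher_config(seed = 100L + j)))
})

fx_sample_task_idx <- c(3L, 40L, 137L, 200L)

# value-iteration oracle on the explicit MDP of a task
vi_q_oracle <- function(task, gamma = 0.99, iters = 400L) {
  tt <- mazelang:::task_tables(task)
  Q <- matrix(0, tt$n_states, 4)
  for (i in seq_len(iters)) {
    V <- apply(Q, 1, max)
    Q <- tt$rew + gamma * ifelse(tt$term, 0,
                                 matrix(V[tt$nxt], tt$n_states, 4))
  }
  Q
}

# independent absorbing-chain transition matrix (built from maze_step, not
# from the package's task_tables)
oracle_transition_matrix <- function(policy, task) {
  n <- task$world$n_int
  ns <- n * n
  M <- matrix(0, ns, ns)
  goal_i <- 1L + task$goal[1] + task$goal[2] * n
  wall_i <- if (nrow(task$world$walls))
    1L + task$world$walls[, 1] + task$world$walls[, 2] * n else integer(0)
  for (s in seq_len(ns)) {
    if (s == goal_i) { M[s, s] <- 1; next }
    if (s %in% wall_i) { M[s, s] <- 1; next }
    xy <- c((s - 1L) %% n, (s - 1L) %/% n)
    for (a in 1:4) {
      tr <- maze_step(task, xy, a)
      ni <- 1L + tr$next_state[1] + tr$next_state[2] * n
      M[s, ni] <- M[s, ni] + policy[s, a]
    }
  }
  M
}
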