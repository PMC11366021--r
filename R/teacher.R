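# Teacher agents: one deep-Q network per maze task.  The net maps the two
# state coordinates to four action values and is trained by one-step
# semi-gradient updates of the Bellman residual over a dual replay memory
# (all unique transitions plus an over-weighted window of recent ones).

# Tabulate the deterministic environment of a task: next-state index,
# reward and terminal flag for every (state, action) pair.
task_tables <- function(task) {
  world <- task$world
  n <- world$n_int
  ns <- n * n
  wall <- rep(FALSE, ns)
  if (nrow(world$walls))
    wall[cell_index(world$walls[, 1], world$walls[, 2], n)] <- TRUE
  goal <- cell_index(task$goal[1], task$goal[2], n)
  nxt <- matrix(0L, ns, 4); rew <- matrix(0, ns, 4); term <- matrix(FALSE, ns, 4)
  for (s in seq_len(ns)) {
    xy <- index_cell(s, n)
    for (a in 1:4) {
      nx <- xy[1] + ACTION_DX[a]; ny <- xy[2] + ACTION_DY[a]
      if (nx < 0L || ny < 0L || nx >= n || ny >= n ||
          wall[cell_index(nx, ny, n)]) {
        nxt[s, a] <- s; rew[s, a] <- world$reward_wall
      } else {
        ni <- cell_index(nx, ny, n)
        nxt[s, a] <- ni
        rew[s, a] <- if (ni == goal) world$reward_goal else world$reward_step
        term[s, a] <- ni == goal
      }
    }
  }
  xy <- t(vapply(seq_len(ns), index_cell, integer(2), n_int = n))
  # linear indices of M[s, nxt[s, a]] per action, for fast chain assembly
  Midx <- lapply(1:4, function(a) seq_len(ns) + (nxt[, a] - 1L) * ns)
  list(n = n, n_states = ns, wall = wall, goal = goal,
       start = cell_index(0L, 0L, n), nxt = nxt, rew = rew, term = term,
       states_xy = xy, Midx = Midx)
}

# States reachable from the start without passing through the absorbing
# goal (the goal itself is included when adjacent to the reachable set).
reachable_states <- function(tt) {
  seen <- rep(FALSE, tt$n_states)
  seen[tt$start] <- TRUE
  queue <- tt$start
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (a in 1:4) {
      ni <- tt$nxt[cur, a]
      if (seen[ni]) next
      seen[ni] <- TRUE
      if (ni != tt$goal) queue <- c(queue, ni)   # cannot leave the goal
    }
  }
  which(seen)
}

# BFS distance to the goal from every non-wall cell (moves are reversible,
# so a reverse BFS from the goal suffices).
goal_distances <- function(tt) {
  d <- rep(Inf, tt$n_states); d[tt$goal] <- 0
  queue <- tt$goal
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    xy <- index_cell(cur, tt$n)
    for (a in 1:4) {
      nx <- xy[1] + ACTION_DX[a]; ny <- xy[2] + ACTION_DY[a]
      if (nx < 0L || ny < 0L || nx >= tt$n || ny >= tt$n) next
      ni <- cell_index(nx, ny, tt$n)
      if (tt$wall[ni] || is.finite(d[ni])) next
      d[ni] <- d[cur] + 1
      queue <- c(queue, ni)
    }
  }
  d
}

#' Teacher training configuration
#'
#' @param gamma_bellman temporal discount in the Bellman target.
#' @param short_term_length length L of the recency window whose transitions
#'   are counted a second time in the loss.
#' @param learning_rate Adam step size.
#' @param episodes maximum training episodes.
#' @param max_steps_per_episode episode step cap.
#' @param eps_start,eps_end,eps_decay_frac epsilon-greedy exploration:
#'   epsilon decays linearly from \code{eps_start} to \code{eps_end} over the
#'   first \code{eps_decay_frac} fraction of episodes.
#' @param patience consecutive episode-end checks with an everywhere-optimal
#'   greedy policy required before stopping early.
#' @param min_episodes episodes always run before early stopping is
#'   considered.
#' @param min_env_steps total environment steps always taken before early
#'   stopping.
#' @param coverage_frac fraction of the free (state, action) pairs that
#'   must be present in the long-term memory before early stopping, so the
#'   loss constrains (almost) every pair even for tasks whose goal sits
#'   next to the start and whose episodes are short.
#' @param polish_steps maximum extra full-batch gradient steps after the
#'   policy has converged, sharpening the Q-values toward the Bellman fixed
#'   point.
#' @param polish_tol Bellman mean-squared residual below which polishing
#'   stops.
#' @param polish_lr Adam step size during the polish phase (defaults to
#'   three times the training rate; the batch is fixed there, so larger
#'   steps are safe and reach the residual tolerance sooner).
#' @param out_init_scale multiplier on the output layer's initial weights so
#'   initial Q-values start near zero.
#' @param seed integer seed.
#' @return list of class \code{teacher_config}.
#' @export
teacher_config <- function(gamma_bellman = 0.99, short_term_length = 20L,
                           learning_rate = 2e-3, episodes = 500L,
                           max_steps_per_episode = 50L,
                           eps_start = 1.0, eps_end = 0.05,
                           eps_decay_frac = 0.6, patience = 2L,
                           min_episodes = 15L, min_env_steps = 500L,
                           coverage_frac = 1.0,
                           polish_steps = 12000L, polish_tol = 5e-5,
                           polish_lr = 3 * learning_rate,
                           out_init_scale = 0.01, seed = 1L) {
  stopifnot(gamma_bellman >= 0, gamma_bellman <= 1)
  structure(list(gamma_bellman = gamma_bellman,
                 short_term_length = as.integer(short_term_length),
                 learning_rate = learning_rate,
                 episodes = as.integer(episodes),
                 max_steps_per_episode = as.integer(max_steps_per_episode),
                 eps_start = eps_start, eps_end = eps_end,
                 eps_decay_frac = eps_decay_frac,
                 patience = as.integer(patience),
                 min_episodes = as.integer(min_episodes),
                 min_env_steps = as.integer(min_env_steps),
                 coverage_frac = coverage_frac,
                 polish_steps = as.integer(polish_steps),
                 polish_tol = polish_tol, polish_lr = polish_lr,
                 out_init_scale = out_init_scale,
                 seed = as.integer(seed)),
            class = "teacher_config")
}

# map raw grid coordinates to the [-1, 1] network input range
norm_coords <- function(xy, n_int) xy / (n_int - 1) * 2 - 1

#' Deep-Q Bellman loss
#'
#' Mean squared Bellman residual over a transition multiset:
#' \code{mean(|Q(s,a) - (r + gamma max_a' Q(s',a'))|^2)}; for terminal
#' transitions the bootstrap term is dropped (the goal is absorbing).
#'
#' @param net an \code{\link{mlp}} teacher network (as found in a trained
#'   \code{teacher} object; inputs are the normalized state coordinates).
#' @param transitions data.frame with columns \code{x, y, action, reward,
#'   next_x, next_y, terminal} in raw grid coordinates; duplicated rows
#'   carry extra weight.
#' @param gamma discount factor.
#' @param n_int interior size used to normalize coordinates (default taken
#'   from the net's \code{n_int} attribute, else 4).
#' @return non-negative scalar.
#' @export
dqn_loss <- function(net, transitions, gamma, n_int = NULL) {
  if (NROW(transitions) == 0L) stop("empty transition set")
  if (is.null(n_int)) n_int <- attr(net, "n_int") %||% 4L
  X <- norm_coords(cbind(transitions$x, transitions$y), n_int)
  Xn <- norm_coords(cbind(transitions$next_x, transitions$next_y), n_int)
  Q <- mlp_forward(net, X)
  Qn <- mlp_forward(net, Xn)
  qsa <- Q[cbind(seq_len(nrow(Q)), transitions$action)]
  target <- transitions$reward +
    ifelse(transitions$terminal, 0, gamma * apply(Qn, 1, max))
  mean((qsa - target)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the training multiset from the dual replay memory
#'
#' The loss multiset is the union of all unique transitions (long-term
#' memory) plus the last-L transitions (short-term memory) counted again, so
#' recently executed transitions weigh more.
#'
#' @param memory list with elements \code{long_term} (data.frame of unique
#'   transitions) and \code{short_term} (data.frame of the last L
#'   transitions, duplicates allowed).
#' @return data.frame multiset of transitions.
#' @export
build_transition_set <- function(memory) {
  if (NROW(memory$long_term) == 0L) stop("empty replay memory")
  rbind(memory$long_term, memory$short_term)
}

# Greedy path length from start under a tabulated Q (n_states x 4);
# Inf if the greedy policy loops, bounces, or exceeds the cap.
greedy_path_length_q <- function(q, tt) {
  s <- tt$start
  for (step in seq_len(tt$n_states)) {
    a <- which.max(q[s, ])
    ns <- tt$nxt[s, a]
    if (ns == s) return(Inf)          # bounce: greedy policy stuck
    if (ns == tt$goal) return(step)
    s <- ns
  }
  Inf
}

#' Train a teacher on one task
#'
#' Deep Q-learning: epsilon-greedy episodes from the fixed start, one Adam
#' step on the Bellman loss over the full replay multiset after every
#' environment step.  Bellman targets are clamped to the attainable value
#' range of the task (between \code{reward_wall/(1-gamma)} and
#' \code{reward_goal}), which removes the unbounded bootstrap feedback loop
#' that plain semi-gradient updates are prone to.  Training stops early once
#' the greedy action is shortest-path-optimal at every reachable state for
#' \code{patience} consecutive episode ends, followed by a short full-batch
#' polish phase.
#'
#' @param task a \code{\link{maze_task}}.
#' @param config a \code{\link{teacher_config}}.
#' @return object of class \code{teacher}: fields \code{net}, \code{q} (the
#'   n x n x 4 Q-matrix with wall rows zeroed), \code{converged} (greedy
#'   path from start has length s_opt), \code{policy_optimal_everywhere},
#'   \code{episodes_run}, \code{s_opt}.
#' @export
train_teacher <- function(task, config = teacher_config()) {
  tt <- task_tables(task)
  gd <- goal_distances(tt)
  s_opt <- shortest_path_length(task)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  net <- mlp(c(2L, 10L, 20L, 20L, 4L))
  net$W[[4]] <- net$W[[4]] * config$out_init_scale
  attr(net, "n_int") <- tt$n
  params <- mlp_params(net)
  opt <- adam_init(params, lr = config$learning_rate)

  gamma <- config$gamma_bellman
  qlo <- task$world$reward_wall / max(1 - gamma, 1e-6)
  qhi <- task$world$reward_goal
  ns <- tt$n_states
  seen <- matrix(FALSE, ns, 4)            # long-term memory membership
  lt_s <- integer(0); lt_a <- integer(0)  # long-term (s, a) lists
  L <- config$short_term_length
  st_s <- integer(0); st_a <- integer(0)  # short-term window
  Xall <- norm_coords(tt$states_xy, tt$n)
  eps_span <- max(1, floor(config$episodes * config$eps_decay_frac))
  stable <- 0L; episodes_run <- 0L; env_steps <- 0L
  # optimality and coverage are only meaningful at states the agent can
  # actually occupy: reachable from the start without crossing the goal
  nongoal <- setdiff(reachable_states(tt), tt$goal)
  n_free_pairs <- 4L * length(nongoal)

  # batch structure rebuilt only when the replay memory changes
  batch <- NULL
  make_batch <- function() {
    bs <- c(lt_s, st_s); ba <- c(lt_a, st_a)
    m <- length(bs)
    pair <- (ba - 1L) * ns + bs
    ind <- matrix(0, m, ns * 4L)       # scatter matrix for the Q gradient
    ind[cbind(seq_len(m), pair)] <- 1
    batch <<- list(m = m, pair = pair, rew = tt$rew[pair],
                   nxt = tt$nxt[pair], trm = which(tt$term[pair]),
                   ind = ind)
  }

  grad_step <- function(fw) {
    Qtab <- fw$out
    vmax <- pmax(Qtab[, 1], Qtab[, 2], Qtab[, 3], Qtab[, 4])
    target <- batch$rew + gamma * vmax[batch$nxt]
    target[batch$trm] <- batch$rew[batch$trm]
    target <- pmin(pmax(target, qlo), qhi)
    resid <- Qtab[batch$pair] - target
    Gq <- matrix(crossprod(batch$ind, 2 * resid / batch$m), ns, 4)
    grads <- mlp_backward(net, fw, Gq)
    flat <- list()
    for (l in seq_along(grads$gW))
      flat <- c(flat, list(grads$gW[[l]], grads$gb[[l]]))
    upd <- adam_step(opt, params, flat)
    opt <<- upd$opt; params <<- upd$params
    net <<- mlp_set_params(net, params)
    mean(resid^2)
  }

  for (ep in seq_len(config$episodes)) {
    episodes_run <- ep
    eps <- max(config$eps_end,
               config$eps_start - (config$eps_start - config$eps_end) *
                 (ep - 1) / eps_span)
    s <- tt$start
    for (step in seq_len(config$max_steps_per_episode)) {
      fw <- mlp_forward(net, Xall, cache = TRUE)
      a <- if (stats::runif(1) < eps) sample.int(4L, 1L) else
        which.max(fw$out[s, ])
      if (!seen[s, a]) {
        seen[s, a] <- TRUE
        lt_s <- c(lt_s, s); lt_a <- c(lt_a, a)
      }
      st_s <- c(st_s, s); st_a <- c(st_a, a)
      if (length(st_s) > L) { st_s <- st_s[-1L]; st_a <- st_a[-1L] }
      make_batch()
      grad_step(fw)
      env_steps <- env_steps + 1L
      ns_idx <- tt$nxt[s, a]
      if (ns_idx == tt$goal) break
      s <- ns_idx
    }
    Qtab <- mlp_forward(net, Xall)
    ga <- max.col(Qtab[nongoal, , drop = FALSE], ties.method = "first")
    everywhere_opt <- all(gd[tt$nxt[cbind(nongoal, ga)]] == gd[nongoal] - 1)
    if (everywhere_opt) {
      stable <- stable + 1L
      if (stable >= config$patience && ep >= config$min_episodes &&
          env_steps >= config$min_env_steps &&
          length(lt_s) >= config$coverage_frac * n_free_pairs) break
    } else stable <- 0L
  }

  # Polish toward the Bellman fixed point; revert if the extra bootstrap
  # steps disturb the greedy policy (possible at rarely-visited states).
  policy_ok <- function() {
    Qtab <- mlp_forward(net, Xall)
    ga <- max.col(Qtab[nongoal, , drop = FALSE], ties.method = "first")
    all(gd[tt$nxt[cbind(nongoal, ga)]] == gd[nongoal] - 1)
  }
  pre_polish_ok <- policy_ok()
  snapshot <- net
  opt$lr <- config$polish_lr %||% config$learning_rate
  res <- Inf
  for (i in seq_len(config$polish_steps)) {
    res <- grad_step(mlp_forward(net, Xall, cache = TRUE))
    if (res < config$polish_tol) break
  }
  if (pre_polish_ok && !policy_ok()) net <- snapshot

  Qtab <- mlp_forward(net, Xall)
  ga <- apply(Qtab[nongoal, , drop = FALSE], 1, which.max)
  policy_opt <- all(gd[tt$nxt[cbind(nongoal, ga)]] == gd[nongoal] - 1)
  converged <- is.finite(greedy_path_length_q(Qtab, tt)) &&
    greedy_path_length_q(Qtab, tt) == s_opt
  # zero Q at states the agent can never occupy: wall states (bounce-back)
  # and, in the rare tasks whose start is boxed in by wall and goal,
  # states cut off by the absorbing goal -- their values are pure
  # extrapolation with no training signal
  Qtab[tt$wall, ] <- 0
  Qtab[setdiff(seq_len(ns), reachable_states(tt)), ] <- 0
  q <- qtab_to_qmatrix(Qtab, tt$n)
  structure(list(net = net, q = q, converged = converged,
                 policy_optimal_everywhere = policy_opt,
                 bellman_mse = res,
                 episodes_run = episodes_run, s_opt = s_opt, task = task,
                 config = config),
            class = "teacher")
}

# Q table (n_states x 4, state index = 1 + x + y*n) as an n x n x 4 array
# indexed [x+1, y+1, action].
qtab_to_qmatrix <- function(Qtab, n) array(Qtab, dim = c(n, n, 4))

qmatrix_to_qtab <- function(q) {
  n <- dim(q)[1]
  matrix(q, n * n, 4)
}

#' @export
print.teacher <- function(x, ...) {
  cat(sprintf("<teacher: s_opt=%d, %s after %d episode(s)>\n", x$s_opt,
              if (x$converged) "converged" else "NOT converged",
              x$episodes_run))
  invisible(x)
}

#' Extract the Q-matrix of a teacher
#'
#' @param teacher a \code{\link{train_teacher}} result.
#' @return n x n x 4 array, wall rows zero.
#' @export
q_matrix <- function(teacher) teacher$q

#' Train teachers for a list of tasks
#'
#' @param tasks list of tasks.
#' @param config base config; task i uses seed \code{seed + i}.
#' @param retries extra attempts (fresh seeds) for tasks whose first run
#'   does not converge or leaves a large Bellman residual.
#' @param bellman_retry_tol residual level above which a converged teacher
#'   is still retried (its Q-values are far from the fixed point); the
#'   best attempt by residual is kept.
#' @param progress print progress every 25 tasks.
#' @return list of \code{teacher} objects.
#' @export
train_teachers <- function(tasks, config = teacher_config(), retries = 2L,
                           bellman_retry_tol = 20 * config$polish_tol,
                           progress = FALSE) {
  out <- vector("list", length(tasks))
  ok <- function(t) t$converged && t$policy_optimal_everywhere &&
    t$bellman_mse <= bellman_retry_tol
  for (i in seq_along(tasks)) {
    cfg <- config
    cfg$seed <- config$seed + i
    tch <- train_teacher(tasks[[i]], cfg)
    r <- 0L
    while (!ok(tch) && r < retries) {
      r <- r + 1L
      cfg$seed <- cfg$seed + 10000L
      cand <- train_teacher(tasks[[i]], cfg)
      better <- (cand$converged && cand$policy_optimal_everywhere) >=
        (tch$converged && tch$policy_optimal_everywhere) &&
        cand$bellman_mse < tch$bellman_mse
      if (better || (!tch$converged && cand$converged)) tch <- cand
    }
    out[[i]] <- tch
    if (progress && i %% 25L == 0L)
      message(sprintf("  trained %d/%d teachers", i, length(tasks)))
  }
  out
}

#' Write a Q-matrix to CSV
#'
#' One row per state with columns x, y, q_right, q_up, q_left, q_down.
#'
#' @param q n x n x 4 array.
#' @param path output file.
#' @return path, invisibly.
#' @export
qmatrix_to_csv <- function(q, path) {
  n <- dim(q)[1]
  tab <- qmatrix_to_qtab(q)
  xy <- t(vapply(seq_len(n * n), index_cell, integer(2), n_int = n))
  df <- data.frame(x = xy[, 1], y = xy[, 2], q_right = tab[, 1],
                   q_up = tab[, 2], q_left = tab[, 3], q_down = tab[, 4])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a teacher's Q-matrix to CSV with a JSON sidecar
#'
#' The sidecar records the task, configuration and seed that produced the
#' Q-matrix.
#'
#' @param teacher a trained \code{teacher}.
#' @param path CSV output path (sidecar gets \code{.json} appended).
#' @return path, invisibly.
#' @export
teacher_to_csv <- function(teacher, path) {
  qmatrix_to_csv(teacher$q, path)
  side <- list(
    task = list(interior_size = teacher$task$world$n_int,
                walls = unname(apply(teacher$task$world$walls, 1, as.list)),
                goal = as.list(teacher$task$goal)),
    config = unclass(teacher$config),
    seed = teacher$config$seed,
    converged = teacher$converged,
    s_opt = teacher$s_opt)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
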