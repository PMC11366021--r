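# Action coding used throughout: 1 = right, 2 = up, 3 = left, 4 = down.
ACTION_DX <- c(1L, 0L, -1L, 0L)
ACTION_DY <- c(0L, 1L, 0L, -1L)

#' Grid-world maze
#'
#' A square grid of interior size \code{n_int} x \code{n_int} surrounded by an
#' implicit impenetrable outer boundary.  A subset of interior cells may be
#' wall states.  Coordinates are 0-based, x to the right and y upwards; the
#' agent always starts in the bottom-left corner (0, 0).
#'
#' @param n_int interior side length (the paper's setting uses 4, i.e. a
#'   6 x 6 grid with its outer ring of walls).
#' @param walls integer matrix with columns x, y (possibly 0 rows) giving
#'   interior wall cells.
#' @param reward_step reward for a regular move (default -0.1).
#' @param reward_wall reward for bouncing off a wall or the boundary
#'   (default -0.5; replaces, not added to, the step reward).
#' @param reward_goal reward for reaching the goal (default +2).
#' @return an object of class \code{grid_world}.
#' @export
grid_world <- function(n_int = 4L, walls = NULL,
                       reward_step = -0.1, reward_wall = -0.5,
                       reward_goal = 2.0) {
  n_int <- as.integer(n_int)
  stopifnot(n_int >= 2L)
  if (is.null(walls)) walls <- matrix(integer(0), ncol = 2L)
  walls <- matrix(as.integer(walls), ncol = 2L)
  colnames(walls) <- c("x", "y")
  if (nrow(walls)) {
    stopifnot(all(walls >= 0L), all(walls < n_int))
    if (any(walls[, 1] == 0L & walls[, 2] == 0L))
      stop("walls must not include the start cell (0, 0)")
    if (anyDuplicated(walls)) stop("duplicate wall cells")
  }
  stopifnot(reward_goal > 0, reward_step < 0, reward_wall < reward_step)
  structure(list(n_int = n_int, walls = walls,
                 reward_step = reward_step, reward_wall = reward_wall,
                 reward_goal = reward_goal),
            class = "grid_world")
}

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf("<grid_world %dx%d, %d wall(s)>\n", x$n_int, x$n_int,
              nrow(x$walls)))
  invisible(x)
}

#' Maze-solving task
#'
#' A task is a world plus a goal location; the start is fixed at (0, 0).
#'
#' @param world a \code{\link{grid_world}}.
#' @param goal length-2 integer vector (x, y).
#' @param check if \code{TRUE}, verify that every non-wall cell is reachable
#'   from the start.
#' @return an object of class \code{maze_task}.
#' @export
maze_task <- function(world, goal, check = TRUE) {
  goal <- as.integer(goal)
  stopifnot(inherits(world, "grid_world"), length(goal) == 2L,
            all(goal >= 0L), all(goal < world$n_int))
  if (goal[1] == 0L && goal[2] == 0L) stop("goal must differ from the start")
  if (cell_is_wall(world, goal[1], goal[2])) stop("goal must not be a wall")
  task <- structure(list(world = world, goal = goal, start = c(0L, 0L)),
                    class = "maze_task")
  if (check && !is_fully_accessible(world))
    stop("world has inaccessible non-wall cells")
  task
}

#' @export
print.maze_task <- function(x, ...) {
  w <- x$world$walls
  wtxt <- if (nrow(w)) paste(apply(w, 1, paste, collapse = ","),
                             collapse = "; ") else "none"
  cat(sprintf("<maze_task %dx%d goal=(%d,%d) walls: %s>\n",
              x$world$n_int, x$world$n_int, x$goal[1], x$goal[2], wtxt))
  invisible(x)
}

cell_is_wall <- function(world, x, y) {
  w <- world$walls
  nrow(w) > 0L && any(w[, 1] == x & w[, 2] == y)
}

# 1-based linear index of cell (x, y), row-major in y then x
cell_index <- function(x, y, n_int) 1L + x + y * n_int

index_cell <- function(i, n_int) {
  i <- i - 1L
  c(i %% n_int, i %/% n_int)
}

#' Single environment step
#'
#' Applies an action at a state.  Moving into an interior wall or the outer
#' boundary bounces the agent back to its current cell with the wall reward;
#' moving onto the goal terminates the episode with the goal reward; any
#' other move yields the step reward.
#'
#' @param task a \code{\link{maze_task}}.
#' @param state length-2 integer (x, y); must not be a wall or the goal.
#' @param action integer 1-4 (right, up, left, down).
#' @return list with \code{state}, \code{action}, \code{reward},
#'   \code{next_state}, \code{terminal}.
#' @export
maze_step <- function(task, state, action) {
  state <- as.integer(state)
  world <- task$world
  if (cell_is_wall(world, state[1], state[2]))
    stop("invalid state: wall cell")
  if (all(state == task$goal)) stop("invalid state: goal cell")
  action <- as.integer(action)
  stopifnot(action >= 1L, action <= 4L)
  nx <- state[1] + ACTION_DX[action]
  ny <- state[2] + ACTION_DY[action]
  n <- world$n_int
  if (nx < 0L || ny < 0L || nx >= n || ny >= n ||
      cell_is_wall(world, nx, ny)) {
    list(state = state, action = action, reward = world$reward_wall,
         next_state = state, terminal = FALSE)
  } else if (nx == task$goal[1] && ny == task$goal[2]) {
    list(state = state, action = action, reward = world$reward_goal,
         next_state = c(nx, ny), terminal = TRUE)
  } else {
    list(state = state, action = action, reward = world$reward_step,
         next_state = c(nx, ny), terminal = FALSE)
  }
}

# BFS distances from start over non-wall cells; Inf where unreachable.
bfs_distances <- function(world) {
  n <- world$n_int
  wall <- rep(FALSE, n * n)
  if (nrow(world$walls))
    wall[cell_index(world$walls[, 1], world$walls[, 2], n)] <- TRUE
  dist <- rep(Inf, n * n)
  start <- cell_index(0L, 0L, n)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    xy <- index_cell(cur, n)
    for (a in 1:4) {
      nx <- xy[1] + ACTION_DX[a]; ny <- xy[2] + ACTION_DY[a]
      if (nx < 0L || ny < 0L || nx >= n || ny >= n) next
      ni <- cell_index(nx, ny, n)
      if (wall[ni] || is.finite(dist[ni])) next
      dist[ni] <- dist[cur] + 1
      queue <- c(queue, ni)
    }
  }
  dist
}

#' Is every non-wall cell reachable from the start?
#'
#' @param world a \code{\link{grid_world}}.
#' @return logical.
#' @export
is_fully_accessible <- function(world) {
  n <- world$n_int
  wall <- rep(FALSE, n * n)
  if (nrow(world$walls))
    wall[cell_index(world$walls[, 1], world$walls[, 2], n)] <- TRUE
  d <- bfs_distances(world)
  all(is.finite(d[!wall]))
}

#' Shortest-path length from start to goal
#'
#' Breadth-first search step count avoiding walls.  This value (s_opt) is
#' both the optimal episode length and the step budget scale used in
#' training (k_opt) and evaluation (2 s_opt).
#'
#' @param task a \code{\link{maze_task}}.
#' @return integer step count.
#' @export
shortest_path_length <- function(task) {
  d <- bfs_distances(task$world)
  s <- d[cell_index(task$goal[1], task$goal[2], task$world$n_int)]
  if (!is.finite(s)) stop("infeasible task: goal unreachable from start")
  as.integer(s)
}

# all interior cells except start, row-major (y outer, x inner)
non_start_cells <- function(n_int) {
  g <- expand.grid(x = 0:(n_int - 1L), y = 0:(n_int - 1L))
  g <- as.matrix(g[!(g$x == 0L & g$y == 0L), , drop = FALSE])
  storage.mode(g) <- "integer"
  g
}

#' Enumerate the training task suite
#'
#' All tasks over the zero-wall world and every one-wall world: the wall may
#' occupy any non-start cell, and the goal any remaining non-start, non-wall
#' cell.  For interior size n this yields (n^2-1)^2 tasks.  Ordering is
#' deterministic: the empty world first, then walls in row-major order, and
#' goals in row-major order within each world.
#'
#' @param n_int interior side length.
#' @return list of \code{\link{maze_task}} objects; each carries attributes
#'   \code{world_id} and \code{task_id}.
#' @export
enumerate_training_tasks <- function(n_int = 4L) {
  n_int <- as.integer(n_int)
  stopifnot(n_int >= 2L)
  cells <- non_start_cells(n_int)
  worlds <- c(list(grid_world(n_int)),
              lapply(seq_len(nrow(cells)), function(i)
                grid_world(n_int, walls = cells[i, , drop = FALSE])))
  tasks <- list()
  tid <- 0L
  for (wi in seq_along(worlds)) {
    w <- worlds[[wi]]
    for (gi in seq_len(nrow(cells))) {
      g <- cells[gi, ]
      if (cell_is_wall(w, g[1], g[2])) next
      tid <- tid + 1L
      tk <- maze_task(w, g, check = FALSE)
      attr(tk, "world_id") <- wi
      attr(tk, "task_id") <- tid
      tasks[[tid]] <- tk
    }
  }
  tasks
}

#' Enumerate the held-out test task suite
#'
#' All two-wall worlds whose non-wall cells remain fully reachable from the
#' start, each paired with every valid goal.  For interior size 4 this gives
#' 101 worlds and 1313 tasks.
#'
#' @param n_int interior side length.
#' @return list of \code{\link{maze_task}} objects with \code{world_id} and
#'   \code{task_id} attributes.
#' @export
enumerate_test_tasks <- function(n_int = 4L) {
  n_int <- as.integer(n_int)
  cells <- non_start_cells(n_int)
  nc <- nrow(cells)
  tasks <- list()
  tid <- 0L; wid <- 0L
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    w <- grid_world(n_int, walls = cells[c(i, j), , drop = FALSE])
    if (!is_fully_accessible(w)) next
    wid <- wid + 1L
    for (gi in seq_len(nc)) {
      g <- cells[gi, ]
      if (gi == i || gi == j) next
      tid <- tid + 1L
      tk <- maze_task(w, g, check = FALSE)
      attr(tk, "world_id") <- wid
      attr(tk, "task_id") <- tid
      tasks[[tid]] <- tk
    }
  }
  attr(tasks, "n_worlds") <- wid
  tasks
}

#' Serialize a task list to JSON
#'
#' @param tasks list of \code{\link{maze_task}}.
#' @param path file path; if \code{NULL} the JSON string is returned.
#' @return path (invisibly) or a JSON string.
#' @export
tasks_to_json <- function(tasks, path = NULL) {
  rec <- lapply(seq_along(tasks), function(i) {
    tk <- tasks[[i]]
    list(task_id = i,
         world_id = attr(tk, "world_id"),
         interior_size = tk$world$n_int,
         walls = unname(apply(tk$world$walls, 1, as.list)),
         goal = as.list(tk$goal))
  })
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
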