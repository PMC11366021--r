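test_that("environment steps follow the bounce/step/goal reward scheme", {
  w <- grid_world(4)
  tk <- maze_task(w, c(3, 3))

  # boundary bounce from the start
  tr <- maze_step(tk, c(0, 0), 3)  # left
  expect_equal(tr$next_state, c(0, 0))
  expect_equal(tr$reward, -0.5)
  expect_false(tr$terminal)

  # free move
  tr <- maze_step(tk, c(0, 0), 1)  # right
  expect_equal(tr$next_state, c(1, 0))
  expect_equal(tr$reward, -0.1)

  # stepping onto the goal terminates with +2
  tr <- maze_step(tk, c(3, 2), 2)  # up into (3,3)
  expect_true(tr$terminal)
  expect_equal(tr$reward, 2.0)

  # interior wall bounce
  wt <- maze_task(grid_world(4, walls = rbind(c(1, 0))), c(3, 3))
  tr <- maze_step(wt, c(0, 0), 1)
  expect_equal(tr$next_state, c(0, 0))
  expect_equal(tr$reward, -0.5)

  # invalid source states
  expect_error(maze_step(wt, c(1, 0), 1), "wall")
  expect_error(maze_step(tk, c(3, 3), 1), "goal")
})

test_that("step never returns a wall cell and terminal iff goal", {
  tk <- maze_task(grid_world(4, walls = rbind(c(2, 1))), c(1, 3))
  for (x in 0:3) for (y in 0:3) {
    if ((x == 2 && y == 1) || (x == 1 && y == 3)) next
    for (a in 1:4) {
      tr <- maze_step(tk, c(x, y), a)
      expect_false(all(tr$next_state == c(2, 1)))
      expect_identical(tr$terminal, all(tr$next_state == c(1, 3)))
    }
  }
})

test_that("training-task enumeration matches the closed form", {
  for (n in 2:4) {
    tasks <- enumerate_training_tasks(n)
    expect_length(tasks, (n^2 - 1)^2)
  }
  tasks <- enumerate_training_tasks(4)
  expect_length(tasks, 225)
  wids <- vapply(tasks, attr, integer(1), "world_id")
  expect_equal(length(unique(wids)), 16)       # empty world + 15 one-wall
  expect_equal(sum(wids == 1L), 15)            # empty world: 15 goals
  expect_true(all(table(wids[wids > 1]) == 14))  # one-wall worlds: 14 each

  # deterministic ordering
  t2 <- enumerate_training_tasks(4)
  expect_identical(tasks_to_json(tasks), tasks_to_json(t2))
})

test_that("test-task enumeration filters inaccessible worlds", {
  tasks <- enumerate_test_tasks(4)
  expect_equal(attr(tasks, "n_worlds"), 101)
  expect_length(tasks, 1313)
  wids <- vapply(tasks, attr, integer(1), "world_id")
  expect_true(all(table(wids) == 13))          # 13 goals per retained world
})

test_that("accessibility filter agrees with independent connectivity check", {
  # brute force over all C(15,2) = 105 two-wall arrangements
  cells <- mazelang:::non_start_cells(4L)
  pass <- 0L
  for (i in 1:14) for (j in (i + 1):15) {
    w <- grid_world(4, walls = cells[c(i, j), , drop = FALSE])
    ours <- is_fully_accessible(w)
    # oracle: connectivity of the non-wall cell graph via igraph
    wall_set <- paste(cells[c(i, j), 1], cells[c(i, j), 2])
    free <- expand.grid(x = 0:3, y = 0:3)
    free <- free[!(paste(free$x, free$y) %in% wall_set), ]
    edges <- c()
    for (r in seq_len(nrow(free))) for (d in list(c(1, 0), c(0, 1))) {
      nb <- c(free$x[r] + d[1], free$y[r] + d[2])
      if (paste(nb[1], nb[2]) %in% paste(free$x, free$y))
        edges <- c(edges, paste(free$x[r], free$y[r]), paste(nb[1], nb[2]))
    }
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                     directed = FALSE)
    oracle <- igraph::components(g)$no == 1 &&
      igraph::vcount(g) == nrow(free)
    expect_identical(ours, oracle)
    pass <- pass + ours
  }
  expect_equal(pass, 101L)                     # 4 of 105 must fail
})

test_that("sealed-off start is detected", {
  w <- grid_world(4, walls = rbind(c(0, 1), c(1, 0)))
  expect_false(is_fully_accessible(w))
  expect_true(is_fully_accessible(grid_world(4)))
})

test_that("shortest paths match Manhattan distance and exhaustive search", {
  empty <- grid_world(4)
  expect_equal(shortest_path_length(maze_task(empty, c(3, 3))), 6)
  expect_equal(shortest_path_length(maze_task(empty, c(1, 0))), 1)

  # with a wall: exhaustive breadth-first enumeration of action sequences
  tk <- maze_task(grid_world(4, walls = rbind(c(1, 0))), c(3, 0))
  brute <- local({
    frontier <- list(c(0, 0))
    seen <- "0 0"
    steps <- 0
    repeat {
      steps <- steps + 1
      nxt <- list()
      for (s in frontier) for (a in 1:4) {
        tr <- maze_step(tk, s, a)
        if (tr$terminal) return(steps)
        key <- paste(tr$next_state, collapse = " ")
        if (!(key %in% seen)) { seen <- c(seen, key); nxt <- c(nxt, list(tr$next_state)) }
      }
      frontier <- nxt
    }
  })
  expect_equal(shortest_path_length(tk), brute)

  # every enumerated task is solvable within the state budget
  tasks <- enumerate_training_tasks(3)
  s <- vapply(tasks, shortest_path_length, integer(1))
  expect_true(all(s >= 1 & s <= 8))
})

test_that("world and task constructors validate their invariants", {
  expect_error(grid_world(4, walls = rbind(c(0, 0))), "start")
  expect_error(grid_world(4, walls = rbind(c(4, 0))))
  expect_error(maze_task(grid_world(4), c(0, 0)), "start")
  expect_error(maze_task(grid_world(4, walls = rbind(c(2, 2))), c(2, 2)),
               "wall")
})

test_that("task JSON serialization round-trips the fields", {
  tasks <- enumerate_training_tasks(3)[c(1, 20, 50)]
  js <- jsonlite::fromJSON(tasks_to_json(tasks), simplifyVector = FALSE)
  expect_length(js, 3)
  expect_equal(js[[2]]$interior_size, 3)
  expect_equal(unlist(js[[2]]$goal), tasks[[2]]$goal)
})
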