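# Evaluation scenarios and baselines: informed/misinformed students versus
# random walkers across goal-pattern generalization scenarios, t-tests over
# language seeds, the close-the-loop ("telephone") protocol, and language
# filtering.

#' Goal-pattern masks
#'
#' Seven boolean masks over interior cells selecting the trained goal
#' locations.  Pattern i is the checkerboard (cells with even x+y, start
#' excluded); ii rows, iii columns, iv near half, v far half, vi border,
#' vii center are plausible reconstructions of the remaining patterns and
#' are configurable here.
#'
#' @param id pattern number 1-7 (i-vii).
#' @param n_int interior size.
#' @return logical n x n matrix indexed [x+1, y+1]; start is always FALSE.
#' @export
goal_pattern <- function(id, n_int = 4L) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > 7L) stop("pattern id must be 1..7")
  x <- matrix(rep(0:(n_int - 1L), n_int), n_int, n_int)
  y <- t(x)
  m <- switch(as.integer(id),
    (x + y) %% 2L == 0L,                       # i   checkerboard
    y %% 2L == 0L,                             # ii  every other row
    x %% 2L == 0L,                             # iii every other column
    x + y <= (n_int - 1L),                     # iv  near half (around start)
    x + y >= n_int,                            # v   far half
    x == 0L | y == 0L | x == n_int - 1L | y == n_int - 1L,  # vi border
    x > 0L & y > 0L & x < n_int - 1L & y < n_int - 1L)      # vii center
  m[1, 1] <- FALSE
  m
}

goal_in_pattern <- function(task, mask) mask[task$goal[1] + 1L, task$goal[2] + 1L]

#' Baseline walker policy
#'
#' @param task a \code{\link{maze_task}}.
#' @param kind \code{"random"} (uniform over the four actions) or
#'   \code{"smart_random"} (uniform over actions that do not hit a wall or
#'   the boundary; falls back to uniform if every move is blocked).
#' @return n_states x 4 row-stochastic policy matrix.
#' @export
walker_policy <- function(task, kind = c("random", "smart_random")) {
  kind <- match.arg(kind)
  tt <- task_tables(task)
  if (kind == "random") return(matrix(0.25, tt$n_states, 4L))
  ok <- tt$nxt != matrix(seq_len(tt$n_states), tt$n_states, 4L)  # non-bounce
  ok[rowSums(ok) == 0L, ] <- TRUE
  ok / rowSums(ok)
}

# softmax policy of a student given a message, as n_states x 4
student_policy <- function(net, m, world) {
  row_softmax(qmatrix_to_qtab(student_q_matrix(net, m, world)))
}

#' Per-task solve rates for a student under a message set
#'
#' @param net student network.
#' @param messages matrix, one message per task row.
#' @param tasks list of tasks.
#' @param budget_factor step budget multiplier on s_opt.
#' @return numeric vector of analytic solve rates.
#' @export
student_solve_rates <- function(net, messages, tasks, budget_factor = 2) {
  vapply(seq_along(tasks), function(i) {
    solve_rate(student_policy(net, messages[i, ], tasks[[i]]$world),
               tasks[[i]], budget_factor)
  }, numeric(1))
}

# misinformed message assignment: for each task draw a different task index
misinform <- function(n_tasks, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(n_tasks), function(i)
    sample(setdiff(seq_len(n_tasks), i), 1L), integer(1))
}

#' Evaluate students across scenarios, patterns, and agents
#'
#' For each trained language, a student is trained (against the frozen
#' language's messages) on the tasks whose goals lie in each pattern; solve
#' rates are then measured for four agents (informed, misinformed, random
#' walker, smart random walker) in up to four scenarios: trained tasks with
#' trained goals, trained mazes with unknown goals, new two-wall mazes with
#' trained and with unknown goals.
#'
#' @param languages list of \code{trained_language} objects (one per seed).
#' @param teacher_qs list of teacher Q-matrices for \code{tasks}.
#' @param tasks training task list (zero- and one-wall worlds).
#' @param patterns integer vector of pattern ids (1-7).
#' @param scenarios character subset of \code{c("trained_goals",
#'   "unknown_goals", "new_mazes_trained", "new_mazes_unknown")}.
#' @param test_teacher_qs,test_tasks Q-matrices and tasks for the held-out
#'   two-wall mazes (required for the new-maze scenarios).
#' @param student_cfg \code{\link{student_config}} for the per-pattern
#'   students.
#' @param eval_seed seed for the misinformed message draw.
#' @return object of class \code{solve_rate_report}: \code{cells} (tidy
#'   per-language data.frame) and \code{summary} (mean, SEM and p-values per
#'   scenario x pattern x agent).
#' @export
evaluate_grid <- function(languages, teacher_qs, tasks, patterns = 1:7,
                          scenarios = c("trained_goals", "unknown_goals"),
                          test_teacher_qs = NULL, test_tasks = NULL,
                          student_cfg = student_config(),
                          eval_seed = 1L) {
  scenarios <- match.arg(scenarios, c("trained_goals", "unknown_goals",
                                      "new_mazes_trained",
                                      "new_mazes_unknown"),
                         several.ok = TRUE)
  needs_test <- any(grepl("new_mazes", scenarios))
  if (needs_test && (is.null(test_tasks) || is.null(test_teacher_qs)))
    stop("new-maze scenarios require test_tasks and test_teacher_qs")
  n_int <- tasks[[1]]$world$n_int
  rows <- list()
  for (li in seq_along(languages)) {
    lang <- languages[[li]]
    msgs <- encode(lang$net, teacher_qs)
    test_msgs <- if (needs_test) encode(lang$net, test_teacher_qs)
    for (p in patterns) {
      mask <- goal_pattern(p, n_int)
      train_sel <- vapply(tasks, goal_in_pattern, logical(1), mask = mask)
      scfg <- student_cfg
      scfg$seed <- student_cfg$seed + 1000L * li + p
      stu <- train_student(msgs[train_sel, , drop = FALSE],
                           tasks[train_sel], scfg)$net
      for (sc in scenarios) {
        if (sc %in% c("trained_goals", "unknown_goals")) {
          sel <- if (sc == "trained_goals") train_sel else !train_sel
          sc_tasks <- tasks[sel]; sc_msgs <- msgs[sel, , drop = FALSE]
        } else {
          tsel <- vapply(test_tasks, goal_in_pattern, logical(1), mask = mask)
          if (sc == "new_mazes_unknown") tsel <- !tsel
          sc_tasks <- test_tasks[tsel]
          sc_msgs <- test_msgs[tsel, , drop = FALSE]
        }
        if (!length(sc_tasks)) next
        mis <- misinform(length(sc_tasks), eval_seed + 17L * li + p)
        informed <- mean(student_solve_rates(stu, sc_msgs, sc_tasks))
        misinformed <- mean(student_solve_rates(
          stu, sc_msgs[mis, , drop = FALSE], sc_tasks))
        rnd <- mean(vapply(sc_tasks, function(tk)
          solve_rate(walker_policy(tk, "random"), tk), numeric(1)))
        smart <- mean(vapply(sc_tasks, function(tk)
          solve_rate(walker_policy(tk, "smart_random"), tk), numeric(1)))
        rows[[length(rows) + 1L]] <- data.frame(
          language = li, scenario = sc, pattern = p,
          agent = c("informed", "misinformed", "random", "smart_random"),
          solve_rate = c(informed, misinformed, rnd, smart),
          n_tasks = length(sc_tasks))
      }
    }
  }
  cells <- do.call(rbind, rows)
  structure(list(cells = cells, summary = summarize_solve_rates(cells)),
            class = "solve_rate_report")
}

# aggregate per-language cells into mean/SEM and attach t-tests
summarize_solve_rates <- function(cells) {
  key <- unique(cells[c("scenario", "pattern")])
  out <- list()
  for (r in seq_len(nrow(key))) {
    sub <- cells[cells$scenario == key$scenario[r] &
                   cells$pattern == key$pattern[r], ]
    ag <- stats::aggregate(solve_rate ~ agent, sub, mean)
    sem <- stats::aggregate(solve_rate ~ agent, sub,
                            function(v) stats::sd(v) / sqrt(length(v)))
    st <- significance_tests(sub)
    out[[r]] <- data.frame(scenario = key$scenario[r],
                           pattern = key$pattern[r],
                           agent = ag$agent, mean = ag$solve_rate,
                           sem = ifelse(is.na(sem$solve_rate), 0,
                                        sem$solve_rate),
                           p_vs_misinformed = st$p_vs_misinformed,
                           p_vs_smart_random = st$p_vs_smart_random)
  }
  do.call(rbind, out)
}

#' @export
print.solve_rate_report <- function(x, ...) {
  cat("<solve_rate_report>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Paired significance tests across language seeds
#'
#' Two-sided t-test of the informed student against the misinformed one and
#' a one-sided (greater) t-test against the smart random walker, Bonferroni
#' corrected by the number of simultaneous comparisons.
#'
#' @param cells tidy per-language solve-rate rows for one scenario/pattern
#'   cell (columns \code{language}, \code{agent}, \code{solve_rate}).
#' @param bonferroni correction factor (default: number of tests = 2).
#' @return list: \code{p_vs_misinformed}, \code{p_vs_smart_random}
#'   (corrected, capped at 1; NA with fewer than 2 seeds; degenerate
#'   zero-variance pairs give p = 1 with a flag).
#' @export
significance_tests <- function(cells, bonferroni = 2) {
  get <- function(agent) {
    v <- cells[cells$agent == agent, ]
    v[order(v$language), "solve_rate"]
  }
  inf <- get("informed"); mis <- get("misinformed")
  smart <- get("smart_random")
  safe_t <- function(x, y, alternative) {
    if (length(x) < 2L) return(NA_real_)
    if (stats::sd(x - y) == 0)
      return(if (alternative == "greater" && mean(x) > mean(y)) 0 else 1)
    stats::t.test(x, y, paired = TRUE, alternative = alternative)$p.value
  }
  p1 <- safe_t(inf, mis, "two.sided")
  p2 <- safe_t(inf, smart, "greater")
  list(p_vs_misinformed = min(1, p1 * bonferroni),
       p_vs_smart_random = min(1, p2 * bonferroni))
}

#' Close-the-loop protocol
#'
#' The student's own task representations (its Q-matrices computed with the
#' teacher-derived messages, wall rows zeroed to match the teacher
#' convention) are encoded by the frozen language into "student messages";
#' the student is then re-evaluated when given its own messages (informed)
#' or a random other task's student message (misinformed).
#'
#' @param student a trained student network.
#' @param language a \code{trained_language} (trained with feedback, then
#'   frozen).
#' @param tasks task list.
#' @param teacher_qs teacher Q-matrices for \code{tasks} (source of the
#'   first-pass messages).
#' @param eval_seed seed for the misinformed draw.
#' @return list of class \code{loop_result}: \code{student_messages},
#'   \code{rates} (per-task informed/misinformed/walker rates with teacher
#'   and student messages), \code{means}.
#' @export
close_the_loop <- function(student, language, tasks, teacher_qs,
                           eval_seed = 1L) {
  msgs <- encode(language$net, teacher_qs)
  n <- length(tasks)
  n_int <- tasks[[1]]$world$n_int
  student_qs <- lapply(seq_len(n), function(i) {
    q <- student_q_matrix(student, msgs[i, ], tasks[[i]]$world)
    tt <- task_tables(tasks[[i]])
    qt <- qmatrix_to_qtab(q)
    qt[tt$wall, ] <- 0
    qtab_to_qmatrix(qt, n_int)
  })
  smsgs <- encode(language$net, student_qs)
  mis <- misinform(n, eval_seed)
  rates <- data.frame(
    task = seq_len(n),
    informed_teacher = student_solve_rates(student, msgs, tasks),
    informed_student = student_solve_rates(student, smsgs, tasks),
    misinformed_student = student_solve_rates(
      student, smsgs[mis, , drop = FALSE], tasks),
    random = vapply(tasks, function(tk)
      solve_rate(walker_policy(tk, "random"), tk), numeric(1)),
    smart_random = vapply(tasks, function(tk)
      solve_rate(walker_policy(tk, "smart_random"), tk), numeric(1)))
  structure(list(student_messages = smsgs, student_qs = student_qs,
                 rates = rates, means = colMeans(rates[-1])),
            class = "loop_result")
}

#' @export
print.loop_result <- function(x, ...) {
  cat("<loop_result>\n")
  print(round(x$means, 3))
  invisible(x)
}

#' Filter languages by informed-student advantage
#'
#' Retains a language iff the informed student's mean performance on the
#' trained tasks strictly exceeds both the misinformed student's and the
#' random walker's.
#'
#' @param loop_results data.frame with one row per language and columns
#'   \code{informed}, \code{misinformed}, \code{random} (mean trained-task
#'   performances).
#' @return logical vector: which languages are retained.
#' @export
filter_languages <- function(loop_results) {
  with(loop_results,
       informed > pmax(misinformed, random))
}
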