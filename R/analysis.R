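# Representation-space analytics: within/between group variance
# decomposition with an F test, spatial task distances and topographic
# similarity, and plug-in Shannon entropy of binned 2-PC projections.

#' Within- and between-group variance of labeled messages
#'
#' Sum-of-squares decomposition over groups of message vectors:
#' \code{Var_within = sum_i sum_j ||m_ij - mbar_i||^2},
#' \code{Var_between = sum_i M_i ||mbar_i - mbar||^2}, and the ratio
#' \code{beta = Var_between / (Var_within + Var_between)} (near 1 when group
#' identity dominates the embedding).
#'
#' @param messages numeric matrix, one message per row.
#' @param labels group label per row.
#' @return list of class \code{variance_report}: \code{var_within},
#'   \code{var_between}, \code{beta}, \code{n_groups}, \code{n_messages}.
#' @export
group_variances <- function(messages, labels) {
  messages <- as.matrix(messages)
  stopifnot(nrow(messages) == length(labels), nrow(messages) >= 2L)
  labels <- as.factor(labels)
  grand <- colMeans(messages)
  vw <- 0; vb <- 0
  for (g in levels(labels)) {
    rows <- messages[labels == g, , drop = FALSE]
    mi <- colMeans(rows)
    vw <- vw + sum(sweep(rows, 2L, mi)^2)
    vb <- vb + nrow(rows) * sum((mi - grand)^2)
  }
  if (vw + vb == 0)
    stop("degenerate data: all messages identical, beta undefined")
  structure(list(var_within = vw, var_between = vb,
                 beta = vb / (vw + vb),
                 n_groups = nlevels(labels), n_messages = nrow(messages)),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf(
    "<variance_report: within %.4g, between %.4g, beta %.3f (N=%d, M=%d)>\n",
    x$var_within, x$var_between, x$beta, x$n_groups, x$n_messages))
  invisible(x)
}

#' F test for group mean differences
#'
#' \code{F = MS_B / MS_W} with \code{MS_B = Var_between/(N-1)} and
#' \code{MS_W = Var_within/(M-N)}; the critical value is the F-distribution
#' quantile at \code{1 - p_level}.
#'
#' @param report a \code{\link{group_variances}} result.
#' @param p_level significance level (default 0.05).
#' @return list: \code{f_value}, \code{f_crit}, \code{significant},
#'   \code{df1}, \code{df2}, \code{ms_b}, \code{ms_w}, and a
#'   \code{degenerate} flag when \code{MS_W = 0} (infinite F).
#' @export
f_test <- function(report, p_level = 0.05) {
  N <- report$n_groups; M <- report$n_messages
  df1 <- N - 1L; df2 <- M - N
  stopifnot(df1 >= 1L, df2 >= 1L)
  ms_b <- report$var_between / df1
  ms_w <- report$var_within / df2
  degenerate <- ms_w == 0
  f_value <- if (degenerate) Inf else ms_b / ms_w
  f_crit <- stats::qf(1 - p_level, df1, df2)
  list(f_value = f_value, f_crit = f_crit,
       significant = f_value > f_crit, df1 = df1, df2 = df2,
       ms_b = ms_b, ms_w = ms_w, degenerate = degenerate)
}

#' Topographic-similarity configuration
#'
#' Weight matrices applied to the wall and goal displacement vectors in the
#' spatial task distance, and the convention for comparing worlds with
#' unequal wall counts (a missing wall is placed at a virtual off-grid
#' position).
#'
#' @param wall_weight 2x2 weight matrix for wall displacements.
#' @param goal_weight 2x2 weight matrix for the goal displacement.
#' @param absent_wall virtual coordinates representing "no wall".
#' @return list of class \code{toposim_config}.
#' @export
toposim_config <- function(wall_weight = diag(2), goal_weight = diag(2),
                           absent_wall = c(-1, -1)) {
  stopifnot(all(dim(wall_weight) == 2L), all(dim(goal_weight) == 2L))
  structure(list(wall_weight = wall_weight, goal_weight = goal_weight,
                 absent_wall = absent_wall),
            class = "toposim_config")
}

#' Spatial distance between two tasks
#'
#' \code{||R_wall dw||_2 + ||R_goal dg||_2} where \code{dg} is the goal
#' displacement and \code{dw} stacks per-wall displacements under a
#' minimal-cost matching of the two wall sets (absent walls are matched to
#' the virtual position in \code{cfg$absent_wall}).
#'
#' @param t1,t2 \code{\link{maze_task}} objects of equal interior size.
#' @param cfg a \code{\link{toposim_config}}.
#' @return non-negative scalar.
#' @export
task_distance <- function(t1, t2, cfg = toposim_config()) {
  stopifnot(t1$world$n_int == t2$world$n_int)
  dg <- drop(cfg$goal_weight %*% (t1$goal - t2$goal))
  w1 <- t1$world$walls; w2 <- t2$world$walls
  k <- max(nrow(w1), nrow(w2))
  dist_w <- 0
  if (k > 0) {
    pad <- function(w) {
      if (nrow(w) < k)
        w <- rbind(w, matrix(rep(cfg$absent_wall, k - nrow(w)),
                             ncol = 2L, byrow = TRUE))
      w
    }
    w1 <- pad(w1); w2 <- pad(w2)
    # minimal-cost assignment over permutations (wall counts are tiny)
    perms <- all_permutations(k)
    best <- Inf
    for (pi in seq_len(nrow(perms))) {
      d <- w1 - w2[perms[pi, ], , drop = FALSE]
      dw <- as.vector(t(cfg$wall_weight %*% t(d)))
      best <- min(best, sqrt(sum(dw^2)))
    }
    dist_w <- best
  }
  dist_w + sqrt(sum(dg^2))
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Topographic similarity of a message set
#'
#' Computes all pairwise distances in message space (Euclidean) and in
#' meaning space -- spatial task distances for a task list, Frobenius
#' distances for a list of Q-matrices, Euclidean for a plain matrix -- and
#' returns the slope of the ordinary least-squares fit of message distance
#' on meaning distance (larger slope = more compositional mapping).
#'
#' @param messages numeric matrix, one message per row.
#' @param meanings list of \code{maze_task}s, list of Q-matrices, or a
#'   numeric matrix of meaning vectors.
#' @param cfg \code{\link{toposim_config}} used for task meanings.
#' @return list: \code{slope}, \code{intercept}, \code{message_dist},
#'   \code{meaning_dist}.
#' @export
topographic_similarity <- function(messages, meanings,
                                   cfg = toposim_config()) {
  messages <- as.matrix(messages)
  n <- nrow(messages)
  stopifnot(n >= 3L)
  dmsg <- as.vector(stats::dist(messages))
  if (is.list(meanings) && inherits(meanings[[1]], "maze_task")) {
    stopifnot(length(meanings) == n)
    dm <- numeric(n * (n - 1) / 2); idx <- 1L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dm[idx] <- task_distance(meanings[[i]], meanings[[j]], cfg)
      idx <- idx + 1L
    }
  } else if (is.list(meanings)) {        # Q-matrices: Frobenius norm
    V <- do.call(rbind, lapply(meanings, as.vector))
    dm <- as.vector(stats::dist(V))
  } else {
    dm <- as.vector(stats::dist(as.matrix(meanings)))
  }
  if (stats::var(dm) == 0) stop("zero variance in meaning distances")
  fit <- stats::lm.fit(cbind(1, dm), dmsg)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       message_dist = dmsg, meaning_dist = dm)
}

#' Binned Shannon entropy of a sample set
#'
#' Projects the samples onto their first two principal components, rescales
#' both axes by one common factor so (almost) all points lie in [-1, 1]^2,
#' partitions the square into \code{bins_per_axis^2} equal square bins, and
#' returns the Shannon entropy (bits) of the bin-occupancy frequencies.
#'
#' The common factor is the \code{norm_quantile} quantile (default 0.99) of
#' the per-point largest absolute PC coordinate; the few points beyond it
#' are clipped into the edge bins.  With a well-behaved cloud this equals
#' the maximum-coordinate normalization; under heavy tails it stops one or
#' two extreme samples from squashing the whole distribution into a single
#' bin, which would turn the statistic into a measure of the outlier rather
#' than of the ensemble.
#'
#' @param samples numeric matrix, one sample per row (>= 2 rows).
#' @param bins_per_axis number of bins along each PC axis.
#' @param norm_quantile quantile of the per-point max-abs PC coordinate
#'   used as the common rescaling factor (1 = strict maximum).
#' @return entropy in bits.
#' @export
binned_entropy <- function(samples, bins_per_axis, norm_quantile = 0.99) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) >= 2L, bins_per_axis >= 1L)
  pcs <- two_pcs(samples)
  r <- pmax(abs(pcs[, 1]), abs(pcs[, 2]))
  f <- as.numeric(stats::quantile(r, norm_quantile))
  if (f == 0) f <- max(r)
  if (f == 0) return(0)                   # all samples identical
  pcs <- pcs / f
  # map [-1, 1] to bins 1..B (right-closed; -1 and clipped points fall
  # into the boundary bins)
  B <- as.integer(bins_per_axis)
  bx <- pmin(pmax(ceiling((pcs[, 1] + 1) / 2 * B), 1L), B)
  by <- pmin(pmax(ceiling((pcs[, 2] + 1) / 2 * B), 1L), B)
  counts <- table(bx + B * (by - 1L))
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# first two principal components (centered; no per-axis rescaling)
two_pcs <- function(X) {
  X <- sweep(X, 2L, colMeans(X))
  if (ncol(X) == 1L) return(cbind(X, 0))
  sv <- svd(X, nu = 2L, nv = 2L)
  scores <- X %*% sv$v
  if (ncol(scores) < 2L) scores <- cbind(scores, 0)
  scores[, 1:2, drop = FALSE]
}

#' Entropy ordering across pipeline stages
#'
#' Computes the binned entropy of the teacher Q-matrices, the messages and
#' the student Q-matrices (each PCA-projected separately) over a range of
#' bin sizes, and reports whether the information-capacity ordering
#' teacher >= message >= student holds at each bin size.
#'
#' @param teacher_qs list of teacher Q-matrices.
#' @param messages message matrix (rows = tasks).
#' @param student_qs list of student Q-matrices for the same tasks.
#' @param bin_range integer vector of bins-per-axis values.
#' @return data.frame: bins, teacher, message, student, ordered (per-bin
#'   flag); attribute \code{mean_ordered} says whether the ordering holds
#'   for the bin-averaged entropies (the ranking of the whole curves).
#' @export
entropy_ordering_report <- function(teacher_qs, messages, student_qs,
                                    bin_range = 2:20) {
  Tq <- do.call(rbind, lapply(teacher_qs, as.vector))
  Sq <- do.call(rbind, lapply(student_qs, as.vector))
  M <- as.matrix(messages)
  out <- lapply(bin_range, function(b) {
    et <- binned_entropy(Tq, b)
    em <- binned_entropy(M, b)
    es <- binned_entropy(Sq, b)
    data.frame(bins = b, teacher = et, message = em, student = es,
               ordered = et >= em && em >= es)
  })
  out <- do.call(rbind, out)
  attr(out, "mean_ordered") <- mean(out$teacher) >= mean(out$message) &&
    mean(out$message) >= mean(out$student)
  out
}
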