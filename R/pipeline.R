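# Pipeline plumbing: a single configuration object, stage-by-stage
# execution with persisted artifacts, and tidy CSV/JSON exports.

#' Experiment configuration
#'
#' Bundles the maze, teacher, language, student and evaluation settings; a
#' config plus its seed determines every artifact.
#'
#' @param n_int maze interior size.
#' @param n_languages languages (seeds) per condition.
#' @param feedback train the language with student feedback.
#' @param patterns goal-pattern ids to evaluate.
#' @param scenarios evaluation scenarios.
#' @param teacher,language,student stage configs.
#' @param outdir output directory for artifacts.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(n_int = 4L, n_languages = 5L, feedback = TRUE,
                              patterns = 1:7,
                              scenarios = c("trained_goals", "unknown_goals"),
                              teacher = teacher_config(),
                              language = language_config(feedback = feedback),
                              student = student_config(),
                              outdir = tempfile("mazelang_run_"),
                              seed = 1L) {
  language$feedback <- feedback
  structure(list(n_int = as.integer(n_int),
                 n_languages = as.integer(n_languages),
                 feedback = feedback, patterns = patterns,
                 scenarios = scenarios, teacher = teacher,
                 language = language, student = student,
                 outdir = outdir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full pipeline
#'
#' Executes train-teachers, train-language (one per seed), evaluate and
#' analyze stages, persisting each stage's artifacts under
#' \code{config$outdir} so a rerun resumes from what exists.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param progress print stage progress.
#' @return list of class \code{run_manifest}: file inventory plus the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(config$outdir, ...)
  say <- function(...) if (progress) message(sprintf(...))

  tasks <- enumerate_training_tasks(config$n_int)
  tasks_to_json(tasks, pth("tasks.json"))

  teach_file <- pth("teachers.rds")
  if (file.exists(teach_file)) {
    teachers <- readRDS(teach_file)
    say("teachers: loaded %d from cache", length(teachers))
  } else {
    say("teachers: training %d", length(tasks))
    tcfg <- config$teacher; tcfg$seed <- config$seed * 1000L
    teachers <- train_teachers(tasks, tcfg, progress = progress)
    saveRDS(teachers, teach_file)
  }
  teacher_qs <- lapply(teachers, q_matrix)

  langs_file <- pth("languages.rds")
  if (file.exists(langs_file)) {
    langs <- readRDS(langs_file)
    say("languages: loaded %d from cache", length(langs))
  } else {
    langs <- lapply(seq_len(config$n_languages), function(i) {
      say("languages: training %d/%d", i, config$n_languages)
      lcfg <- config$language
      lcfg$seed <- config$seed * 100L + i
      train_language(teacher_qs, tasks, lcfg)
    })
    saveRDS(langs, langs_file)
  }
  for (i in seq_along(langs))
    messages_to_csv(langs[[i]]$messages, pth(sprintf("messages_%d.csv", i)),
                    labels = task_labels(tasks))

  say("evaluate: %d patterns x %d scenarios", length(config$patterns),
      length(config$scenarios))
  report <- evaluate_grid(langs, teacher_qs, tasks,
                          patterns = config$patterns,
                          scenarios = config$scenarios,
                          student_cfg = config$student,
                          eval_seed = config$seed)
  utils::write.csv(report$summary, pth("solve_rates.csv"), row.names = FALSE)

  say("analyze: variance/entropy/toposim")
  anova_tab <- message_anova_table(langs[[1]]$messages, tasks)
  utils::write.csv(anova_tab, pth("anova.csv"), row.names = FALSE)

  files <- setdiff(list.files(config$outdir), "manifest.json")
  checksums <- vapply(files, function(f)
    as.character(tools::md5sum(pth(f))), character(1))
  timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(
    list(files = files, checksums = unname(checksums),
         seed = config$seed, timestamp = timestamp),
    pth("manifest.json"), auto_unbox = TRUE)
  structure(
    list(config = config, files = c(files, "manifest.json"),
         checksums = checksums, timestamp = timestamp,
         teachers = teachers, languages = langs, report = report,
         anova = anova_tab),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest: %d artifact(s) in %s>\n", length(x$files),
              x$config$outdir))
  invisible(x)
}

# wall/goal label columns for a task list
task_labels <- function(tasks) {
  data.frame(
    wall = vapply(tasks, function(tk) {
      w <- tk$world$walls
      if (nrow(w) == 0L) "none" else
        paste(apply(w, 1, paste, collapse = ","), collapse = ";")
    }, character(1)),
    goal = vapply(tasks, function(tk)
      paste(tk$goal, collapse = ","), character(1)))
}

#' Message-space ANOVA table by wall and goal grouping
#'
#' Groups the messages of the single-wall-world tasks (the zero-wall world
#' is removed so both groupings share degrees of freedom) by wall position
#' and by goal location, and reports the variance decomposition and F test
#' for each grouping.
#'
#' @param messages message matrix for the full training task list.
#' @param tasks the corresponding task list.
#' @param p_level significance level.
#' @return data.frame: grouping, var_within, var_between, beta, f_value,
#'   f_crit, significant.
#' @export
message_anova_table <- function(messages, tasks, p_level = 0.05) {
  lab <- task_labels(tasks)
  keep <- lab$wall != "none"
  out <- lapply(c(wall = "wall", goal = "goal"), function(g) {
    gv <- group_variances(messages[keep, , drop = FALSE], lab[[g]][keep])
    ft <- f_test(gv, p_level)
    data.frame(grouping = g, var_within = gv$var_within,
               var_between = gv$var_between, beta = gv$beta,
               f_value = ft$f_value, f_crit = ft$f_crit,
               significant = ft$significant)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export a bundle of analysis artifacts
#'
#' Writes the ANOVA table, entropy curves and solve-rate summary as tidy
#' CSV files plus a JSON summary.
#'
#' @param manifest a \code{\link{run_pipeline}} result.
#' @param dir output directory (defaults to the run's outdir).
#' @return invisibly, the JSON summary path.
#' @export
export_report <- function(manifest, dir = manifest$config$outdir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(manifest$anova, file.path(dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$report$summary,
                   file.path(dir, "solve_rates.csv"), row.names = FALSE)
  summary <- list(
    n_teachers = length(manifest$teachers),
    teacher_convergence = mean(vapply(manifest$teachers, `[[`, logical(1),
                                      "converged")),
    n_languages = length(manifest$languages),
    anova = manifest$anova,
    solve_rates = manifest$report$summary)
  path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save a network checkpoint with a JSON manifest
#'
#' Writes the object to a single binary file plus a JSON sidecar recording
#' its class, configuration and seed, so a checkpoint directory remains
#' self-describing.
#'
#' @param object a trained object (\code{teacher}, \code{trained_language},
#'   \code{trained_student}, or any R object).
#' @param path file path for the checkpoint (the manifest gets
#'   \code{.json} appended).
#' @return path, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  cfg <- object$config
  manifest <- list(
    class = class(object)[1],
    config = if (!is.null(cfg)) unclass(cfg),
    seed = cfg$seed,
    saved = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    checksum = as.character(tools::md5sum(path)))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a checkpoint saved by \code{\link{save_checkpoint}}
#'
#' @param path checkpoint path.
#' @param verify check the manifest checksum before loading.
#' @return the stored object.
#' @export
load_checkpoint <- function(path, verify = TRUE) {
  mf_path <- paste0(path, ".json")
  if (verify && file.exists(mf_path)) {
    mf <- jsonlite::fromJSON(mf_path)
    if (!identical(as.character(tools::md5sum(path)), mf$checksum))
      stop("checkpoint checksum mismatch: ", path)
  }
  readRDS(path)
}

#' Read a message CSV written by \code{\link{messages_to_csv}}
#'
#' @param path CSV path.
#' @return list with \code{messages} (matrix) and \code{labels}
#'   (data.frame of any non-message columns).
#' @export
read_messages_csv <- function(path) {
  df <- utils::read.csv(path)
  mcols <- grep("^m_[0-9]+$", names(df))
  list(messages = as.matrix(df[mcols]),
       labels = df[setdiff(seq_along(df), mcols)])
}
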