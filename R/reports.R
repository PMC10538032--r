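#' Report writers
#'
#' All result tables are written as plain CSV with a deterministic
#' column order; reading a written file back reproduces the records.
#'
#' @name reports
NULL

write_csv_report <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the head-position report (rat stage 1)
#'
#' @param head_positions data.frame from [run_rat1_pipeline()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_head_report <- function(head_positions, path) {
  write_csv_report(head_positions[, c("frame", "x", "y", "status")], path)
}

#' Write the visit report and entry counts (rat stage 2)
#'
#' @param visits,entries from [run_rat2_pipeline()].
#' @param path output CSV path; the entry counts go to
#'   `<path>.entries.csv`.
#' @return the visit-report path, invisibly.
#' @export
write_visit_report <- function(visits, entries, path) {
  write_csv_report(visits[, c("compartment", "start_s", "end_s",
                              "duration_s")], path)
  write_csv_report(data.frame(compartment = names(entries),
                              entries = as.integer(entries)),
                   paste0(path, ".entries.csv"))
  invisible(path)
}

#' Write the monkey per-frame report
#'
#' @param report data.frame from [run_monkey_pipeline()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_monkey_report <- function(report, path) {
  write_csv_report(report, path)
}

#' Write the fused panda trajectory
#'
#' @param entries analyzed track entries (with velocity and stress).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectory_report <- function(entries, path) {
  cols <- intersect(c("frame_index", "camera_id", "x", "y", "attribute",
                      "v", "stress"), names(entries))
  write_csv_report(entries[, cols], path)
}

#' Write the stress-episode report
#'
#' Columns: `episode_id`, `class`, `start_time_s`, `end_time_s`,
#' `duration_s`, `camera`.
#'
#' @param episodes data.frame from [classify_stress()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_episode_report <- function(episodes, path) {
  write_csv_report(episodes[, c("episode_id", "class", "start_time_s",
                                "end_time_s", "duration_s", "camera")],
                   path)
}
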