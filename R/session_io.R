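#' Write a session bundle to disk
#'
#' The interchange bundle is one directory per session, all plain text:
#' `F.csv` / `Fneu.csv` (ROI-by-frame matrices, no header), `trials.csv`,
#' `licks.csv`, `ground_truth.json`, and `params.yaml` (frame rate, group,
#' schedule parameters).
#'
#' @param session Session list as produced by [synthesize_session()].
#' @param ground_truth Ground-truth list (optional, `NULL` to omit).
#' @param schedule A `trial_table`.
#' @param licks A `lick_train`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, ground_truth, schedule, licks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(session$F),
                     file.path(dir, "F.csv"), col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(session$Fneu),
                     file.path(dir, "Fneu.csv"), col.names = FALSE)
  data.table::fwrite(as.data.frame(schedule), file.path(dir, "trials.csv"))
  data.table::fwrite(data.frame(time_s = as.numeric(licks)),
                     file.path(dir, "licks.csv"))
  pars <- attr(schedule, "params")
  yaml::write_yaml(list(frame_rate = session$frame_rate,
                        group = session$group,
                        schedule_params = unclass(pars)),
                   file.path(dir, "params.yaml"))
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    gt$schedule_params <- NULL
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with `session`, `schedule`, `licks`, and `ground_truth`
#'   (`NULL` if absent).
#' @export
read_session_bundle <- function(dir) {
  stop_if_not(dir.exists(dir), paste("no session bundle at", dir))
  pars_raw <- yaml::read_yaml(file.path(dir, "params.yaml"))
  Fm <- as.matrix(data.table::fread(file.path(dir, "F.csv"), header = FALSE))
  Fneu <- as.matrix(data.table::fread(file.path(dir, "Fneu.csv"), header = FALSE))
  dimnames(Fm) <- dimnames(Fneu) <- NULL
  schedule <- as.data.frame(data.table::fread(file.path(dir, "trials.csv")))
  sp <- pars_raw$schedule_params
  if (!is.null(sp)) {
    sp$sound_levels <- unlist(sp$sound_levels)
    attr(schedule, "params") <- do.call(schedule_params, sp)
  }
  class(schedule) <- c("trial_table", "data.frame")
  licks <- as.data.frame(data.table::fread(file.path(dir, "licks.csv")))$time_s
  if (is.null(licks)) licks <- numeric(0)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(session = list(F = Fm, Fneu = Fneu, frame_rate = pars_raw$frame_rate,
                      group = pars_raw$group),
       schedule = schedule,
       licks = structure(sort(as.numeric(licks)), class = c("lick_train", "numeric")),
       ground_truth = gt)
}
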