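#' Minirhizotron imaging schedule
#'
#' Describes the observation process: the imaging session days on the study
#' timeline (day 0 = start of the second growing season; negative days reach
#' back into the first season), the season windows, and the total image frame
#' area against which root lengths are normalized. The default frame area is
#' 46 frames of 13 x 18 mm2 per tube.
#'
#' @param session_days Strictly increasing numeric vector of imaging days.
#' @param seasons Named list of `c(start, end)` windows (days); windows must
#'   not overlap.
#' @param frame_area Total imaged area per tube, m2.
#' @return Object of class `"imaging_schedule"`.
#' @export
imaging_schedule <- function(session_days,
                             seasons = list(),
                             frame_area = 46 * 0.013 * 0.018) {
  session_days <- as.numeric(session_days)
  if (length(session_days) == 0L) stop("schedule has no sessions", call. = FALSE)
  if (any(diff(session_days) <= 0)) {
    stop("session days must be strictly increasing", call. = FALSE)
  }
  if (frame_area <= 0) stop("frame_area must be positive", call. = FALSE)
  if (length(seasons)) {
    b <- do.call(rbind, lapply(seasons, function(w) {
      if (length(w) != 2L || w[1] >= w[2]) {
        stop("each season window must be c(start, end) with start < end",
             call. = FALSE)
      }
      w
    }))
    b <- b[order(b[, 1]), , drop = FALSE]
    if (nrow(b) > 1L && any(b[-1, 1] < b[-nrow(b), 2])) {
      stop("season windows overlap", call. = FALSE)
    }
  }
  structure(list(session_days = session_days, seasons = seasons,
                 frame_area = frame_area),
            class = "imaging_schedule")
}

#' @export
print.imaging_schedule <- function(x, ...) {
  cat(sprintf("Imaging schedule: %d sessions, day %g to %g, frame area %.6f m2\n",
              length(x$session_days), min(x$session_days), max(x$session_days),
              x$frame_area))
  for (nm in names(x$seasons)) {
    cat(sprintf("  %s: [%g, %g]\n", nm, x$seasons[[nm]][1], x$seasons[[nm]][2]))
  }
  invisible(x)
}

root_statuses <- c("absent", "live", "dead", "disappeared")

#' Longitudinal root observation set
#'
#' Per-root, per-session records from repeated minirhizotron imaging. Each
#' root carries one row per session with its live length and status. Valid
#' status trajectories are absent, then live, then optionally dead and/or
#' disappeared (dead always before disappeared); a root is never live again
#' after death, and length is zero whenever the root is not live. Roots
#' reclassified from short to long must carry the long class at every
#' session (retrospective reclassification).
#'
#' @param observations Data frame with columns `root_id`, `seedling_id`,
#'   `treatment`, `root_class` (`"short"` or `"long"`), `session_day`,
#'   `length_m`, `status`.
#' @param schedule An [imaging_schedule()].
#' @param truth Optional data frame of latent ground truth (from the
#'   synthetic generator): `root_id`, `appearance_day`, `death_day`.
#' @return Object of class `"root_obs_set"`.
#' @export
root_observation_set <- function(observations, schedule, truth = NULL) {
  stopifnot(inherits(schedule, "imaging_schedule"))
  req <- c("root_id", "seedling_id", "treatment", "root_class",
           "session_day", "length_m", "status")
  miss <- setdiff(req, names(observations))
  if (length(miss)) {
    stop("observations lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  obs <- as.data.frame(observations)[req]
  obs$status <- as.character(obs$status)
  obs$root_class <- as.character(obs$root_class)
  validate_root_observations(obs)
  obs <- obs[order(obs$root_id, obs$session_day), ]
  rownames(obs) <- NULL
  structure(list(observations = obs, schedule = schedule, truth = truth),
            class = "root_obs_set")
}

validate_root_observations <- function(obs) {
  bad_status <- setdiff(unique(obs$status), root_statuses)
  if (length(bad_status)) {
    stop("unknown status token(s): ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(obs$root_class), c("short", "long"))
  if (length(bad_class)) {
    stop("unknown root class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  for (id in unique(obs$root_id)) {
    r <- obs[obs$root_id == id, ]
    r <- r[order(r$session_day), ]
    if (anyDuplicated(r$session_day)) {
      problems <- c(problems, sprintf("root %s: duplicated session days", id))
      next
    }
    # phase code must be non-decreasing: absent(0) -> live(1) -> dead(2) ->
    # disappeared(3); additionally absent never follows live
    ph <- match(r$status, root_statuses) - 1L
    if (any(diff(ph) < 0L)) {
      problems <- c(problems,
                    sprintf("root %s: invalid status order (%s)", id,
                            paste(r$status, collapse = " -> ")))
    }
    if (any(r$length_m[r$status != "live"] != 0, na.rm = TRUE)) {
      problems <- c(problems,
                    sprintf("root %s: nonzero length on non-live session", id))
    }
    if (any(r$length_m < 0, na.rm = TRUE)) {
      problems <- c(problems, sprintf("root %s: negative length", id))
    }
    if (length(unique(r$root_class)) > 1L) {
      problems <- c(problems,
                    sprintf("root %s: class changes between sessions (reclassify retrospectively)", id))
    }
  }
  if (length(problems)) {
    stop("invalid root observations:\n  ",
         paste(utils::head(problems, 10L), collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.root_obs_set <- function(x, ...) {
  obs <- x$observations
  cat(sprintf("Root observation set: %d roots, %d seedlings, %d sessions\n",
              length(unique(obs$root_id)), length(unique(obs$seedling_id)),
              length(unique(obs$session_day))))
  cat(sprintf("  classes: %s; treatments: %s\n",
              paste(sort(unique(obs$root_class)), collapse = "/"),
              paste(sort(unique(obs$treatment)), collapse = ", ")))
  if (!is.null(x$truth)) cat("  latent ground truth attached\n")
  invisible(x)
}

#' Read a root observation table from CSV
#'
#' Expects a comma-separated, UTF-8 table with header columns `root_id`,
#' `seedling_id`, `treatment`, `root_class`, `session_day`, `length_m`,
#' `status`. Malformed trajectories are rejected with diagnostics naming the
#' offending roots.
#'
#' @param file Path to the CSV file.
#' @param schedule An [imaging_schedule()]; if `NULL`, one is built from the
#'   distinct session days in the file (default frame area).
#' @return A [root_observation_set()].
#' @export
read_root_table <- function(file, schedule = NULL) {
  obs <- utils::read.csv(file, stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(schedule)) {
    schedule <- imaging_schedule(sort(unique(obs$session_day)))
  }
  root_observation_set(obs, schedule)
}

#' Write a root observation table to CSV
#'
#' @param set A [root_observation_set()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_root_table <- function(set, file) {
  stopifnot(inherits(set, "root_obs_set"))
  utils::write.csv(set$observations, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Derive interval-censored death times from root observations
#'
#' For each root, the death time is bracketed by the last session at which it
#' was seen live (exclusive) and the first session at which it was seen dead
#' -- or disappeared, if it was never recorded dead (inclusive). Roots still
#' live at their final session are right-censored. Ages are measured from the
#' root's appearance reference: by default the midpoint of the appearance
#' interval (between the last session the root was absent and the first
#' session it was live), which is unbiased under uniform appearance within
#' the interval; `origin = "first-live"` uses the first live session instead.
#' A root already live at its first recorded session falls back to that
#' session as its reference.
#'
#' @param set A [root_observation_set()].
#' @param origin `"midpoint"` (default) or `"first-live"`.
#' @return An [ic_intervals()] set with columns `left`, `right`, `id`,
#'   `group` (treatment), plus `root_class`, `seedling_id`, and
#'   `appearance_ref` (study-day origin used). The origin rule is recorded in
#'   attribute `"age_origin"`.
#' @export
derive_intervals <- function(set, origin = c("midpoint", "first-live")) {
  stopifnot(inherits(set, "root_obs_set"))
  origin <- match.arg(origin)
  obs <- set$observations
  per_root <- split(obs, obs$root_id)
  rows <- lapply(per_root, function(r) {
    r <- r[order(r$session_day), ]
    live_days <- r$session_day[r$status == "live"]
    if (length(live_days) == 0L) {
      stop(sprintf("root %s has no live session", r$root_id[1]), call. = FALSE)
    }
    first_live <- min(live_days)
    last_live <- max(live_days)
    absent_before <- r$session_day[r$status == "absent" & r$session_day < first_live]
    ref <- if (origin == "midpoint" && length(absent_before)) {
      (max(absent_before) + first_live) / 2
    } else {
      first_live
    }
    end_days <- r$session_day[r$status %in% c("dead", "disappeared")]
    R <- if (length(end_days)) min(end_days) else Inf
    data.frame(
      left = last_live - ref,
      right = if (is.finite(R)) R - ref else Inf,
      id = r$root_id[1],
      group = r$treatment[1],
      root_class = r$root_class[1],
      seedling_id = r$seedling_id[1],
      appearance_ref = ref
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$id), ]
  class(out) <- c("ic_set", "data.frame")
  attr(out, "age_origin") <- origin
  out
}
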