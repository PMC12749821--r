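#' Trial-level behavioral data: session sets
#'
#' A `session_set` holds per-trial behavioral records grouped into sessions.
#' Each trial records a session identifier, a trial index (strictly increasing
#' within a session), a signed stimulus contrast in \[-1, 1\] (negative = left
#' stimulus, magnitude = contrast fraction), a binary choice (0 = left,
#' 1 = right), a signed reward (-1 = incorrect, +1 = correct) and, optionally,
#' the generating probability of a right-side stimulus for the current block
#' (`block_p_right` in \{0.5, 0.2, 0.8\}) and auxiliary covariates such as
#' `response_time`.
#'
#' @param trials data.frame with columns `session_id`, `trial_index`,
#'   `signed_contrast`, `choice`, `reward` and optionally `block_p_right`,
#'   `response_time` or other auxiliary per-trial columns.
#' @param contrast_sd optional numeric normalizer for signed contrast, stored
#'   with the data so test sessions can reuse a training-set constant.
#' @param validate if `TRUE` (default) basic value checks are run and violations
#'   raise errors.
#' @return an object of class `session_set`: a list with elements `sessions`
#'   (named list of per-session data.frames, each sorted by `trial_index`) and
#'   `contrast_sd`.
#' @seealso [read_trials()], [write_trials()], [validate_sessions()]
#' @export
session_set <- function(trials, contrast_sd = NULL, validate = TRUE) {
  stopifnot(is.data.frame(trials))
  mandatory <- c("session_id", "trial_index", "signed_contrast", "choice", "reward")
  missing_cols <- setdiff(mandatory, names(trials))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop("empty trial table: a session_set must contain trials")
  if (validate) {
    bad_choice <- which(!(trials$choice %in% c(0, 1)))
    if (length(bad_choice) > 0L) {
      stop("non-binary choice value at row(s): ",
           paste(head(bad_choice, 5L), collapse = ", "))
    }
    bad_reward <- which(!(trials$reward %in% c(-1, 1)))
    if (length(bad_reward) > 0L) {
      stop("reward must be -1 or +1; violation at row(s): ",
           paste(head(bad_reward, 5L), collapse = ", "))
    }
  }
  trials$session_id <- as.character(trials$session_id)
  sessions <- split(trials, factor(trials$session_id, levels = unique(trials$session_id)))
  sessions <- lapply(sessions, function(s) {
    s <- s[order(s$trial_index), , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  structure(list(sessions = sessions, contrast_sd = contrast_sd),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  n <- vapply(x$sessions, nrow, integer(1))
  cat("session_set:", length(n), "session(s),", sum(n), "trial(s)\n")
  cat("  trials per session:", paste(range(n), collapse = "-"), "\n")
  if (!is.null(x$contrast_sd)) {
    cat("  contrast normalizer:", format(x$contrast_sd, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.session_set <- function(x, ...) {
  out <- do.call(rbind, c(x$sessions, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
length.session_set <- function(x) length(x$sessions)

#' Number of trials in a session set
#' @param data a [session_set()].
#' @return integer total trial count.
#' @export
n_trials <- function(data) {
  stopifnot(inherits(data, "session_set"))
  sum(vapply(data$sessions, nrow, integer(1)))
}

#' Read a trial table from a delimited file
#'
#' The on-disk format is a flat delimited UTF-8 table with a header row; one
#' file may hold many sessions. Column order is free but names are fixed:
#' `session_id`, `trial_index`, `signed_contrast`, `choice`, `reward`, plus
#' optional `block_p_right`, `response_time` and any other auxiliary columns,
#' which are preserved.
#'
#' @param path path to an existing delimited text file.
#' @param sep field separator (default comma).
#' @return a [session_set()] grouped by `session_id`, each session sorted by
#'   `trial_index`.
#' @export
read_trials <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  trials <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  session_set(trials)
}

#' Write a session set to a delimited file
#'
#' Round-trip property: `read_trials(write_trials(x, p))` reproduces `x`
#' field-for-field, including auxiliary columns.
#'
#' @param data a [session_set()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "session_set"))
  if (length(data$sessions) == 0L) stop("refusing to write an empty session_set")
  df <- as.data.frame(data)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a session set and report violations
#'
#' Report-only check: trials are flagged, never dropped. Findings cover gaps in
#' `trial_index`, out-of-range contrasts, non-binary choices and rewards, and
#' invalid block probabilities.
#'
#' @param data a [session_set()] (possibly built with `validate = FALSE`).
#' @return data.frame with columns `session_id`, `finding`, `detail`; zero rows
#'   when the data are clean.
#' @export
validate_sessions <- function(data) {
  stopifnot(inherits(data, "session_set"))
  findings <- list()
  add <- function(sid, finding, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      session_id = sid, finding = finding, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (sid in names(data$sessions)) {
    s <- data$sessions[[sid]]
    d <- diff(s$trial_index)
    if (any(d <= 0)) add(sid, "order", "trial_index not strictly increasing")
    gaps <- which(d > 1)
    for (g in gaps) {
      add(sid, "gap", sprintf("trial_index gap %d -> %d",
                              s$trial_index[g], s$trial_index[g + 1L]))
    }
    bad <- which(!(s$choice %in% c(0, 1)))
    for (b in bad) add(sid, "range", sprintf("choice = %s at trial_index %d",
                                             format(s$choice[b]), s$trial_index[b]))
    bad <- which(!(s$reward %in% c(-1, 1)))
    for (b in bad) add(sid, "range", sprintf("reward = %s at trial_index %d",
                                             format(s$reward[b]), s$trial_index[b]))
    bad <- which(abs(s$signed_contrast) > 1 | !is.finite(s$signed_contrast))
    for (b in bad) add(sid, "range", sprintf("signed_contrast = %s at trial_index %d",
                                             format(s$signed_contrast[b]), s$trial_index[b]))
    if ("block_p_right" %in% names(s)) {
      ok <- is.na(s$block_p_right) | s$block_p_right %in% c(0.5, 0.2, 0.8)
      for (b in which(!ok)) {
        add(sid, "range", sprintf("block_p_right = %s at trial_index %d",
                                  format(s$block_p_right[b]), s$trial_index[b]))
      }
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(session_id = character(0), finding = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Concatenate session sets
#' @param ... session_set objects with disjoint session ids.
#' @return a combined [session_set()].
#' @export
c_sessions <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "session_set")))
  ids <- unlist(lapply(parts, function(p) names(p$sessions)))
  if (anyDuplicated(ids)) stop("duplicate session ids across inputs")
  session_set(do.call(rbind, lapply(parts, as.data.frame)))
}
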