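#' Per-trial criterion flags
#'
#' Evaluates one of the run criteria per trial: `"correct"` - the first
#' saccade after trial onset landed inside the 3x3-degree window (trials
#' with no resolvable first saccade are flagged `FALSE` and counted); or
#' `"microsaccade_free"` - no microsaccade onset inside the trial's
#' `interval` around onset.
#'
#' @param trials Trial log.
#' @param events Event table.
#' @param criterion `"correct"` or `"microsaccade_free"`.
#' @param interval Window around trial onset for the microsaccade-free
#'   criterion, ms.
#' @param first_sacc Optional precomputed [first_saccade_after_onset()].
#' @return Logical vector, one flag per trial, with the number of unresolved
#'   trials in `attr(, "n_unresolved")`.
#' @export
trial_flags <- function(trials, events,
                        criterion = c("correct", "microsaccade_free"),
                        interval = c(-200, 800), first_sacc = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "correct") {
    if (is.null(first_sacc)) {
      first_sacc <- first_saccade_after_onset(trials, events)
    }
    flags <- first_sacc$correct & first_sacc$resolved
    attr(flags, "n_unresolved") <- sum(!first_sacc$resolved)
    return(flags)
  }
  tsub <- zg_subject_of(trials); esub <- zg_subject_of(events)
  flags <- logical(nrow(trials))
  for (s in unique(tsub)) {
    trs <- which(tsub == s)
    tt <- sort(events$onset_ms[esub == s & events$class == "microsaccade"])
    if (!length(tt)) { flags[trs] <- TRUE; next }
    lo <- findInterval(trials$onset_ms[trs] + interval[1], tt, left.open = TRUE)
    hi <- findInterval(trials$onset_ms[trs] + interval[2], tt)
    flags[trs] <- hi == lo
  }
  attr(flags, "n_unresolved") <- 0L
  flags
}

#' Maximal-run table
#'
#' Counts maximal runs of consecutive `TRUE` flags: a run of length L counts
#' once toward length L and does not contribute to any shorter length
#' (sub-runs are not counted).  When `by` is given (e.g. block), runs are
#' computed within groups and never span a group boundary.
#'
#' @param flags Logical vector (empty allowed).
#' @param by Optional grouping vector of the same length; runs do not cross
#'   group boundaries.
#' @param criterion Label stored in the result.
#' @return Object of class `zg_run_table`: data frame `length`, `count`
#'   (maximal runs of that length), with attributes `longest`,
#'   `total_trials`, `n_false`, `criterion`.
#' @export
#' @examples
#' maximal_runs(c(TRUE, TRUE, TRUE, FALSE, TRUE))  # runs of 3 and 1
maximal_runs <- function(flags, by = NULL, criterion = "correct") {
  flags <- as.logical(flags)
  groups <- if (is.null(by)) list(flags) else split(flags, by)
  lens <- unlist(lapply(groups, function(f) {
    if (!length(f)) return(integer(0))
    r <- rle(f)
    r$lengths[r$values]
  }), use.names = FALSE)
  tab <- if (length(lens)) {
    tb <- table(lens)
    data.frame(length = as.integer(names(tb)), count = as.integer(tb))
  } else {
    data.frame(length = integer(0), count = integer(0))
  }
  structure(tab,
            longest = if (length(lens)) max(lens) else 0L,
            total_trials = length(flags),
            n_false = sum(!flags),
            criterion = criterion,
            class = c("zg_run_table", "data.frame"))
}

#' @export
as.data.frame.zg_run_table <- function(x, ...) {
  data.frame(length = x$length, count = x$count)
}

#' @export
print.zg_run_table <- function(x, ...) {
  cat(sprintf("<zg_run_table> criterion '%s': %d trials, longest run %d\n",
              attr(x, "criterion"), attr(x, "total_trials"),
              attr(x, "longest")))
  print(as.data.frame(x))
  invisible(x)
}
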