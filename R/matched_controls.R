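#' Incidence-density matched control selection
#'
#' Time-forward nested case-control sampling: for each case, controls are
#' drawn without replacement from the risk set at the case's event time
#' (subjects whose follow-up time is at least the case's event time),
#' exactly matching on enrollment year, ethnicity, and sex. One control
#' per case is selected on the first pass; further passes add the second,
#' third, ..., `n_per_case`-th control. A case whose matched risk set is
#' exhausted keeps fewer controls and is flagged rather than failing.
#'
#' @param events Data frame with one row per subject and columns
#'   `sample_id`, `case` (0/1), `time` (event time for cases, end of
#'   follow-up for non-cases), `year` (enrollment year), `ethnicity`,
#'   `sex`.
#' @param n_per_case Controls sought per case.
#' @return Data frame with columns `case_id`, `control_id`, `pass`; the
#'   attribute `"shortfall"` names cases that received fewer than
#'   `n_per_case` controls. Selection order and ties use the current RNG,
#'   so results are reproducible under `set.seed()`.
#' @examples
#' ev <- data.frame(sample_id = c("a", "b", "c"),
#'                  case = c(1, 0, 0), time = c(2, 5, 5),
#'                  year = 2000, ethnicity = "E", sex = 1)
#' set.seed(1)
#' sample_matched_controls(ev, n_per_case = 2)
#' @export
sample_matched_controls <- function(events, n_per_case = 1L) {
  need <- c("sample_id", "case", "time", "year", "ethnicity", "sex")
  if (!all(need %in% names(events)))
    stopf("events must have columns %s", paste(need, collapse = ", "))
  if (!is_count(n_per_case)) stopf("'n_per_case' must be a positive integer")
  cases <- events[events$case == 1, , drop = FALSE]
  cases <- cases[order(cases$time), , drop = FALSE]
  used <- character(0)
  rows <- list()
  got <- setNames(integer(nrow(cases)), cases$sample_id)
  for (pass in seq_len(n_per_case)) {
    for (i in seq_len(nrow(cases))) {
      ca <- cases[i, ]
      elig <- events$sample_id != ca$sample_id &
        !(events$sample_id %in% used) &
        events$time >= ca$time &
        # a subject who later becomes a case is still at risk now
        !(events$case == 1 & events$time <= ca$time) &
        events$year == ca$year &
        events$ethnicity == ca$ethnicity &
        events$sex == ca$sex
      ids <- events$sample_id[elig]
      if (!length(ids)) next
      pick <- if (length(ids) == 1L) ids else sample(ids, 1L)
      used <- c(used, pick)
      got[ca$sample_id] <- got[ca$sample_id] + 1L
      rows[[length(rows) + 1L]] <- data.frame(case_id = ca$sample_id,
                                              control_id = pick,
                                              pass = pass,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), control_id = character(0),
               pass = integer(0), stringsAsFactors = FALSE)
  attr(out, "shortfall") <- names(got)[got < n_per_case]
  out
}
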