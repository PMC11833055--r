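#' Novel-object recognition index
#'
#' Preference for a novel over a familiar object, as a percentage of total
#' exploration time: `100 * tn / (tn + tf)` where `tn` is time spent
#' examining the novel object and `tf` the familiar one. 50 means no
#' preference; higher values indicate better recognition memory. The index
#' is unit-free: rescaling both times by the same factor leaves it
#' unchanged, and `recognition_index(tn, tf) + recognition_index(tf, tn)`
#' is exactly 100.
#'
#' @param tn,tf Nonnegative exploration times (seconds) for the novel and
#'   familiar objects; `tn + tf` must be positive.
#' @return Percentage in `[0, 100]`.
#' @export
recognition_index <- function(tn, tf) {
  stopifnot(is.numeric(tn), is.numeric(tf), tn >= 0, tf >= 0)
  if (any(tn + tf <= 0))
    stop("recognition index undefined: total exploration time is zero")
  100 * tn / (tn + tf)
}

check_arm_sequence <- function(seq, arms) {
  seq <- as.character(seq)
  if (length(arms) != 3L || anyDuplicated(arms))
    stop("the maze alphabet must be three distinct arm labels")
  bad <- setdiff(unique(seq), arms)
  if (length(bad))
    stop("arm label(s) not in the declared alphabet: ",
         paste(bad, collapse = ", "))
  seq
}

#' Count spontaneous alternations in an arm-entry sequence
#'
#' An alternation is an entry into three different arms in turn: a window of
#' three consecutive entries containing three distinct arms. Windows
#' overlap, so the sequence A,B,C,A,B,C scores 4. Consecutive re-entries
#' into the same arm count as entries but never complete an alternation.
#'
#' @param seq Character vector of arm labels in entry order.
#' @param arms The three-arm alphabet; default `c("A", "B", "C")`.
#' @return Nonnegative integer count (0 for sequences shorter than 3).
#' @export
count_alternations <- function(seq, arms = c("A", "B", "C")) {
  seq <- check_arm_sequence(seq, arms)
  n <- length(seq)
  if (n < 3L) return(0L)
  triple <- vapply(seq_len(n - 2L), function(i)
    length(unique(seq[i:(i + 2L)])) == 3L, logical(1))
  sum(triple)
}

#' Y-maze spontaneous alternation percentage
#'
#' `100 * alternations / (entries - 2)`: the number of overlapping
#' three-distinct-arm windows over the maximum number possible, so a mouse
#' that always rotates through all three arms scores 100. Requires at least
#' three entries.
#'
#' @inheritParams count_alternations
#' @return Percentage in `[0, 100]`.
#' @export
spontaneous_alternation_pct <- function(seq, arms = c("A", "B", "C")) {
  seq <- check_arm_sequence(seq, arms)
  if (length(seq) < 3L)
    stop("spontaneous alternation undefined for fewer than 3 entries")
  100 * count_alternations(seq, arms) / (length(seq) - 2L)
}

#' Elevated plus maze event counts
#'
#' @param open_entries,closed_entries Nonnegative entry counts into the open
#'   and closed arms.
#' @param open_time Seconds spent in the open arms.
#' @param total_time Total session seconds; `open_time <= total_time`.
#' @return An object of class `epm_counts`.
#' @export
epm_counts <- function(open_entries, closed_entries, open_time = NA_real_,
                       total_time = NA_real_) {
  stopifnot(open_entries >= 0, closed_entries >= 0,
            open_entries == as.integer(open_entries),
            closed_entries == as.integer(closed_entries))
  if (!is.na(open_time) && !is.na(total_time))
    stopifnot(open_time >= 0, open_time <= total_time)
  structure(list(open_entries = as.integer(open_entries),
                 closed_entries = as.integer(closed_entries),
                 open_time = open_time, total_time = total_time),
            class = "epm_counts")
}

#' Open-arm entry percentage
#'
#' Entries into the open arms divided by total arm entries, times 100.
#'
#' @param e An [epm_counts] object.
#' @return Percentage in `[0, 100]`.
#' @export
open_arm_entry_pct <- function(e) {
  stopifnot(inherits(e, "epm_counts"))
  tot <- e$open_entries + e$closed_entries
  if (tot == 0L) stop("open-arm entry percentage undefined: no arm entries")
  100 * e$open_entries / tot
}

#' Open-arm time percentage
#'
#' Time spent in the open arms as a percentage of total session time.
#'
#' @param e An [epm_counts] object with `open_time` and `total_time` set.
#' @return Percentage in `[0, 100]`.
#' @export
open_arm_time_pct <- function(e) {
  stopifnot(inherits(e, "epm_counts"))
  if (is.na(e$open_time) || is.na(e$total_time))
    stop("open_time and total_time are required")
  if (e$total_time <= 0) stop("open-arm time percentage undefined: zero total time")
  100 * e$open_time / e$total_time
}

#' Score Y-maze entries for many subjects
#'
#' Takes a long event table (one row per arm entry, in order) and returns
#' per-subject alternation indices.
#'
#' @param events Data frame with columns `subject` and `arm`, rows in entry
#'   order within subject.
#' @param arms The three-arm alphabet.
#' @return Data frame with columns `subject`, `entries`, `alternations`,
#'   `alternation_pct`.
#' @export
score_ymaze_events <- function(events, arms = c("A", "B", "C")) {
  stopifnot(is.data.frame(events), all(c("subject", "arm") %in% names(events)))
  res <- lapply(split(as.character(events$arm), events$subject), function(s) {
    data.frame(entries = length(s),
               alternations = count_alternations(s, arms),
               alternation_pct = if (length(s) >= 3L)
                 spontaneous_alternation_pct(s, arms) else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- cbind(subject = names(res), out)
  rownames(out) <- NULL
  out
}
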