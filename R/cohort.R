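#' Build assessment record tables
#'
#' Validates a long-format assessment table, one row per patient-assessment.
#' Required columns: `patient_id`, `day` (non-negative integer days since the
#' patient's first visit), `state` (integer disability-state code, see
#' [encode_state()]), `age` (baseline age in years), `sex` (`"male"` or
#' `"female"`), `death_day` (integer or `NA` when no death was recorded) and
#' `censor_day` (administrative end of follow-up).
#'
#' @param df data.frame with the columns above (`state` may instead be given
#'   as nine 0/1 domain columns named as in [adl_domains()]).
#' @return validated data.frame of class `assessment_records`.
#' @export
assessment_records <- function(df) {
  df <- as.data.frame(df)
  if (!("state" %in% names(df))) {
    doms <- adl_domains()
    if (!all(doms %in% names(df))) {
      stop("need either a 'state' column or the nine domain columns ",
           paste(doms, collapse = ","))
    }
    bin <- as.matrix(df[doms])
    if (!all(bin %in% c(0, 1))) {
      bad <- which(!(bin %in% c(0, 1)))[1]
      stop("domain columns must be 0/1; offending entry index ", bad)
    }
    df$state <- as.integer(bin %*% .adl_bits[doms])
    df <- df[setdiff(names(df), doms)]
  }
  need <- c("patient_id", "day", "state", "age", "sex", "censor_day")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!("death_day" %in% names(df))) df$death_day <- NA_integer_
  df$patient_id <- as.character(df$patient_id)
  df$day <- as.integer(df$day)
  df$state <- .check_code(df$state)
  if (anyNA(df$day) || any(df$day < 0L)) stop("'day' must be non-negative integers")
  if (!all(df$sex %in% c("male", "female"))) stop("'sex' must be 'male' or 'female'")
  class(df) <- c("assessment_records", "data.frame")
  df
}

#' Apply cohort exclusion rules
#'
#' Removes patients with insufficient longitudinal information (fewer than
#' `min_visits` assessments), invalid baseline age (missing or non-positive)
#' or inconsistent death ordering (a recorded death day earlier than the last
#' assessment day). Duplicate `(patient, day)` rows keep the last record, with
#' a warning. Each removed patient is attributed to the first rule that
#' catches them, so the audit counts sum to the number of patients removed.
#'
#' @param records an [assessment_records()] table.
#' @param min_visits minimum number of assessments per retained patient.
#' @return list with elements `records` (the filtered table) and `audit`
#'   (named integer vector: `invalid_age`, `death_order`, `min_visits`).
#' @export
apply_exclusions <- function(records, min_visits = 3L) {
  if (nrow(records) == 0L) stop("empty assessment table")
  records <- records[order(records$patient_id, records$day), , drop = FALSE]
  dup <- duplicated(records[c("patient_id", "day")], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate (patient, day) row(s); keeping the last record")
    records <- records[!dup, , drop = FALSE]
  }
  by_pat <- split(seq_len(nrow(records)), records$patient_id)
  audit <- c(invalid_age = 0L, death_order = 0L, min_visits = 0L)
  keep <- logical(nrow(records))
  for (rows in by_pat) {
    age <- records$age[rows[1]]
    dd <- records$death_day[rows[1]]
    if (is.na(age) || age <= 0) {
      audit["invalid_age"] <- audit["invalid_age"] + 1L
    } else if (!is.na(dd) && dd < max(records$day[rows])) {
      audit["death_order"] <- audit["death_order"] + 1L
    } else if (length(rows) < min_visits) {
      audit["min_visits"] <- audit["min_visits"] + 1L
    } else {
      keep[rows] <- TRUE
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, audit = audit)
}

#' Build a spell sequence from ordered visits
#'
#' Collapses per-visit states into maximal runs ("spells") of a constant
#' state. The observed state is assumed to persist between consecutive
#' assessments, so a spell begins at the first visit day of its run and ends
#' at the first visit day of the next run; the last spell ends at the last
#' visit day, extended by one day when that would give it zero duration, so
#' every spell has positive duration.
#'
#' @param days strictly increasing visit days (integers).
#' @param states integer state codes, one per visit.
#' @param patient_id optional identifier attached to the sequence.
#' @return object of class `traj`: a list with `patient_id`, `days`, `states`
#'   (per-visit, for Markov-stage transitions) and `spells`
#'   (data.frame `state`, `begin`, `end`, `duration`).
#' @export
build_spells <- function(days, states, patient_id = NA_character_) {
  days <- as.numeric(days)
  states <- as.integer(states)
  if (length(days) != length(states) || length(days) < 1L) {
    stop("days and states must be non-empty and the same length")
  }
  if (is.unsorted(days, strictly = TRUE)) stop("visit days must be strictly increasing")
  days <- days - days[1]
  run <- c(TRUE, states[-1] != states[-length(states)])
  begin <- days[run]
  state <- states[run]
  end <- c(begin[-1], days[length(days)])
  n <- length(state)
  if (end[n] <= begin[n]) end[n] <- begin[n] + 1  # minimum spell duration 1 day
  visits <- diff(c(which(run), length(states) + 1L))
  structure(list(
    patient_id = patient_id,
    days = days,
    states = states,
    spells = data.frame(state = state, begin = begin, end = end,
                        duration = end - begin, visits = visits)
  ), class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  lab <- paste0("(", state_label(pmin(x$spells$state, 511L)), ",",
                x$spells$duration, ")", collapse = " ")
  cat("<traj ", x$patient_id, "> ", lab, "\n", sep = "")
  invisible(x)
}

#' Sequence-level descriptive statistics
#'
#' @param x a `traj` object.
#' @return named numeric vector: `length_days` (end of last spell minus begin
#'   of first), `n_spells`, `n_states` (distinct states visited) and
#'   `recurrence` (spells per distinct state; 1 means no state is revisited).
#' @export
traj_stats <- function(x) {
  sp <- x$spells
  c(length_days = sp$end[nrow(sp)] - sp$begin[1],
    n_spells = nrow(sp),
    n_states = length(unique(sp$state)),
    recurrence = nrow(sp) / length(unique(sp$state)))
}

#' Build spell sequences for every retained patient
#'
#' @param records an [assessment_records()] table (post-exclusion).
#' @return named list of `traj` objects, one per patient.
#' @export
build_sequences <- function(records) {
  records <- records[order(records$patient_id, records$day), , drop = FALSE]
  lapply(split(records, records$patient_id), function(d) {
    build_spells(d$day, d$state, patient_id = d$patient_id[1])
  })
}

#' Restrict sequences to the most frequent states
#'
#' State frequencies are counted over assessment rows (each visit contributes
#' its weight, 1 for raw sequences). The top `K` states are kept; ties at rank
#' `K` keep all tied states (so more than `K` states may survive, with a
#' message). Non-top states are handled per `strategy`: `"drop"` removes
#' those assessments, rebuilds spells and re-applies the minimum-visit rule
#' (sequences falling below `min_visits` are removed); `"other"` recodes them
#' to the synthetic OTHER state (code 512), which is suitable for
#' descriptive tables but not for severity-based substitution costs.
#'
#' @param seqs list of `traj` objects (or a `traj_pool`, in which case
#'   pattern weights multiply the assessment counts and the result is
#'   re-merged into a pool).
#' @param K number of states to keep.
#' @param strategy `"drop"` or `"other"`.
#' @param min_visits minimum visits re-applied after dropping.
#' @return same shape as the input (list of `traj` or `traj_pool`).
#' @export
restrict_states <- function(seqs, K = 25L, strategy = c("drop", "other"),
                            min_visits = 3L) {
  strategy <- match.arg(strategy)
  if (inherits(seqs, "traj_pool")) {
    expanded <- rep(seq_along(seqs$seqs), times = seqs$weights)
    members <- unlist(seqs$members, use.names = FALSE)
    raw <- seqs$seqs[expanded]
    for (i in seq_along(raw)) raw[[i]]$patient_id <- members[i]
    return(merge_identical(restrict_states(raw, K, strategy, min_visits)))
  }
  tab <- table(unlist(lapply(seqs, `[[`, "states")))
  if (K >= length(tab)) {
    warning("K >= number of observed states; sequences unchanged")
    return(seqs)
  }
  freq <- sort(tab, decreasing = TRUE)
  cutoff <- as.numeric(freq[K])
  keep_states <- as.integer(names(freq)[freq >= cutoff])
  if (length(keep_states) > K) {
    message("frequency tie at rank ", K, ": keeping ", length(keep_states), " states")
  }
  out <- lapply(seqs, function(s) {
    inside <- s$states %in% keep_states
    if (all(inside)) return(s)
    if (strategy == "other") {
      st <- s$states
      st[!inside] <- OTHER_STATE
      return(build_spells(s$days, st, s$patient_id))
    }
    if (sum(inside) < min_visits) return(NULL)
    build_spells(s$days[inside], s$states[inside], s$patient_id)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Synthetic state code for non-top-K assessments under the "other" strategy
#' @export
OTHER_STATE <- 512L

#' Merge identical trajectories into a frequency-weighted pool
#'
#' Sequences with identical `(state, begin, end)` spell lists collapse into a
#' single pattern carrying an integer frequency weight; the sum of weights
#' equals the number of input sequences. Identical states with different
#' durations are distinct patterns.
#'
#' @param seqs list of `traj` objects.
#' @return object of class `traj_pool`: list with `seqs` (unique patterns),
#'   `weights`, `members` (patient ids per pattern) and `alphabet` (sorted
#'   state codes present).
#' @export
merge_identical <- function(seqs) {
  keys <- vapply(seqs, function(s) {
    paste(s$spells$state, s$spells$begin, s$spells$end, sep = ",", collapse = ";")
  }, character(1))
  idx <- split(seq_along(seqs), keys)
  # stable order: first occurrence
  idx <- idx[order(vapply(idx, min, integer(1)))]
  pool <- structure(list(
    seqs = lapply(idx, function(i) seqs[[i[1]]]),
    weights = vapply(idx, length, integer(1)),
    members = lapply(idx, function(i) {
      vapply(seqs[i], function(s) as.character(s$patient_id), character(1))
    }),
    alphabet = sort(unique(unlist(lapply(seqs, function(s) unique(s$states)))))
  ), class = "traj_pool")
  names(pool$seqs) <- NULL
  names(pool$weights) <- NULL
  names(pool$members) <- NULL
  pool
}

#' @export
print.traj_pool <- function(x, ...) {
  cat("<traj_pool> ", length(x$seqs), " unique patterns, ",
      sum(x$weights), " sequences, ", length(x$alphabet), " states\n", sep = "")
  invisible(x)
}

#' Number of unique patterns in a pool
#' @param pool a `traj_pool`.
#' @export
pool_size <- function(pool) length(pool$seqs)

#' Weighted state distribution over time
#'
#' At each grid day `t`, the weighted proportion of sequences occupying each
#' state among sequences whose observation window covers `t` (no imputation
#' beyond observed follow-up: sequences whose last spell ends before `t` drop
#' out of the denominator).
#'
#' @param pool a `traj_pool`.
#' @param time_grid non-empty vector of days.
#' @return data.frame with columns `day`, `state`, `proportion`, `n_covered`
#'   (weighted count of sequences under observation at `day`).
#' @export
state_distribution <- function(pool, time_grid) {
  if (length(time_grid) == 0L) stop("empty time grid")
  res <- lapply(as.numeric(time_grid), function(t) {
    states <- integer(0); w <- numeric(0)
    for (i in seq_along(pool$seqs)) {
      sp <- pool$seqs[[i]]$spells
      if (t < sp$begin[1] || t > sp$end[nrow(sp)]) next
      j <- findInterval(t, sp$begin)
      states <- c(states, sp$state[j]); w <- c(w, pool$weights[i])
    }
    if (length(w) == 0L) {
      return(data.frame(day = t, state = NA_integer_, proportion = NA_real_,
                        n_covered = 0))
    }
    agg <- tapply(w, states, sum)
    data.frame(day = t, state = as.integer(names(agg)),
               proportion = as.numeric(agg) / sum(w), n_covered = sum(w))
  })
  do.call(rbind, res)
}

#' Weighted descriptive statistics of a pool
#'
#' Weighted means of trajectory length in days, number of distinct states
#' visited and recurrence degree, optionally within clusters.
#'
#' @param pool a `traj_pool`.
#' @param labels optional integer cluster labels (one per pattern).
#' @return data.frame with one row per cluster (or a single `all` row).
#' @export
pool_stats <- function(pool, labels = NULL) {
  st <- t(vapply(pool$seqs, traj_stats, numeric(4)))
  w <- pool$weights
  if (is.null(labels)) labels <- rep(1L, length(w))
  out <- lapply(sort(unique(labels)), function(cl) {
    i <- labels == cl
    data.frame(cluster = cl, n = sum(w[i]), n_patterns = sum(i),
               mean_length = sum(w[i] * st[i, "length_days"]) / sum(w[i]),
               mean_n_states = sum(w[i] * st[i, "n_states"]) / sum(w[i]),
               mean_recurrence = sum(w[i] * st[i, "recurrence"]) / sum(w[i]))
  })
  do.call(rbind, out)
}
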