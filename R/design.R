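#' Experimental design specification
#'
#' Describes a dual-task contrast-discrimination session run with the method
#' of constant stimuli: fixed test-contrast levels, a fixed standard contrast,
#' an equal number of repetitions of every level in each of the two task
#' positions, and a block structure. The default corresponds to the study
#' design: 7 test contrasts from 13 to 31% in steps of 3% around a 22%
#' standard, 60 repetitions per level and task position, giving 420 trials
#' in 6 blocks of 70.
#'
#' @param levels Numeric vector of test-patch contrasts (% contrast).
#' @param standard Standard-patch contrast (% contrast).
#' @param reps_per_level Repetitions of each level per task position.
#' @param blocks Number of blocks the session is divided into.
#'
#' @return An object of class `design_spec`.
#' @examples
#' design_spec()
#' @export
design_spec <- function(levels = seq(13, 31, by = 3),
                        standard = 22,
                        reps_per_level = 60,
                        blocks = 6) {
  stopifnot(is.numeric(levels), length(levels) >= 1, !anyDuplicated(levels),
            is.numeric(standard), length(standard) == 1,
            reps_per_level >= 1, blocks >= 1)
  structure(
    list(levels = as.numeric(levels), standard = as.numeric(standard),
         reps_per_level = as.integer(reps_per_level),
         blocks = as.integer(blocks)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  n <- length(x$levels) * x$reps_per_level
  cat("Design: ", length(x$levels), " test levels (",
      paste(x$levels, collapse = ", "), "% contrast), standard ",
      x$standard, "%\n", sep = "")
  cat(x$reps_per_level, "reps/level/task position;", n, "trials in",
      x$blocks, "blocks\n")
  invisible(x)
}

#' Total number of trials implied by a design
#' @param spec A [design_spec()].
#' @return Integer trial count (levels x reps per level).
#' @export
n_trials <- function(spec) {
  length(spec$levels) * spec$reps_per_level
}

# Column order of a session table; also the on-disk CSV header.
trial_columns <- c("participant_id", "block", "trial",
                   "task1_delta", "task1_side", "decision1", "rt1_ms",
                   "task2_delta", "task2_side", "decision2", "rt2_ms",
                   "conf_choice")

#' Generate a randomized session design
#'
#' Builds the trial templates for one session: each test-contrast level
#' appears exactly `reps_per_level` times in each of the two task positions,
#' the two positions are counterbalanced independently, test-patch laterality
#' is randomized, and trial order is shuffled. Response fields (`decision1`,
#' `decision2`, `rt1_ms`, `rt2_ms`, `conf_choice`) are returned as `NA` to be
#' filled by an observer (human or simulated).
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed controlling shuffling and laterality; the design
#'   is deterministic given the seed.
#' @param participant_id Identifier copied into every row.
#'
#' @return A tibble with one row per trial; deltas are signed contrast
#'   differences test minus standard (% contrast).
#' @examples
#' d <- generate_design(design_spec(), seed = 1)
#' nrow(d)           # 420
#' table(d$task1_delta)
#' @export
generate_design <- function(spec = design_spec(), seed = 1L,
                            participant_id = "sim") {
  stopifnot(inherits(spec, "design_spec"))
  n <- n_trials(spec)
  if (n %% spec$blocks != 0) {
    stop(sprintf(
      "total trials (%d) not divisible into %d blocks: remainder %d",
      n, spec$blocks, n %% spec$blocks))
  }
  deltas <- spec$levels - spec$standard
  shuffle <- function(x) x[sample.int(length(x))]
  with_rng_seed(seed, {
    # independent counterbalancing of the two task positions
    task1 <- shuffle(rep(deltas, each = spec$reps_per_level))
    task2 <- shuffle(rep(deltas, each = spec$reps_per_level))
    side1 <- sample(c("left", "right"), n, replace = TRUE)
    side2 <- sample(c("left", "right"), n, replace = TRUE)
    tibble::tibble(
      participant_id = participant_id,
      block = rep(seq_len(spec$blocks), each = n %/% spec$blocks),
      trial = seq_len(n),
      task1_delta = task1,
      task1_side = side1,
      decision1 = NA_character_,
      rt1_ms = NA_real_,
      task2_delta = task2,
      task2_side = side2,
      decision2 = NA_character_,
      rt2_ms = NA_real_,
      conf_choice = NA_integer_
    )
  })
}

validate_trials <- function(trials, levels_delta = NULL, require_responses = TRUE) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop(sprintf("%s on row %s", what,
                   paste(utils::head(which(!ok), 5), collapse = ", ")))
    }
  }
  if (!is.null(levels_delta)) {
    for (col in c("task1_delta", "task2_delta")) {
      bad_row(trials[[col]] %in% levels_delta,
              sprintf("out-of-range %s (allowed: %s)", col,
                      paste(levels_delta, collapse = ", ")))
    }
  }
  if (require_responses) {
    bad_row(!is.na(trials$conf_choice) & trials$conf_choice %in% c(1L, 2L),
            "unknown conf_choice code (must be 1 or 2)")
    for (col in c("decision1", "decision2")) {
      bad_row(trials[[col]] %in% c("higher", "lower"),
              sprintf("unknown %s label (must be higher/lower)", col))
    }
    for (col in c("rt1_ms", "rt2_ms")) {
      bad_row(is.finite(trials[[col]]) & trials[[col]] > 0,
              sprintf("non-positive %s", col))
    }
  }
  invisible(trials)
}

#' Read / write session tables
#'
#' Sessions are stored as plain comma-separated text with one row per trial
#' and the fixed header `participant_id, block, trial, task1_delta,
#' task1_side, decision1, rt1_ms, task2_delta, task2_side, decision2,
#' rt2_ms, conf_choice`. On reading, rows are validated against the trial
#' invariants (decision labels, positive RTs, confidence code 1 or 2, and —
#' when `levels_delta` is given — membership of the deltas in the design);
#' violations raise an error citing the first offending rows.
#'
#' @param path File path.
#' @param levels_delta Optional numeric vector of admissible signed deltas.
#' @return `read_session_table()` returns a tibble of trials;
#'   `write_session_table()` returns `path` invisibly.
#' @export
read_session_table <- function(path, levels_delta = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  trials <- tibble::as_tibble(raw)
  validate_trials(trials, levels_delta = levels_delta)
  trials[trial_columns]
}

#' @rdname read_session_table
#' @param trials A session tibble as produced by [generate_design()] or
#'   [simulate_session()].
#' @export
write_session_table <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[trial_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

participant_columns <- c("participant_id", "age_group", "age",
                         "dsst", "tmt_b_s", "vst_c_s", "lps3", "digit_span")

#' Read / write participant tables
#'
#' Participant covariates (age group, age, and the cognitive battery: DSST,
#' TMT-B and VST-C completion times in seconds, LPS-3, backward digit span)
#' as comma-separated text with header `participant_id, age_group, age, dsst,
#' tmt_b_s, vst_c_s, lps3, digit_span`.
#'
#' @param path File path.
#' @return `read_participants_table()` returns a tibble.
#' @export
read_participants_table <- function(path) {
  p <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(participant_columns, names(p))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  num <- c("dsst", "tmt_b_s", "vst_c_s", "lps3", "digit_span")
  bad <- vapply(num, function(col) any(p[[col]] < 0, na.rm = TRUE), logical(1))
  if (any(bad)) stop("negative cognitive scores in: ",
                     paste(num[bad], collapse = ", "))
  p[participant_columns]
}

#' @rdname read_participants_table
#' @param participants A participants tibble.
#' @export
write_participants_table <- function(participants, path) {
  utils::write.csv(participants[participant_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Unstack a session into one row per perceptual decision
#'
#' Each trial holds two perceptual decisions; most analyses work on the
#' decision level. The returned table carries the binary confidence code
#' (1 if that decision was selected in the confidence task, 0 otherwise)
#' and, when responses are present, a correctness label. Correctness at a
#' zero contrast difference is undefined and stored as `"arbitrary"`.
#'
#' @param trials A session tibble.
#' @return A tibble with columns `participant_id, trial, task, delta,
#'   decision, rt_ms, confidence, correct`.
#' @export
decisions_long <- function(trials) {
  validate_trials(trials)
  one <- function(task_no) {
    d <- trials[[paste0("task", task_no, "_delta")]]
    dec <- trials[[paste0("decision", task_no)]]
    rt <- trials[[paste0("rt", task_no, "_ms")]]
    correct <- ifelse(d == 0, "arbitrary",
                      ifelse((d > 0) == (dec == "higher"), "correct", "incorrect"))
    tibble::tibble(
      participant_id = trials$participant_id,
      trial = trials$trial,
      task = task_no,
      delta = d,
      decision = dec,
      rt_ms = rt,
      confidence = as.integer(trials$conf_choice == task_no),
      correct = correct
    )
  }
  out <- dplyr::bind_rows(one(1L), one(2L))
  dplyr::arrange(out, .data$participant_id, .data$trial, .data$task)
}

#' Filter decisions by response time
#'
#' Removes anticipatory and delayed responses from response-time analyses:
#' decisions with RT below `low_ms` or above `high_ms` are discarded. The
#' bounds only scope RT analyses; psychometric and confidence-set analyses
#' keep all decisions. The per-participant exclusion rate (fraction of
#' decisions removed) is reported alongside.
#'
#' @param decisions A decision-level tibble from [decisions_long()].
#' @param low_ms,high_ms RT bounds in ms (defaults 100 and 3000).
#' @return A list with `kept` (the surviving decisions) and `exclusion`
#'   (tibble: participant_id, n_total, n_excluded, rate).
#' @examples
#' d <- decisions_long(simulate_session(observer_params(sigma_s = 5), seed = 1))
#' filter_rts(d)$exclusion
#' @export
filter_rts <- function(decisions, low_ms = 100, high_ms = 3000) {
  stopifnot(low_ms >= 0, high_ms > low_ms)
  if (nrow(decisions) == 0) {
    return(list(kept = decisions,
                exclusion = tibble::tibble(participant_id = character(),
                                           n_total = integer(),
                                           n_excluded = integer(),
                                           rate = numeric())))
  }
  out <- !is.na(decisions$rt_ms) &
    decisions$rt_ms >= low_ms & decisions$rt_ms <= high_ms
  excl <- decisions |>
    dplyr::mutate(.kept = out) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_excluded = sum(!.data$.kept),
                     rate = 1 - sum(.data$.kept) / dplyr::n(),
                     .by = "participant_id")
  list(kept = decisions[out, , drop = FALSE], exclusion = excl)
}
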