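#' Study design parameters
#'
#' Encodes the longitudinal two-group design: weekly sessions of three
#' stimulus conditions, each presenting a balanced block of emotional face
#' stimuli. The experimental group (EG) hears emotion-congruent music during
#' its middle condition (M); the control group (CG) sees faces only in all
#' three conditions. A follow-up assessment one week after the last session
#' presents a single no-music condition (NM1) and is modelled as an extra
#' session index.
#'
#' @param n_sessions Number of weekly sessions (default 4).
#' @param post_assessment Logical; add a follow-up NM1-only assessment as
#'   session `n_sessions + 1` (default `TRUE`).
#' @param eg_size,cg_size Number of participants per group (defaults 14, 11).
#' @param eeg_per_group Number of participants per group with EEG recordings
#'   (default 6).
#' @param stimuli_per_condition Stimuli per condition (default 12); must be
#'   divisible by the number of emotions (4) and by 2 (sex balance).
#' @param stimulus_duration_s Stimulus duration in seconds (default 10).
#' @param transition_s Inter-stimulus transition in seconds (default 5);
#'   verbal responses are collected during transitions.
#'
#' @return A list of class `design_config`.
#' @examples
#' design_config()
#' @export
design_config <- function(n_sessions = 4,
                          post_assessment = TRUE,
                          eg_size = 14,
                          cg_size = 11,
                          eeg_per_group = 6,
                          stimuli_per_condition = 12,
                          stimulus_duration_s = 10,
                          transition_s = 5) {
  assert_scalar_number(n_sessions, "n_sessions", positive = TRUE)
  assert_scalar_number(stimuli_per_condition, "stimuli_per_condition", positive = TRUE)
  assert_scalar_number(stimulus_duration_s, "stimulus_duration_s", positive = TRUE)
  assert_scalar_number(transition_s, "transition_s")
  if (stimuli_per_condition %% length(emotion_levels) != 0) {
    abort(sprintf(
      "`stimuli_per_condition` (%d) must divide evenly over the %d emotions.",
      stimuli_per_condition, length(emotion_levels)
    ))
  }
  if (stimuli_per_condition %% 2 != 0) {
    abort("`stimuli_per_condition` must be even for a 50/50 face-sex balance.")
  }
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      post_assessment = isTRUE(post_assessment),
      eg_size = as.integer(eg_size),
      cg_size = as.integer(cg_size),
      eeg_per_group = as.integer(eeg_per_group),
      stimuli_per_condition = as.integer(stimuli_per_condition),
      stimulus_duration_s = stimulus_duration_s,
      transition_s = transition_s
    ),
    class = "design_config"
  )
}

conditions_for <- function(group, session_index, design) {
  post <- design$post_assessment && session_index == design$n_sessions + 1L
  if (post) {
    return("NM1")
  }
  if (group == "EG") c("NM1", "M", "NM3") else c("NM1", "NM2", "NM3")
}

#' Build the stimulus schedule of one participant-session
#'
#' Lays out, for each condition of the session, a balanced randomized block
#' of stimuli: `stimuli_per_condition` events, equally many per emotion,
#' half male and half female faces, presented in random order with fixed
#' stimulus duration and inter-stimulus transition. EG sessions run
#' conditions NM1, M, NM3 (music in M only); CG sessions run NM1, NM2, NM3.
#' Stimulus identifiers are unique across a participant's whole study, so no
#' stimulus repeats.
#'
#' @param participant_id Participant identifier string.
#' @param group `"EG"` or `"CG"`.
#' @param session_index 1-based session number; `n_sessions + 1` denotes the
#'   follow-up assessment (single NM1 condition).
#' @param design A [design_config()].
#' @param seed Integer seed driving the randomization of stimulus order and
#'   face-sex assignment.
#'
#' @return A tibble of class `stimulus_schedule`, one row per stimulus event,
#'   with columns `participant_id`, `group`, `session_index`, `condition`,
#'   `onset_s`, `duration_s`, `emotion`, `face_sex`, `stimulus_id`,
#'   `with_music`, and attribute `transition_s`.
#' @examples
#' sched <- build_schedule("EG01", "EG", 1, design_config(), seed = 1)
#' dplyr::count(sched, condition, emotion)
#' @export
build_schedule <- function(participant_id, group, session_index,
                           design = design_config(), seed = 1) {
  group <- match.arg(group, c("EG", "CG"))
  stopifnot(inherits(design, "design_config"))
  session_index <- as.integer(session_index)
  max_session <- design$n_sessions + as.integer(design$post_assessment)
  if (session_index < 1L || session_index > max_session) {
    abort(sprintf("`session_index` must be in 1..%d.", max_session))
  }
  conds <- conditions_for(group, session_index, design)
  n_stim <- design$stimuli_per_condition
  per_emotion <- n_stim %/% length(emotion_levels)

  with_seed(seed, {
    blocks <- purrr::map(seq_along(conds), function(ci) {
      cond <- conds[ci]
      emotions <- sample(rep(emotion_levels, per_emotion))
      sexes <- sample(rep(c("male", "female"), each = n_stim %/% 2L))
      tibble(
        condition = cond,
        slot = seq_len(n_stim),
        emotion = emotions,
        face_sex = sexes
      )
    })
    events <- bind_rows(blocks)
    n_total <- nrow(events)
    step <- design$transition_s + design$stimulus_duration_s
    events <- events %>%
      mutate(
        onset_s = design$transition_s + (dplyr::row_number() - 1L) * step,
        duration_s = design$stimulus_duration_s,
        with_music = .data$condition == "M",
        stimulus_id = sprintf(
          "%s_s%02d_%s_%02d", participant_id, session_index,
          .data$condition, .data$slot
        ),
        participant_id = participant_id,
        group = group,
        session_index = session_index
      ) %>%
      select(
        "participant_id", "group", "session_index", "condition",
        "onset_s", "duration_s", "emotion", "face_sex", "stimulus_id",
        "with_music"
      )
    new_stimulus_schedule(events, transition_s = design$transition_s)
  })
}

new_stimulus_schedule <- function(events, transition_s) {
  events <- as_tibble(events)
  attr(events, "transition_s") <- transition_s
  class(events) <- c("stimulus_schedule", class(events))
  events
}

#' Build schedules for a whole study
#'
#' One [build_schedule()] call per participant-session, for all EG and CG
#' participants and all sessions (including the follow-up assessment when the
#' design has one). Participant identifiers are `EG01..` / `CG01..`; the
#' first `eeg_per_group` participants of each group are flagged as EEG
#' participants.
#'
#' @inheritParams build_schedule
#' @return A list of `stimulus_schedule` tibbles, named
#'   `<participant>_s<session>`.
#' @examples
#' sch <- build_study_schedules(design_config(eg_size = 2, cg_size = 1), seed = 1)
#' length(sch)
#' @export
build_study_schedules <- function(design = design_config(), seed = 1) {
  roster <- study_roster(design)
  sessions <- seq_len(design$n_sessions + as.integer(design$post_assessment))
  grid <- tidyr::expand_grid(roster, session_index = sessions)
  out <- purrr::pmap(
    list(grid$participant_id, grid$group, grid$session_index, seq_len(nrow(grid))),
    function(pid, grp, ses, k) {
      build_schedule(pid, grp, ses, design, seed = derive_seed(seed, k))
    }
  )
  names(out) <- sprintf("%s_s%02d", grid$participant_id, grid$session_index)
  out
}

#' @rdname build_study_schedules
#' @export
study_roster <- function(design = design_config()) {
  tibble(
    participant_id = c(
      sprintf("EG%02d", seq_len(design$eg_size)),
      sprintf("CG%02d", seq_len(design$cg_size))
    ),
    group = rep(c("EG", "CG"), c(design$eg_size, design$cg_size)),
    has_eeg = c(
      seq_len(design$eg_size) <= design$eeg_per_group,
      seq_len(design$cg_size) <= design$eeg_per_group
    )
  )
}

#' Specify the accuracy model for simulated verbal responses
#'
#' Responses are Bernoulli draws: a participant answers correctly with
#' probability `baseline` in every condition; for EG participants the
#' probability increases by `eg_session_gain` per elapsed session
#' (`baseline + gain * (session - 1)`, clamped to \[0, 1\]), emulating a
#' training effect confined to the experimental group. Incorrect responses
#' are uniform over the three remaining emotions.
#'
#' @param baseline Baseline probability of a correct response, in \[0, 1\].
#' @param eg_session_gain Per-session accuracy increment for EG (CG gain is 0).
#' @return A list of class `response_effect`.
#' @export
response_effect <- function(baseline = 0.5, eg_session_gain = 0.1) {
  assert_scalar_number(baseline, "baseline")
  assert_scalar_number(eg_session_gain, "eg_session_gain")
  if (baseline < 0 || baseline > 1) {
    abort("`baseline` must lie in [0, 1].")
  }
  structure(
    list(baseline = baseline, eg_session_gain = eg_session_gain),
    class = "response_effect"
  )
}

#' Simulate verbal emotion-identification responses
#'
#' For every stimulus event in the given schedules, draws the participant's
#' verbal answer to "how is this person feeling?" under the accuracy model of
#' [response_effect()].
#'
#' @param schedules A `stimulus_schedule` or list of them.
#' @param effect A [response_effect()].
#' @param seed Integer seed.
#' @return A tibble with one row per stimulus: `participant_id`, `group`,
#'   `session_index`, `condition`, `stimulus_id`, `true_emotion`,
#'   `responded_emotion`, `correct`.
#' @examples
#' sched <- build_schedule("EG01", "EG", 1, seed = 1)
#' resp <- simulate_verbal_responses(sched, response_effect(1, 0), seed = 1)
#' all(resp$correct)
#' @export
simulate_verbal_responses <- function(schedules,
                                      effect = response_effect(),
                                      seed = 1) {
  stopifnot(inherits(effect, "response_effect"))
  if (inherits(schedules, "stimulus_schedule")) {
    schedules <- list(schedules)
  }
  events <- bind_rows(lapply(schedules, as_tibble))
  p <- ifelse(
    events$group == "EG",
    clamp01(effect$baseline + effect$eg_session_gain * (events$session_index - 1)),
    effect$baseline
  )
  with_seed(seed, {
    correct <- runif(nrow(events)) < p
    responded <- events$emotion
    wrong <- which(!correct)
    if (length(wrong)) {
      responded[wrong] <- vapply(events$emotion[wrong], function(e) {
        sample(setdiff(emotion_levels, e), 1L)
      }, character(1))
    }
    tibble(
      participant_id = events$participant_id,
      group = events$group,
      session_index = events$session_index,
      condition = events$condition,
      stimulus_id = events$stimulus_id,
      true_emotion = events$emotion,
      responded_emotion = responded,
      correct = correct
    )
  })
}

# Validate the schedule invariants; used by the generator before synthesis.
validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  req <- c("onset_s", "duration_s", "emotion", "condition", "stimulus_id")
  missing <- setdiff(req, names(schedule))
  if (length(missing)) {
    abort(paste0("schedule lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(schedule) == 0) {
    return(invisible(schedule))
  }
  if (is.unsorted(schedule$onset_s, strictly = TRUE)) {
    abort("schedule events must be sorted by onset.")
  }
  ends <- schedule$onset_s + schedule$duration_s
  if (any(head(ends, -1) > tail(schedule$onset_s, -1) + 1e-9)) {
    abort("schedule events must not overlap.")
  }
  if (anyDuplicated(schedule$stimulus_id)) {
    abort("stimulus_id values must be unique within a schedule.")
  }
  invisible(schedule)
}
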