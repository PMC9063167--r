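#' Classify a musical tempo into slow / moderate / fast
#'
#' Tempo bins follow the stimulus-matching convention used for the music
#' paradigm: slow 40--72 bpm, moderate 72--120 bpm, fast 120--208 bpm.
#' Bins are half-open `[lo, hi)` with the top bin closed at 208, so the
#' shared boundaries 72 and 120 belong to the upper class.
#'
#' @param tempo_bpm Numeric vector of tempi in beats per minute; every value
#'   must lie in `[40, 208]`.
#' @return Character vector with values `"slow"`, `"moderate"` or `"fast"`.
#' @examples
#' classify_tempo(c(60, 100, 150))
#' @export
classify_tempo <- function(tempo_bpm) {
  stopifnot(is.numeric(tempo_bpm))
  if (any(!is.finite(tempo_bpm)) || any(tempo_bpm < 40 | tempo_bpm > 208)) {
    stop("tempo_bpm must lie in [40, 208] beats/min", call. = FALSE)
  }
  ifelse(tempo_bpm < 72, "slow", ifelse(tempo_bpm < 120, "moderate", "fast"))
}

#' Build a stimulus record table
#'
#' Convenience constructor for the stimulus features used in matching:
#' tempo (binned by [classify_tempo()]), mode, genre, lyrics and language.
#'
#' @param id Character ids.
#' @param familiarity `"familiar"` or `"unfamiliar"`.
#' @param tempo_bpm Tempo in beats per minute.
#' @param mode `"major"` or `"minor"`.
#' @param genre Free-text genre label (e.g. `"pop"`, `"rock"`, `"classic"`).
#' @param has_lyrics Logical; does the excerpt have lyrics.
#' @param language Lyric language; only meaningful when `has_lyrics` is TRUE
#'   (coerced to `NA` otherwise).
#' @param liking `"liked"`, `"disliked"` or `NA` (unfamiliar pool songs).
#' @return A `data.frame` with one row per stimulus.
#' @export
stimulus_record <- function(id, familiarity, tempo_bpm, mode, genre,
                            has_lyrics, language = NA_character_,
                            liking = NA_character_) {
  stopifnot(all(familiarity %in% c("familiar", "unfamiliar")),
            all(mode %in% c("major", "minor")),
            is.logical(has_lyrics))
  language <- ifelse(has_lyrics, as.character(language), NA_character_)
  data.frame(
    id = as.character(id),
    familiarity = familiarity,
    liking = as.character(liking),
    tempo_bpm = as.numeric(tempo_bpm),
    tempo_class = classify_tempo(tempo_bpm),
    mode = mode,
    genre = as.character(genre),
    has_lyrics = has_lyrics,
    language = language,
    stringsAsFactors = FALSE
  )
}

stimuli_compatible <- function(a, b) {
  ok <- a$tempo_class == b$tempo_class &&
    a$mode == b$mode &&
    a$genre == b$genre &&
    a$has_lyrics == b$has_lyrics
  if (ok && isTRUE(a$has_lyrics)) {
    ok <- identical(a$language, b$language)
  }
  ok
}

#' Match familiar songs with unfamiliar pool songs on musical features
#'
#' Pairs each familiar excerpt with a distinct unfamiliar excerpt agreeing
#' on tempo class, mode, genre, presence of lyrics and (for songs with
#' lyrics) lyric language. Matching is greedy first-fit in input order;
#' familiar songs with no remaining compatible candidate are reported as
#' unmatched rather than raising an error.
#'
#' @param familiar `data.frame` of familiar stimuli (see [stimulus_record()]).
#' @param pool `data.frame` of unfamiliar candidate stimuli.
#' @return A list with `pairs` (data.frame of `familiar_id`, `unfamiliar_id`)
#'   and `unmatched` (character vector of familiar ids left unmatched).
#' @export
match_stimuli <- function(familiar, pool) {
  stopifnot(is.data.frame(familiar), is.data.frame(pool))
  if (nrow(pool) == 0L) stop("unfamiliar pool is empty", call. = FALSE)
  if (!all(pool$familiarity == "unfamiliar")) {
    stop("pool must contain only unfamiliar stimuli", call. = FALSE)
  }
  used <- rep(FALSE, nrow(pool))
  pairs_f <- character(0)
  pairs_u <- character(0)
  unmatched <- character(0)
  for (i in seq_len(nrow(familiar))) {
    hit <- 0L
    for (j in seq_len(nrow(pool))) {
      if (!used[j] && stimuli_compatible(familiar[i, ], pool[j, ])) {
        hit <- j
        break
      }
    }
    if (hit > 0L) {
      used[hit] <- TRUE
      pairs_f <- c(pairs_f, familiar$id[i])
      pairs_u <- c(pairs_u, pool$id[hit])
    } else {
      unmatched <- c(unmatched, familiar$id[i])
    }
  }
  list(
    pairs = data.frame(familiar_id = pairs_f, unfamiliar_id = pairs_u,
                       stringsAsFactors = FALSE),
    unmatched = unmatched
  )
}

#' Define the music-task paradigm
#'
#' The default paradigm is 8 familiar-liked + 8 familiar-disliked + 24
#' unfamiliar 30 s excerpts delivered in 4 task runs of 10 excerpts, flanked
#' by two 3 min resting-state runs, sampled at 600 Hz.
#'
#' @param n_familiar_liked,n_familiar_disliked,n_unfamiliar Excerpt counts.
#' @param n_task_runs,excerpts_per_run Run structure.
#' @param trial_duration_s,rest_duration_s Durations in seconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return A validated list of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_familiar_liked = 8L, n_familiar_disliked = 8L,
                          n_unfamiliar = 24L, n_task_runs = 4L,
                          excerpts_per_run = 10L, trial_duration_s = 30,
                          rest_duration_s = 180, sampling_rate_hz = 600) {
  spec <- list(
    n_familiar_liked = as.integer(n_familiar_liked),
    n_familiar_disliked = as.integer(n_familiar_disliked),
    n_unfamiliar = as.integer(n_unfamiliar),
    n_task_runs = as.integer(n_task_runs),
    excerpts_per_run = as.integer(excerpts_per_run),
    trial_duration_s = trial_duration_s,
    rest_duration_s = rest_duration_s,
    sampling_rate_hz = sampling_rate_hz
  )
  counts <- c(spec$n_familiar_liked + spec$n_familiar_disliked + spec$n_unfamiliar,
              spec$n_task_runs, spec$excerpts_per_run)
  if (spec$n_familiar_liked < 0L || spec$n_familiar_disliked < 0L ||
      spec$n_unfamiliar < 0L || any(counts[-1] <= 0L) ||
      spec$trial_duration_s <= 0 || spec$rest_duration_s <= 0 ||
      spec$sampling_rate_hz <= 0) {
    stop("paradigm counts and durations must be positive", call. = FALSE)
  }
  total <- spec$n_familiar_liked + spec$n_familiar_disliked + spec$n_unfamiliar
  if (total != spec$n_task_runs * spec$excerpts_per_run) {
    stop(sprintf(
      "excerpt counts (%d) must equal n_task_runs * excerpts_per_run (%d)",
      total, spec$n_task_runs * spec$excerpts_per_run), call. = FALSE)
  }
  structure(spec, class = "paradigm_spec")
}

#' Build a per-subject trial manifest from a paradigm spec
#'
#' Lays out all music excerpts across the task runs (stimulus order
#' randomized when `shuffle = TRUE`) and appends two resting-state records.
#' Each music trial carries both the stimulus-defined condition and the
#' response-derived condition used for analysis; the latter defaults to the
#' stimulus label but can be flipped per trial to emulate in-scanner
#' familiarity ratings that disagree with the pre-selected labels.
#'
#' @param spec A [paradigm_spec()].
#' @param subject Subject id.
#' @param group Group label (e.g. `"ASD"` or `"TD"`).
#' @param shuffle Randomize excerpt order across runs.
#' @param response_flip_rate Probability that a trial's response-derived
#'   familiarity label disagrees with the stimulus label (default 0).
#' @return A `data.frame` manifest with columns `subject`, `group`, `run`,
#'   `trial`, `stimulus`, `liking`, `condition_stimulus`,
#'   `condition_response`, `is_rest`, `motion_mm` (filled with `NA`; the
#'   simulator supplies motion).
#' @export
build_paradigm <- function(spec, subject = "S01", group = "TD",
                           shuffle = FALSE, response_flip_rate = 0) {
  stopifnot(inherits(spec, "paradigm_spec"),
            response_flip_rate >= 0, response_flip_rate <= 1)
  fam <- c(rep("familiar", spec$n_familiar_liked + spec$n_familiar_disliked),
           rep("unfamiliar", spec$n_unfamiliar))
  liking <- c(rep("liked", spec$n_familiar_liked),
              rep("disliked", spec$n_familiar_disliked),
              rep(NA_character_, spec$n_unfamiliar))
  stim <- sprintf("stim%02d", seq_along(fam))
  ord <- if (shuffle) sample.int(length(fam)) else seq_along(fam)
  n_music <- length(fam)
  run <- rep(seq_len(spec$n_task_runs), each = spec$excerpts_per_run)
  cond_resp <- fam[ord]
  if (response_flip_rate > 0) {
    flip <- stats::runif(n_music) < response_flip_rate
    cond_resp[flip] <- ifelse(cond_resp[flip] == "familiar",
                              "unfamiliar", "familiar")
  }
  music <- data.frame(
    subject = subject, group = group, run = run,
    trial = seq_len(n_music),
    stimulus = stim[ord],
    liking = liking[ord],
    condition_stimulus = fam[ord],
    condition_response = cond_resp,
    is_rest = FALSE,
    motion_mm = NA_real_,
    stringsAsFactors = FALSE
  )
  rest <- data.frame(
    subject = subject, group = group, run = c(0L, spec$n_task_runs + 1L),
    trial = n_music + 1:2,
    stimulus = c("rest_pre", "rest_post"),
    liking = NA_character_,
    condition_stimulus = "rest",
    condition_response = "rest",
    is_rest = TRUE,
    motion_mm = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(music, rest)
}
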