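# shared fixtures: small band tables, random symmetric matrices, toy
# manifests -- everything generated in code at test time

one_band <- function(label = "alpha", lo = 8, hi = 14) {
  data.frame(label = label, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

# n subjects of p x p symmetric zero-diagonal edge-noise matrices, with an
# optional additive effect on given edges
random_symmetric_matrices <- function(n, p, effect_edges = NULL, delta = 0) {
  lapply(seq_len(n), function(s) {
    M <- matrix(0, p, p)
    M[upper.tri(M)] <- stats::rnorm(p * (p - 1) / 2)
    M <- M + t(M)
    if (!is.null(effect_edges)) {
      for (r in seq_len(nrow(effect_edges))) {
        i <- effect_edges[r, 1]; j <- effect_edges[r, 2]
        M[i, j] <- M[i, j] + delta
        M[j, i] <- M[i, j]
      }
    }
    M
  })
}

# clique edge set on the first k nodes (robust planted subnetwork)
clique_edges <- function(k) t(utils::combn(k, 2))

toy_manifest <- function(subject, n_familiar, n_unfamiliar,
                         motion = 0, group = "TD") {
  n <- n_familiar + n_unfamiliar
  data.frame(
    subject = subject, group = group, run = 1L, trial = seq_len(n),
    stimulus = sprintf("s%02d", seq_len(n)),
    liking = NA_character_,
    condition_stimulus = rep(c("familiar", "unfamiliar"),
                             c(n_familiar, n_unfamiliar)),
    condition_response = rep(c("familiar", "unfamiliar"),
                             c(n_familiar, n_unfamiliar)),
    is_rest = FALSE,
    motion_mm = rep_len(motion, n),
    stringsAsFactors = FALSE
  )
}

stimulus_pool <- function(n, familiarity = "unfamiliar", seed = 1) {
  set.seed(seed)
  tempo <- stats::runif(n, 41, 207)
  lyr <- stats::runif(n) < 0.7
  stimulus_record(
    id = sprintf("%s%03d", substr(familiarity, 1, 1), seq_len(n)),
    familiarity = familiarity,
    tempo_bpm = tempo,
    mode = sample(c("major", "minor"), n, replace = TRUE),
    genre = sample(c("pop", "rock", "classic"), n, replace = TRUE),
    has_lyrics = lyr,
    language = ifelse(lyr, sample(c("English", "French", "Spanish"), n,
                                  replace = TRUE), NA)
  )
}

# brute-force pair-compatibility oracle used against match_stimuli
stimuli_match_ok <- function(a, b) {
  a$tempo_class == b$tempo_class && a$mode == b$mode &&
    a$genre == b$genre && a$has_lyrics == b$has_lyrics &&
    (!a$has_lyrics || identical(a$language, b$language))
}
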