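#!/usr/bin/env Rscript
# Paradigm construction: tempo-binned stimulus matching and the 40-trial
# music task layout (8 familiar-liked + 8 familiar-disliked + 24 unfamiliar
# excerpts over 4 runs, flanked by two rest runs).
#
# Writes: results/stimulus_matching.tsv, results/paradigm_manifest.tsv

library(megfc)
dir.create("results", showWarnings = FALSE)
set.seed(1)

# a synthetic participant music list: 16 familiar excerpts and a 40-song
# unfamiliar candidate pool with the same feature distribution
mk_pool <- function(n, familiarity, prefix) {
  tempo <- runif(n, 45, 200)
  lyr <- runif(n) < 0.9
  stimulus_record(
    id = sprintf("%s%03d", prefix, seq_len(n)), familiarity = familiarity,
    tempo_bpm = tempo,
    mode = sample(c("major", "minor"), n, replace = TRUE),
    genre = sample(c("pop", "rock", "classic"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2)),
    has_lyrics = lyr,
    language = ifelse(lyr, sample(c("English", "French", "Spanish"), n,
                                  replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                      NA))
}
familiar <- mk_pool(16, "familiar", "f")
familiar$liking <- rep(c("liked", "disliked"), each = 8)
pool <- mk_pool(40, "unfamiliar", "u")

m <- match_stimuli(familiar, pool)
cat(sprintf("matched %d of %d familiar excerpts (%d unmatched)\n",
            nrow(m$pairs), nrow(familiar), length(m$unmatched)))
write.table(m$pairs, "results/stimulus_matching.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

man <- build_paradigm(paradigm_spec(), subject = "S01", group = "TD",
                      shuffle = TRUE)
cat(sprintf("paradigm: %d music trials across %d runs, %d rest records\n",
            sum(!man$is_rest), length(unique(man$run[!man$is_rest])),
            sum(man$is_rest)))
write_manifest(man, "results/paradigm_manifest.tsv")

tab <- table(classify_tempo(familiar$tempo_bpm))
cat("familiar tempo classes:", paste(names(tab), tab, collapse = ", "), "\n")
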