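# Fitted models are expensive to calibrate and train, and composition never
# mutates them, so read-only fixtures are memoized per test run. Tests that
# continue training always build their own model.
.model_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, builder) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

fit_shared_prefix <- function() {
  cached_fit("shared_prefix", function() melody_snn(shared_prefix_fixture()))
}

fit_k545 <- function() {
  cached_fit("k545", function() melody_snn(k545_prefix()))
}

# single 20-note random-walk piece by one composer
walk20_piece <- function() {
  random_walk_corpus(fixture_spec(
    n_pieces = 1, notes_per_piece = 20, genres = "classical",
    composers = "Haydn", seed = 42))[[1]]
}

fit_walk20 <- function() {
  cached_fit("walk20", function() melody_snn(walk20_piece()))
}

# two composers with disjoint pitch ranges (no shared bigrams possible);
# one piece each, so within-composer recombination cannot occur either
disjoint_corpus <- function() {
  random_walk_corpus(fixture_spec(
    n_pieces = 2, notes_per_piece = 8,
    genres = c("classical", "romantic"),
    composers = c("Mozart", "Chopin"),
    disjoint_ranges = TRUE, seed = 11))
}

fit_disjoint <- function() {
  cached_fit("disjoint", function() melody_snn(disjoint_corpus()))
}

note_bigrams <- function(melody) {
  if (nrow(melody) < 2) return(character(0))
  paste(melody$pitch[-nrow(melody)], melody$duration[-nrow(melody)],
        melody$pitch[-1], melody$duration[-1], sep = ":")
}
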