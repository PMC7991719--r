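test_that("learning the sonata opening stores the narrated path", {
  fit <- fit_k545()
  h <- fit$state$history
  expect_equal(unname(h$winners[[1]]["P"]), "P:1:72")   # C5
  expect_equal(unname(h$winners[[1]]["D"]), "D:1:15")   # 960 ticks
  expect_equal(unname(h$winners[[2]]["P"]), "P:2:76")   # E5
  expect_equal(unname(h$winners[[3]]["P"]), "P:3:79")   # G5
  tab <- synapse_table(fit$store)
  w <- function(pre, post) tab$weight[tab$pre == pre & tab$post == post]
  expect_gt(w("P:1:72", "P:2:76"), 0)
  expect_gt(w("P:2:76", "P:3:79"), 0)
  expect_gt(w("P:1:72", "P:3:79"), 0)  # distance-2 link via delayed spikes
  expect_equal(tab$delay_slots[tab$pre == "P:1:72" & tab$post == "P:3:79"], 2L)
  expect_gt(w("D:1:15", "D:2:7"), 0)
  # knowledge-to-memory and title feedback for every visited winner
  for (post in c("P:1:72", "P:2:76", "P:3:79")) {
    expect_gt(w("G:Classical", post), 0)
    expect_gt(w("C:Mozart", post), 0)
    expect_gt(w("T:K545", post), 0)
    expect_gt(w(post, "T:K545"), 0)
  }
})

test_that("the first note creates no inter-layer synapses", {
  model <- melody_snn(sm_piece("g", "c", "one-note",
                               data.frame(pitch = 60L, duration = 480L)))
  tab <- synapse_table(model$store)
  mem <- tab[grepl("^[PD]:", tab$pre) & grepl("^[PD]:", tab$post) &
               !grepl("^T:", tab$post), ]
  expect_equal(nrow(mem), 0)
  expect_gt(tab$weight[tab$pre == "G:g" & tab$post == "P:1:60"], 0)
})

test_that("relearning a piece weakly increases its weights up to the cap", {
  piece <- k545_prefix()
  model <- melody_snn(piece)
  w1 <- synapse_table(model$store)
  learn_track(model, piece)
  w2 <- synapse_table(model$store)
  merged <- merge(w1, w2, by = c("pre", "post"))
  plastic <- merged[merged$plastic.x, ]
  expect_true(all(plastic$weight.y >= plastic$weight.x))
  expect_true(any(plastic$weight.y > plastic$weight.x))
  expect_true(all(plastic$weight.y <= model$config$w_max))
})

test_that("exactly one column per subnetwork fires in each learning slot", {
  corpus <- random_walk_corpus(fixture_spec(
    n_pieces = 1, notes_per_piece = 20, composers = "Solo", seed = 8))
  model <- spikemelody:::new_melody_snn()
  piece <- corpus[[1]]
  model$state$history <- spikemelody:::new_history()
  labels <- list(genre = piece$genre, composer = piece$composer,
                 title = piece$title)
  for (s in seq_len(nrow(piece$melody))) {
    know <- activate_labels(model, labels, "learning")
    raster <- present_note(model, note(piece$melody$pitch[s],
                                       piece$melody$duration[s]), s, know)
    for (pfx in c("P:", "D:")) {
      active <- names(raster$times)[startsWith(names(raster$times), pfx) &
                                      lengths(raster$times) > 0]
      expect_length(active, 1)
    }
  }
})

test_that("sequence order is encoded in the directed weight structure", {
  fit <- fit_walk20()
  piece <- walk20_piece()
  tab <- synapse_table(fit$store)
  mem <- tab[startsWith(tab$pre, "P:") & startsWith(tab$post, "P:"), ]
  # along the path: consecutive-layer weights all positive
  for (s in seq_len(nrow(piece$melody) - 1)) {
    pre <- paste0("P:", s, ":", piece$melody$pitch[s])
    post <- paste0("P:", s + 1, ":", piece$melody$pitch[s + 1])
    expect_gt(mem$weight[mem$pre == pre & mem$post == post], 0)
  }
  # nothing points at columns that never won a slot
  on_path <- paste0("P:", seq_len(nrow(piece$melody)), ":", piece$melody$pitch)
  expect_true(all(mem$post %in% on_path))
  expect_true(all(mem$weight > 0))
})

test_that("ten pieces coexist and each replays under its own composer cue", {
  composers <- paste0("Composer", 1:10)
  corpus <- random_walk_corpus(fixture_spec(
    n_pieces = 10, notes_per_piece = 10, genres = c("classical", "romantic"),
    composers = composers, disjoint_ranges = TRUE, seed = 55))
  fit <- melody_snn(corpus)
  for (piece in corpus) {
    out <- compose(fit, style_cue("composer", piece$composer),
                   piece$melody[1, ], 10, keep_rasters = FALSE)
    expect_identical(out$notes$pitch, piece$melody$pitch)
    expect_identical(out$notes$duration, piece$melody$duration)
  }
})

test_that("a slot beyond the layer cap is rejected", {
  cfg <- sm_config(layer_cap = 3)
  long_piece <- sm_piece("g", "c", "long", data.frame(
    pitch = rep(60L, 4), duration = rep(480L, 4)))
  expect_error(melody_snn(long_piece, cfg), "layer cap")
})
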