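test_that("winner selection follows first-spike order with documented ties", {
  r <- structure(list(times = list(`60` = c(12, 40), `81` = c(19, 30)),
                      window_ms = 250, dt = 0.5), class = "sm_raster")
  expect_equal(select_winner(r), 60L)
  r2 <- structure(list(times = list(`7` = c(10, 20, 30), `5` = c(10, 15, 20, 25)),
                       window_ms = 250, dt = 0.5), class = "sm_raster")
  expect_equal(select_winner(r2), 5L)  # same first spike, higher count wins
  r3 <- structure(list(times = list(`9` = c(10, 20), `4` = c(10, 20)),
                       window_ms = 250, dt = 0.5), class = "sm_raster")
  expect_equal(select_winner(r3), 4L)  # full tie: lowest column
  r4 <- structure(list(times = list(`3` = c(5)), window_ms = 250, dt = 0.5),
                  class = "sm_raster")
  expect_equal(select_winner(r4), 3L)
  empty <- structure(list(times = list(`3` = numeric(0)), window_ms = 250,
                          dt = 0.5), class = "sm_raster")
  expect_error(select_winner(empty), class = "sm_dead_end")
})

test_that("the genre cue resolves the shared-prefix competition both ways", {
  fit <- fit_shared_prefix()
  seeds <- shared_prefix_fixture()$classical$melody[1:2, ]
  classical <- compose(fit, "genre:classical", seeds, 4)
  expect_equal(classical$notes$pitch[3], 60L)   # C4, not A5
  expect_equal(classical$notes$pitch[4], 62L)   # D4
  expect_equal(classical$notes$duration, c(240L, 120L, 240L, 120L))
  romantic <- compose(fit, "genre:romantic", seeds, 4)
  expect_equal(romantic$notes$pitch[3], 81L)    # A5: the mirrored branch
  expect_equal(romantic$notes$provenance, c("seed", "seed", "generated",
                                            "generated"))
})

test_that("a single stored piece replays exactly under its composer's cue", {
  fit <- fit_walk20()
  piece <- walk20_piece()
  out <- compose(fit, style_cue("composer", piece$composer),
                 piece$melody[1, ], nrow(piece$melody), keep_rasters = FALSE)
  expect_equal(out$notes$pitch, piece$melody$pitch)
  expect_equal(out$notes$duration, piece$melody$duration)
})

test_that("composition is deterministic for a fixed model, cue and seeds", {
  fit <- fit_shared_prefix()
  seeds <- shared_prefix_fixture()$classical$melody[1:2, ]
  a <- compose(fit, "genre:classical", seeds, 4, keep_rasters = FALSE)
  b <- compose(fit, "genre:classical", seeds, 4, keep_rasters = FALSE)
  expect_identical(a$notes, b$notes)
})

test_that("composer-cued output only uses that composer's bigrams", {
  fit <- fit_disjoint()
  corpus <- disjoint_corpus()
  for (comp in c("Mozart", "Chopin")) {
    own <- corpus[vapply(corpus, `[[`, character(1), "composer") == comp]
    learned <- unlist(lapply(own, function(p) note_bigrams(p$melody)))
    seed <- own[[1]]$melody[1, ]
    out <- compose(fit, style_cue("composer", comp), seed, 6,
                   keep_rasters = FALSE)
    expect_true(all(note_bigrams(out$notes) %in% learned))
  }
})

test_that("every firing neuron holds the gamma band during composition", {
  fit <- fit_shared_prefix()
  seeds <- shared_prefix_fixture()$classical$melody[1:2, ]
  m <- compose(fit, "genre:classical", seeds, 4)
  secs <- m$slot_ms / 1000
  rate_ok <- function(raster) {
    n <- lengths(raster$times)
    rates <- n[n > 0] / secs
    all(rates >= 30 & rates <= 80)
  }
  for (slot in m$rasters) {
    expect_true(rate_ok(slot$P))
    expect_true(rate_ok(slot$D))
  }
  expect_true(rate_ok(m$knowledge$cue))
  expect_true(rate_ok(m$knowledge$pool))
})

test_that("output length always matches the request", {
  fit <- fit_disjoint()
  corpus <- disjoint_corpus()
  set.seed(31)
  for (i in 1:100) {
    p <- corpus[[sample.int(length(corpus), 1)]]
    n_seed <- sample(1:2, 1)
    len <- sample((n_seed + 1):6, 1)
    out <- compose(fit, style_cue("composer", p$composer),
                   p$melody[seq_len(n_seed), ], len, keep_rasters = FALSE)
    expect_equal(nrow(out$notes), len)
    expect_equal(out$notes$pitch[seq_len(n_seed)],
                 p$melody$pitch[seq_len(n_seed)])
  }
})

test_that("a dead end names its slot and greedy restart recovers cycles", {
  cyc <- sm_piece("classical", "Looper", "cycle", data.frame(
    pitch = c(60L, 64L, 60L), duration = c(480L, 480L, 480L)))
  fit <- melody_snn(cyc)
  expect_error(
    compose(fit, "composer:Looper", cyc$melody[1, ], 6, keep_rasters = FALSE),
    "dead end at slot 4", class = "sm_dead_end")
  out <- compose(fit, "composer:Looper", cyc$melody[1, ], 6,
                 greedy_restart = TRUE, keep_rasters = FALSE)
  expect_equal(nrow(out$notes), 6)
  expect_equal(out$notes$pitch, c(60L, 64L, 60L, 64L, 60L, 64L))
})

test_that("seed validation rejects impossible requests", {
  fit <- fit_k545()
  seeds <- data.frame(pitch = 72L, duration = 960L)
  expect_error(compose(fit, "composer:Mozart", seeds, 1), "seed count")
  expect_error(compose(fit, "composer:Mozart", seeds[0, ], 3), "seed count")
})
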