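test_that("the fitted model exposes the standard modelling verbs", {
  fit <- fit_shared_prefix()
  expect_s3_class(fit, "melody_snn")
  expect_output(print(fit), "pieces learned: 2")
  s <- summary(fit)
  expect_equal(s$n_pieces, 2)
  expect_equal(unname(s$clusters), c(2, 2, 2))
  expect_output(print(s), "Synapses by kind")
  cf <- coef(fit)
  expect_true(all(c("pre", "post", "weight", "delay_slots", "sign",
                    "plastic") %in% names(cf)))
  expect_true(all(cf$weight[cf$plastic] >= 0 &
                    cf$weight[cf$plastic] <= fit$config$w_max))
  expect_true(all(cf$delay_slots[cf$sign == "inh"] == 0))
  seeds <- shared_prefix_fixture()$classical$melody[1:2, ]
  p1 <- predict(fit, "genre:classical", seeds, 4, keep_rasters = FALSE)
  p2 <- compose(fit, "genre:classical", seeds, 4, keep_rasters = FALSE)
  expect_identical(p1$notes, p2$notes)
})

test_that("simulate draws reproducible cue-consistent melodies", {
  fit <- fit_disjoint()
  a <- simulate(fit, nsim = 2, seed = 4, cue = "composer:Mozart",
                keep_rasters = FALSE)
  b <- simulate(fit, nsim = 2, seed = 4, cue = "composer:Mozart",
                keep_rasters = FALSE)
  expect_identical(lapply(a, `[[`, "notes"), lapply(b, `[[`, "notes"))
  corpus <- disjoint_corpus()
  mozart <- corpus[vapply(corpus, `[[`, character(1), "composer") == "Mozart"]
  learned <- unlist(lapply(mozart, function(p) note_bigrams(p$melody)))
  for (m in a) expect_true(all(note_bigrams(m$notes) %in% learned))
  expect_error(simulate(fit, cue = "composer:Nobody"), "no learned piece")
})

test_that("model archives are byte-identical and round-trip exactly", {
  fit <- melody_snn(shared_prefix_fixture())
  f1 <- withr::local_tempfile(fileext = ".smz")
  f2 <- withr::local_tempfile(fileext = ".smz")
  write_melody_snn(fit, f1)
  write_melody_snn(fit, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_melody_snn(f1)
  expect_identical(synapse_table(back), synapse_table(fit))  # exact weights
  expect_identical(back$reg$composer, fit$reg$composer)
  expect_identical(back$state$n_layers, fit$state$n_layers)
  expect_equal(back$cal, fit$cal)
  seeds <- shared_prefix_fixture()$classical$melody[1:2, ]
  a <- compose(fit, "genre:classical", seeds, 4, keep_rasters = FALSE)
  b <- compose(back, "genre:classical", seeds, 4, keep_rasters = FALSE)
  expect_identical(a$notes, b$notes)
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("junk", f3)
  expect_error(read_melody_snn(f3))
})

test_that("configurations hash stably and round-trip through text", {
  cfg <- sm_config()
  expect_identical(config_hash(cfg), config_hash(sm_config()))
  expect_false(identical(config_hash(cfg),
                         config_hash(sm_config(theta_hz = 7))))
  f <- withr::local_tempfile(fileext = ".cfg")
  spikemelody:::write_config(sm_config(gamma_hz = 40, seed = 9L), f)
  back <- spikemelody:::read_config(f)
  expect_equal(back$gamma_hz, 40)
  expect_equal(back$seed, 9L)
  expect_identical(config_hash(back),
                   config_hash(sm_config(gamma_hz = 40, seed = 9L)))
})

test_that("the command-line pipeline learns, composes and demos end to end", {
  dir <- withr::local_tempdir()
  meta <- write_corpus(shared_prefix_fixture(), file.path(dir, "corpus"))
  model_path <- file.path(dir, "model.smz")
  suppressMessages(cmd_learn(meta, model_path, quiet = TRUE))
  expect_true(file.exists(model_path))
  # determinism: relearning writes a byte-identical archive
  model_path2 <- file.path(dir, "model2.smz")
  suppressMessages(cmd_learn(meta, model_path2, quiet = TRUE))
  expect_identical(readBin(model_path, "raw", file.size(model_path)),
                   readBin(model_path2, "raw", file.size(model_path2)))
  out_mid <- file.path(dir, "out.mid")
  mel <- cmd_compose(model_path, "genre:classical", "A5:240,E4:120", 4,
                     out_mid, quiet = TRUE)
  expect_equal(nrow(mel$notes), 4)
  expect_equal(mel$notes$pitch[3], 60L)
  expect_equal(read_midi(out_mid)$melody$pitch, mel$notes$pitch)
  expect_error(cmd_compose(model_path, "composer:Unknown", "A5:240", 3,
                           out_mid, quiet = TRUE), "not learned")
  # encoding demo on the worked example
  demo <- cmd_demo_encode(k545_prefix(), quiet = TRUE)
  expect_equal(demo$pitch_col, c(72L, 76L, 79L))
  expect_equal(demo$duration_col, c(15L, 7L, 7L))
  expect_true(all(demo$spikes >= 4 & demo$spikes <= 8))
  # a corrupt MIDI file in the metadata is a named error
  bad_dir <- file.path(dir, "bad")
  dir.create(bad_dir)
  writeBin(charToRaw("garbage"), file.path(bad_dir, "x.mid"))
  utils::write.csv(data.frame(path = "x.mid", title = "t", composer = "c",
                              genre = "g"),
                   file.path(bad_dir, "meta.csv"), row.names = FALSE)
  expect_error(cmd_learn(file.path(bad_dir, "meta.csv"),
                         file.path(bad_dir, "m.smz"), quiet = TRUE),
               "not a standard MIDI file")
})
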