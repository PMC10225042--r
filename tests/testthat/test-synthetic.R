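# Synthetic maneuver generator and channel model.

test_that("generation is deterministic given the seed", {
  g1 <- generate_maneuver(maneuver_spec("voluntary_cough", seed = 42))
  g2 <- generate_maneuver(maneuver_spec("voluntary_cough", seed = 42))
  expect_identical(g1$waveform$samples, g2$waveform$samples)
  g3 <- generate_maneuver(maneuver_spec("voluntary_cough", seed = 43))
  expect_false(identical(g1$waveform$samples, g3$waveform$samples))
})

test_that("annotations partition the waveform without overlap", {
  for (cl in c("voluntary_cough", "throat_clearing", "reflexive_cough")) {
    g <- generate_maneuver(maneuver_spec(cl, seed = 0))
    a <- g$annotation
    expect_equal(a$start[1], 0L)
    expect_equal(a$end[nrow(a)], length(g$waveform$samples))
    expect_equal(a$start[-1], a$end[-nrow(a)])  # contiguous, no overlap
    expect_true(all(a$end >= a$start))
  }
})

test_that("invalid maneuver specs are rejected", {
  expect_error(maneuver_spec("voluntary_cough", duration_s = 0.05),
               "duration_s must exceed")
  expect_error(maneuver_spec("voluntary_cough",
                             onset_pulse = list(gain = -1)), "gains")
  expect_error(maneuver_spec("voluntary_cough", bogus = 1), "unknown")
  expect_error(maneuver_spec("sneeze"))
})

test_that("class structure matches the intended acoustics", {
  # voluntary cough: onset frames much louder than late frication frames
  g <- generate_maneuver(maneuver_spec("voluntary_cough", seed = 5,
                                       voiced_coda = list(probability = 0)))
  x <- g$waveform$samples
  a <- g$annotation
  on <- x[(a$start[a$fragment == "onset"] + 1):a$end[a$fragment == "onset"]]
  body <- x[(a$start[a$fragment == "body"] + 1):a$end[a$fragment == "body"]]
  expect_gt(mean(on^2), 4 * mean(body^2))

  # throat clearing: energy concentrated below 800 Hz
  g <- generate_maneuver(maneuver_spec("throat_clearing", seed = 5))
  dec <- dct_band_decompose(trim_segment(g$waveform))
  expect_gt(dec$rel_energy[1] + dec$rel_energy[2], 0.8)

  # reflexive cough: onset pulse is brief and strong
  g <- generate_maneuver(maneuver_spec("reflexive_cough", seed = 5))
  a <- g$annotation
  on_len <- a$end[a$fragment == "onset"] - a$start[a$fragment == "onset"]
  expect_lte(on_len / g$waveform$rate, 0.015)
})

test_that("skin-contact channel attenuates high frequencies", {
  ch <- channel_model("skin_contact")
  tone <- make_tone(3000, dur_s = 0.5)
  out <- apply_channel(tone, ch)
  expect_lte(sum(out$samples^2) / sum(tone$samples^2), 0.01)

  # free-standing is the identity
  expect_identical(apply_channel(tone, channel_model("free_standing")), tone)

  # weighted frequency strictly decreases through the tissue channel
  for (cl in c("voluntary_cough", "reflexive_cough")) {
    g <- generate_maneuver(maneuver_spec(cl, seed = 9))
    wf_free <- weighted_frequency(dct_band_decompose(trim_segment(g$waveform)))
    wf_skin <- weighted_frequency(dct_band_decompose(
      trim_segment(apply_channel(g$waveform, ch))))
    expect_lt(wf_skin, wf_free)
  }
})

test_that("cohorts have the right shape and subject-level correlation", {
  gen <- generate_cohort(n_subjects = 8, tokens_per_class = 3,
                         classes = c("voluntary_cough", "throat_clearing"),
                         seed = 1)
  expect_equal(nrow(gen$cohort), 8 * 3 * 2)
  expect_length(gen$waveforms, 48)
  expect_s3_class(gen$cohort, "cohort_table")

  gen2 <- generate_cohort(n_subjects = 8, tokens_per_class = 3,
                          classes = c("voluntary_cough", "throat_clearing"),
                          seed = 2)
  expect_equal(dim(gen2$cohort), dim(gen$cohort))
  expect_false(identical(gen$waveforms[[1]]$samples,
                         gen2$waveforms[[1]]$samples))

  # duration multipliers are shared within subject: within-subject variance
  # of log-duration is well below between-subject variance
  gen3 <- generate_cohort(n_subjects = 12, tokens_per_class = 5,
                          classes = "voluntary_cough", seed = 3)
  ld <- log(gen3$cohort$duration_s)
  within <- mean(tapply(ld, gen3$cohort$subject, stats::var))
  between <- stats::var(tapply(ld, gen3$cohort$subject, mean))
  expect_gt(between, within)
})

test_that("cohort files round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(n_subjects = 2, tokens_per_class = 2,
                         classes = "voluntary_cough", seed = 4, dir = dir)
  expect_true(all(file.exists(gen$files)))
  ct <- read_cohort_table(file.path(dir, "cohort.csv"))
  expect_equal(ct$file_id, gen$cohort$file_id)
  w <- read_wav(gen$files[[1]])
  expect_equal(w$rate, 44100)
})
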