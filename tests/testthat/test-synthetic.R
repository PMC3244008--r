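test_that("posture recordings centre on their gravity profile", {
  spec <- activity_spec("posture", dc_profile = c(2, -3, 9.8), noise_sd = 0.05,
                        drift = 0)
  rec <- synth_recording(spec, 7, seed = 1)
  fr <- make_frames(rec, width = 512)[[1]]
  tol <- 3 * 0.05 / sqrt(512)
  expect_true(all(abs(dc_component(fr) - c(2, -3, 9.8)) < tol))
})

test_that("recordings are reproducible by seed and respect Nyquist", {
  spec <- default_activity_specs()$walking
  r1 <- synth_recording(spec, 8, seed = 5)
  r2 <- synth_recording(spec, 8, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  bad <- activity_spec("bad", dc_profile = 0,
                       periodic = list(list(freq = 40, amp = 1, phase = 0)))
  expect_error(synth_recording(bad, 7), "Nyquist")
})

test_that("walking-like frames out-score cycling-like frames on entropy", {
  specs <- default_activity_specs()
  ew <- extract_features(synth_recording(specs$walking, 14, seed = 0))
  ec <- extract_features(synth_recording(specs$cycling, 14, seed = 0))
  mw <- rowMeans(ew[grep("^entropy_", names(ew))])
  mc <- rowMeans(ec[grep("^entropy_", names(ec))])
  expect_true(all(mw > mc))
})

test_that("frame libraries deliver N labelled 85-component vectors per class", {
  specs <- default_activity_specs()
  lib <- build_frame_library(specs, frames_per_class = 3, seed = 1)
  expect_equal(nrow(lib), 3 * 7)
  expect_equal(as.vector(table(lib$label)), rep(3L, 7))
  expect_length(setdiff(names(lib), c("label", "frame_start")), 85L)
  # posture DC means separate by construction
  mu <- tapply(lib$dc_ch1, lib$label, mean)
  expect_gt(abs(mu["lying"] - mu["standing"]), 0.5)
})

test_that("virtual experiments pair OMM states with class-matched frames", {
  lib <- tiny_library(frames_per_class = 5, seed = 2)
  ex <- make_virtual_experiment(tiny_omm(), lib, n_frames = 80, seed = 3)
  expect_equal(nrow(ex), 80)
  expect_true(all(ex$label %in% tiny_omm()$labels))
  expect_false(any(ex$spurious))
  # frames really come from the labelled pools
  lib_mat <- feature_matrix(lib)
  ex_mat <- feature_matrix(ex)
  for (i in c(1, 40, 80)) {
    pool <- lib_mat[lib$label == ex$label[i], , drop = FALSE]
    expect_true(any(apply(pool, 1, function(r) all(r == ex_mat[i, ]))))
  }
  # degenerate identity chain stays in one class
  m1 <- omm(tiny_omm()$labels, c(1, 0, 0), diag(3))
  ex1 <- make_virtual_experiment(m1, lib, 30, seed = 4)
  expect_true(all(ex1$label == "lying"))
  expect_error(make_virtual_experiment(tiny_omm(), lib[lib$label != "cycling", ], 10),
               "cycling")
})

test_that("garbage injection follows the 1:3 insertion arithmetic", {
  lib <- tiny_library(frames_per_class = 5, seed = 5)
  ex <- make_virtual_experiment(tiny_omm(), lib, n_frames = 300, seed = 6)
  garb <- tiny_library(frames_per_class = 4, seed = 7)
  gex <- inject_garbage(ex, garb, ratio = 1 / 3, seed = 8)
  expect_equal(nrow(gex), 400)
  expect_equal(sum(gex$spurious), 100)
  expect_true(all(gex$label[gex$spurious] == "SPURIOUS"))
  # removing masked frames recovers the genuine sequence exactly
  expect_equal(as.data.frame(gex[!gex$spurious, ]), as.data.frame(ex))

  expect_identical(inject_garbage(ex, garb, ratio = 0), ex)
  expect_error(inject_garbage(ex, garb, ratio = -0.1), "non-negative")
  expect_error(inject_garbage(ex, garb, ratio = 0.5), "1/3")
})

test_that("long experiments reproduce the stationary activity frequencies", {
  m <- seven_activity_omm()
  s <- generate_states(m, 1e5, seed = 1)
  freq <- table(factor(s, levels = m$labels)) / length(s)
  st <- stationary_distribution(m)
  expect_lt(max(abs(as.numeric(freq) - st)), 0.02)
})

test_that("identical seeds make the full feature pipeline byte-deterministic", {
  specs <- default_activity_specs()[c("sitting", "running")]
  l1 <- build_frame_library(specs, frames_per_class = 2, seed = 9)
  l2 <- build_frame_library(specs, frames_per_class = 2, seed = 9)
  expect_identical(l1, l2)
})
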