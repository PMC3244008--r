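frame_of <- function(mat, rate = 76.25) {
  structure(list(window = mat, start_index = 0L, rate = rate),
            class = "accel_frame")
}

test_that("DC component is the per-channel mean", {
  expect_equal(unname(dc_component(frame_of(matrix(9.81, 1, 512)))), 9.81)
  expect_equal(unname(dc_component(frame_of(matrix(c(1, 2, 3, 6), 1)))), 3)
  tt <- seq_len(512)
  sine <- sin(2 * pi * 8 * tt / 512)          # integer number of periods
  expect_equal(unname(dc_component(frame_of(rbind(sine)))), 0, tolerance = 1e-9)
})

test_that("variance feature is the mean squared detrended sample", {
  expect_equal(unname(variance_feature(frame_of(matrix(5, 1, 100)))), 0)
  expect_equal(unname(variance_feature(frame_of(rbind(c(1, -1, 1, -1))))), 1)
  x <- rnorm(512)
  v1 <- variance_feature(frame_of(rbind(x)))
  v2 <- variance_feature(frame_of(rbind(3 * x)))
  expect_equal(unname(v2), unname(9 * v1))
})

test_that("spectral energy obeys Parseval and quadratic scaling", {
  expect_equal(unname(energy_feature(frame_of(matrix(7, 1, 512)))), 0)
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- rnorm(512) + sin(2 * pi * 3 * seq_len(512) / 512)
      # independent oracle: direct time-domain summation of squared
      # detrended samples
      expect_equal(unname(energy_feature(frame_of(rbind(x)))),
                   sum((x - mean(x))^2), tolerance = 1e-9)
      expect_equal(unname(energy_feature(frame_of(rbind(2 * x)))),
                   unname(4 * energy_feature(frame_of(rbind(x)))))
    }
  })
})

test_that("spectral entropy is deterministic and flags degenerate channels", {
  fr <- make_frames(toy_recording())[[1]]
  expect_identical(entropy_feature(fr), entropy_feature(fr))
  expect_warning(e0 <- entropy_feature(frame_of(matrix(0, 1, 512))), "degenerate")
  expect_identical(unname(e0), 0)
})

test_that("impact-rich gait frames carry higher spectral entropy than smooth ones", {
  specs <- default_activity_specs()
  walk <- make_frames(synth_recording(specs$walking, 10, seed = 0))[[1]]
  cyc <- make_frames(synth_recording(specs$cycling, 10, seed = 0))[[1]]
  expect_true(all(entropy_feature(walk) > entropy_feature(cyc)))
})

test_that("correlation block is the cosine of detrended channel pairs", {
  x <- rnorm(512)
  fr <- frame_of(rbind(a = x, b = -x))
  cb <- correlation_block(fr)
  expect_named(cb, c("corr_a_a", "corr_a_b", "corr_b_b"))
  expect_equal(unname(cb), c(1, -1, 1))

  tt <- seq_len(512) / 512
  fr2 <- frame_of(rbind(s = sin(2 * pi * 4 * tt), c = cos(2 * pi * 4 * tt)))
  # independent oracle: direct summation of the detrended dot product
  s <- sin(2 * pi * 4 * tt) - mean(sin(2 * pi * 4 * tt))
  co <- cos(2 * pi * 4 * tt) - mean(cos(2 * pi * 4 * tt))
  expect_equal(unname(correlation_block(fr2)[2]),
               sum(s * co) / sqrt(sum(s^2) * sum(co^2)), tolerance = 1e-9)
  expect_lt(abs(correlation_block(fr2)[2]), 1e-9)

  expect_warning(cz <- correlation_block(frame_of(rbind(x, rep(1, 512)))),
                 "zero-norm")
  expect_equal(unname(cz[2]), 0)
  fr3 <- make_frames(toy_recording(channels = 4))[[1]]
  expect_true(all(abs(correlation_block(fr3)) <= 1))
})

test_that("assembled feature vectors have 3c + c(c+1)/2 aligned components", {
  for (c_ in c(1, 2, 5, 10)) {
    fr <- make_frames(toy_recording(n = 512, channels = c_))[[1]]
    v <- assemble_features(fr)
    expect_length(v, 3 * c_ + c_ * (c_ + 1) / 2)
    expect_identical(names(v), names(assemble_features(fr)))
    expect_equal(unname(v[seq_len(c_)]), unname(dc_component(fr)))
  }
})

test_that("extract_features returns one labelled row per frame", {
  ft <- extract_features(toy_recording(n = 1024, channels = 2), label = "walking")
  expect_s3_class(ft, "tbl_df")
  expect_identical(nrow(ft), 3L)
  expect_identical(ft$frame_start, c(0L, 256L, 512L))
  expect_true(all(ft$label == "walking"))
  expect_identical(ncol(ft), 2L + 3L * 2L + 3L)  # frame_start + label + features
})
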