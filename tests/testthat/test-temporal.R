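# Contours (amplitude, sample entropy, kurtosis) and DCT shape descriptors.

norm_seg <- function(x, rate = 44100) normalize_energy(waveform(x, rate))

test_that("frame coverage arithmetic holds, including partial frames", {
  rate <- 1000
  seg <- norm_seg(stats::rnorm(300, sd = 1) + 1, rate)  # 0.3 s
  fr <- frame_segment(seg, frame_s = 0.02, hop_s = 0.01)
  expect_equal(fr$start, seq(1, 300, by = 10))
  lens <- lengths(fr$frames)
  expect_equal(sum(lens == 20), 29)          # full frames
  expect_true(all(lens[lens < 20] < 20))     # trailing partials keep true length

  # frame = segment length: one frame
  fr1 <- frame_segment(seg, frame_s = 0.3, hop_s = 0.3)
  expect_length(fr1$frames, 1L)
  expect_equal(fr1$frames[[1]], seg$samples)

  # tiling frames conserve every sample
  fr2 <- frame_segment(seg, frame_s = 0.02, hop_s = 0.02)
  expect_equal(sum(lengths(fr2$frames)), 300)
  expect_equal(unlist(fr2$frames), seg$samples)

  # shorter than one frame: single whole-segment frame
  seg_short <- norm_seg(stats::rnorm(25) + 2, rate)
  fr3 <- frame_segment(seg_short, frame_s = 0.05, hop_s = 0.05)
  expect_length(fr3$frames, 1L)
})

test_that("amplitude contour of a normalized segment averages to one", {
  # constant segment: all values exactly 1
  seg <- norm_seg(rep(3, 4410))
  ac <- amplitude_contour(seg)
  expect_true(all(abs(ac$values - 1) < 1e-12))

  # seeded noise, tiling frames: frame-length-weighted mean exactly 1
  set.seed(7)
  for (n in c(4410, 5000, 6301)) {
    seg <- norm_seg(stats::rnorm(n))
    ac <- amplitude_contour(seg, hop_s = 0.02)  # hop = frame
    lens <- lengths(frame_segment(seg, 0.02, 0.02)$frames)
    expect_equal(sum(ac$values * lens) / sum(lens), 1, tolerance = 1e-9)
  }

  # quiet half / loud half: contour step ratio equals mean-square ratio
  x <- c(rep(0.1, 8820), rep(1, 8820))   # 10 tiling 20 ms frames each
  seg <- norm_seg(x)
  ac <- amplitude_contour(seg, hop_s = 0.02)
  expect_equal(ac$values[1] / ac$values[20], 0.01, tolerance = 1e-9)
})

test_that("sample entropy matches the brute-force template-count oracle", {
  # periodic toy series: perfectly predictable at m = 2
  x <- rep(c(1, 2, 3), 20)
  expect_equal(sample_entropy(x, m = 2, r = 0.5),
               sampen_bruteforce(x, 2, 0.5))
  expect_equal(sample_entropy(x, m = 2, r = 0.5), 0)  # A = B for a cycle

  set.seed(8)
  for (i in 1:25) {
    n <- sample(20:300, 1)
    x <- stats::rnorm(n)
    r <- stats::runif(1, 0.1, 0.5) * stats::sd(x)
    m <- sample(1:3, 1)
    expect_equal(sample_entropy(x, m, r), sampen_bruteforce(x, m, r),
                 info = sprintf("n=%d m=%d", n, m))
  }
})

test_that("sample entropy behaves like an irregularity measure", {
  set.seed(9)
  n <- 200
  noise <- stats::rnorm(n)
  sine <- sin(2 * pi * 4 * (1:n) / n)
  sine <- sine * stats::sd(noise) / stats::sd(sine)  # matched SD
  r <- 0.2 * stats::sd(noise)
  expect_gt(sample_entropy(noise, 2, r), sample_entropy(sine, 2, r))

  # constant series is perfectly predictable
  expect_equal(sample_entropy(rep(2.5, 50), 2, 0.1), 0)

  # non-increasing in r
  x <- stats::rnorm(150)
  rs <- seq(0.1, 1, by = 0.1) * stats::sd(x)
  vals <- vapply(rs, function(r) sample_entropy(x, 2, r), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("kurtosis anchors: Gaussian 3, sinusoid 1.5, one-hot closed form", {
  set.seed(10)
  expect_equal(kurtosis_pearson(stats::rnorm(1e5)), 3, tolerance = 0.05)
  # full-period sinusoid: 3/2
  t <- (0:9999) / 10000
  expect_equal(kurtosis_pearson(sin(2 * pi * 5 * t)), 1.5, tolerance = 1e-3)
  # one unit impulse among N-1 zeros, N = 100:
  # m4/m2^2 = (p^3 + (1-p)^3) / (p (1-p)), p = 1/100
  x <- c(1, rep(0, 99))
  expect_equal(kurtosis_pearson(x), 0.970300 / 0.0099, tolerance = 1e-12)

  # scale and shift invariance
  y <- stats::rnorm(500)
  expect_equal(kurtosis_pearson(3 * y - 7), kurtosis_pearson(y),
               tolerance = 1e-12)
  # zero-variance frame undefined
  expect_true(is.na(kurtosis_pearson(rep(1, 10))))
})

test_that("contour kinds carry NA for undefined frames and feed shapes", {
  rate <- 8000
  x <- c(rep(0, 400), stats::rnorm(2000), rep(0, 400))  # flat ends
  seg <- structure(list(samples = x, rate = rate, duration = length(x) / rate),
                   class = "cough_segment")
  ku <- kurtosis_contour(seg, 0.02, 0.02)
  expect_true(is.na(ku$values[1]))      # zero-variance frame
  expect_false(anyNA(ku$values[5:10]))
  sh <- contour_shape(ku)               # NA frames dropped
  expect_length(sh, 3L)
})

test_that("shape coefficients obey the sign conventions", {
  # constant contour -> (c, 0, 0)
  expect_equal(contour_shape(rep(5, 40)),
               c(average = 5, slope = 0, curvature = 0), tolerance = 1e-12)
  # decreasing contour -> positive slope coefficient; increasing -> negative
  dec <- seq(10, 1, length.out = 50)
  expect_gt(contour_shape(dec)[["slope"]], 0)
  expect_lt(contour_shape(rev(dec))[["slope"]], 0)
  # convex (downward-upward) -> positive curvature; concave -> negative
  t <- seq(-1, 1, length.out = 50)
  convex <- t^2
  expect_gt(contour_shape(convex)[["curvature"]], 0)
  expect_lt(contour_shape(-convex)[["curvature"]], 0)
  expect_lt(abs(contour_shape(convex)[["slope"]]), 1e-10)  # symmetric

  expect_error(contour_shape(c(1, 2)), "at least 3")
})

test_that("shape descriptor algebra: linearity and time-reversal symmetry", {
  set.seed(12)
  c1 <- stats::rnorm(30)
  c2 <- stats::rnorm(30)
  sh <- function(v) contour_shape(v)
  expect_equal(sh(2 * c1 - 3 * c2), 2 * sh(c1) - 3 * sh(c2),
               tolerance = 1e-12)
  rev_sh <- sh(rev(c1))
  expect_equal(rev_sh[["average"]], sh(c1)[["average"]], tolerance = 1e-12)
  expect_equal(rev_sh[["slope"]], -sh(c1)[["slope"]], tolerance = 1e-12)
  expect_equal(rev_sh[["curvature"]], sh(c1)[["curvature"]], tolerance = 1e-12)
})
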