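# RGB -> CIELAB chain: analytic cases, the printed-dialect audit trail, the
# exact inverse, and the gray-axis / monotonicity / scaling properties.

test_that("linearization maps the anchors correctly in both dialects", {
  expect_equal(linearize_rgb(c(255, 255, 255)), c(100, 100, 100))
  expect_equal(linearize_rgb(c(0, 0, 0)), c(0, 0, 0))
  # hand evaluation: ((128/255 + 0.055)/1.055)^2.4 * 100
  expect_equal(linearize_rgb(c(128, 128, 128)),
               rep(((128 / 255 + 0.055) / 1.055)^2.4 * 100, 3),
               tolerance = 1e-12)
  expect_equal(unname(linearize_rgb(c(128, 128, 128))[1]), 21.59, tolerance = 1e-2)
  # literal typeset formula overshoots the scale at white
  expect_equal(linearize_rgb(c(255, 255, 255), dialect = "as_printed"),
               rep((1.055^2.4 / 1.055) * 100, 3))
  expect_equal(unname(linearize_rgb(c(255, 255, 255), "as_printed")[1]),
               107.78, tolerance = 1e-2)
  expect_error(linearize_rgb(c(-1, 0, 0)), "out of range")
  expect_error(linearize_rgb(c(0, 0, 300)), "out of range")
})

test_that("XYZ conversion reproduces the printed row sums", {
  xyz <- rgb_to_xyz(c(100, 100, 100))
  expect_equal(unname(xyz["Y"]), 100)          # Y row sums to 1 exactly
  expect_equal(unname(xyz["X"]), 95.75)        # printed X row sum x 100
  expect_equal(unname(xyz["Z"]), 108.90)
  expect_equal(unname(rgb_to_xyz(c(0, 0, 0))), c(0, 0, 0))
  expect_error(rgb_to_xyz(c(-5, 0, 0)), ">= 0")
})

test_that("CIELAB transform matches analytic values and is continuous", {
  expect_equal(unname(xyz_to_lab(c(0, 0, 0))), c(0, 0, 0))
  white <- xyz_to_lab(rgb_to_xyz(linearize_rgb(c(255, 255, 255))))
  expect_equal(unname(white["L"]), 100, tolerance = 1e-9)
  # nonzero a*, b* at white because the default white point differs from the
  # matrix row sums
  expect_equal(unname(white["a"]), 1.61, tolerance = 0.02)
  expect_equal(unname(white["b"]), -0.94, tolerance = 0.02)
  gray <- xyz_to_lab(rgb_to_xyz(linearize_rgb(c(128, 128, 128))))
  expect_equal(unname(gray["L"]), 53.6, tolerance = 0.05)
  # piecewise f continuous at the threshold to within 1e-6 on the f scale
  # (the printed constants 7.787 and 16/116 leave a ~3e-7 seam in f)
  q <- 0.008856
  lo <- xyz_to_lab(c(1, (q - 1e-10) * 100, 1))
  hi <- xyz_to_lab(c(1, (q + 1e-10) * 100, 1))
  expect_lt(abs(lo["L"] - hi["L"]) / 116, 1e-6)
  expect_error(xyz_to_lab(c(-1, 0, 0)), "negative tristimulus")
})

test_that("hue and chroma follow the atan2 reading of the printed formula", {
  hc <- hue_chroma(-10.23, 36.48)  # printed group-3 mean color
  expect_equal(hc$chroma, sqrt(10.23^2 + 36.48^2))
  expect_equal(hc$chroma, 37.93, tolerance = 0.06)
  expect_equal(hc$hue, 105.59, tolerance = 0.2)
  expect_equal(hue_chroma(1, 0), list(hue = 0, chroma = 1, hue_undefined = FALSE))
  hc2 <- hue_chroma(0, -5)
  expect_equal(hc2$hue, 270)
  expect_equal(hc2$chroma, 5)
  hc0 <- hue_chroma(0, 0)
  expect_true(hc0$hue_undefined)
  expect_equal(hc0$hue, 0)
  # agrees with arccos(a/chroma) reflected by the sign of b
  for (ab in list(c(3, 4), c(-3, 4), c(-3, -4), c(3, -4))) {
    want <- acos(ab[1] / sqrt(sum(ab^2))) * 180 / pi
    if (ab[2] < 0) want <- 360 - want
    expect_equal(hue_chroma(ab[1], ab[2])$hue, want)
  }
})

test_that("lightness index spans 0-240 with the printed formula", {
  expect_equal(lightness_index(c(255, 255, 255)), 240)
  expect_equal(lightness_index(c(0, 0, 0)), 0)
  expect_equal(lightness_index(c(255, 0, 0)), 120)  # (255+0)*240/510
  px <- rbind(c(255, 255, 255), c(0, 0, 0))
  expect_equal(lightness_index(px), 120)
  expect_error(lightness_index(c(0, 0, 999)), "out of range")
})

test_that("rgb_to_record composes the chain and flags black's hue", {
  w <- rgb_to_record(c(255, 255, 255))
  expect_equal(w$L, 100, tolerance = 1e-9)
  expect_equal(w$lightness, 240)
  b <- rgb_to_record(c(0, 0, 0))
  expect_equal(c(b$L, b$a, b$b, b$chroma, b$lightness), rep(0, 5))
  expect_true(b$hue_undefined)
  r <- rgb_to_record(c(200, 180, 90))
  expect_equal(r$chroma, sqrt(r$a^2 + r$b^2), tolerance = 1e-9)
  expect_equal(r$hue, (atan2(r$b, r$a) * 180 / pi) %% 360, tolerance = 1e-9)
})

test_that("lab_to_rgb inverts the forward chain on in-gamut colors", {
  for (rec in list(gray_record(), group3_record(), group4_record())) {
    back <- rgb_to_record(lab_to_rgb(rec$L, rec$a, rec$b))
    expect_lt(abs(back$L - rec$L), 0.5)
    expect_lt(abs(back$a - rec$a), 0.5)
    expect_lt(abs(back$b - rec$b), 0.5)
  }
  expect_error(lab_to_rgb(50, 120, -120), "out-of-gamut")
  err <- tryCatch(lab_to_rgb(99, 0, 90), error = conditionMessage)
  expect_match(err, "[RGB] =", fixed = FALSE)  # offending channel is named
})

test_that("gray axis, monotonicity and scaling properties hold", {
  rowsum_white <- white_point(95.75, 100, 108.90)
  for (v in seq(10, 250, by = 30)) {
    lab <- xyz_to_lab(rgb_to_xyz(linearize_rgb(c(v, v, v))))
    expect_lt(abs(lab["a"]), 1.7)
    expect_lt(abs(lab["b"]), 1.0)
    lab0 <- xyz_to_lab(rgb_to_xyz(linearize_rgb(c(v, v, v))), rowsum_white)
    expect_equal(unname(lab0["a"]), 0, tolerance = 1e-9)
    expect_equal(unname(lab0["b"]), 0, tolerance = 1e-9)
  }
  # raising all channels never decreases L* or lightness
  base <- c(40, 90, 130)
  prev <- rgb_to_record(base)
  for (add in c(20, 50, 90, 120)) {
    cur <- rgb_to_record(pmin(base + add, 255))
    expect_gte(cur$L, prev$L)
    expect_gte(cur$lightness, prev$lightness)
    prev <- cur
  }
  # chroma homogeneous of degree 1, hue scale-invariant
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, -50, 50); b <- runif(1, -50, 50); s <- runif(1, 0.1, 5)
    expect_equal(hue_chroma(s * a, s * b)$chroma, s * hue_chroma(a, b)$chroma)
    expect_equal(hue_chroma(s * a, s * b)$hue, hue_chroma(a, b)$hue)
  }
})

test_that("record constructor enforces its invariants", {
  expect_error(colorimetric_record(120, 0, 0, 0, 0, 100), "L\\*")
  expect_error(colorimetric_record(50, 3, 4, 53.13, 6, 100), "chroma")
  expect_error(colorimetric_record(50, 3, 4, 200, 5, 100), "hue")
  expect_silent(colorimetric_record(50, 3, 4, (atan2(4, 3) * 180 / pi), 5, 100))
})
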