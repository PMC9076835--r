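test_that("baseline flattening removes a linear trend and is idempotent", {
  gc <- generate_force_curve(curve_spec(E = 5e9, noise_sd = 0,
                                        baseline_offset = 4e-8,
                                        baseline_slope = 2e-2))
  clean <- generate_force_curve(curve_spec(E = 5e9, noise_sd = 0,
                                           baseline_offset = 0,
                                           baseline_slope = 0))
  f1 <- flatten_baseline(gc$curve)
  ramp <- f1$segment != "pause"  # a constant-height hold has no baseline fit
  expect_equal(f1$force[ramp], clean$curve$force[ramp], tolerance = 1e-10)
  f2 <- flatten_baseline(f1)
  expect_equal(f2$force[ramp], f1$force[ramp], tolerance = 1e-10)
  # a pure line with no contact flattens to zero
  h <- seq(0, 2e-6, length.out = 200)
  line <- force_curve(c(h, rev(h)), 1e-8 + 3e-3 * c(h, rev(h)),
                      rep(c("extend1", "retract_final"), each = 200))
  fl <- flatten_baseline(line)
  expect_lt(max(abs(fl$force)), 1e-18)
})

test_that("contact-point estimation finds the crossing", {
  gc <- generate_force_curve(curve_spec(E = 5e9, contact = 1.1e-6,
                                        noise_sd = 0))
  z0 <- estimate_poc(flatten_baseline(gc$curve))
  spacing <- 2e-6 / 2000
  expect_lt(abs(z0 - 1.1e-6), spacing)
  # curve offset so the minimum force stays positive: no contact
  up <- gc$curve
  up$force <- up$force - min(up$force) + 1e-9
  expect_error(estimate_poc(up, segment = "extend1"), "no-contact")
  # constructed step curve: crossing at the step position
  h <- seq(0, 1e-6, length.out = 101)
  f <- ifelse(h >= h[61], 1e-6, -1e-12)
  step <- force_curve(c(h, rev(h)), c(f, rev(f)),
                      rep(c("extend1", "retract_final"), each = 101))
  expect_lt(abs(estimate_poc(step, segment = "extend1") - h[61]), h[2] - h[1])
})

test_that("tip-sample separation follows height minus deflection", {
  h <- seq(0, 1e-6, length.out = 50)
  cv <- force_curve(c(h, rev(h)), rep(0, 100),
                    rep(c("extend1", "retract_final"), each = 50),
                    spring_constant = 40)
  expect_equal(tip_sample_distance(cv)$separation, cv$height)
  cv$force <- rep(40 * 2e-9, 100)  # constant deflection of 2 nm
  expect_equal(tip_sample_distance(cv)$separation, cv$height - 2e-9)
  # linear contact: deflection c*(z - z0) compresses the contact branch
  k <- 40; cshare <- 0.3; z0 <- 4e-7
  defl <- pmax(h - z0, 0) * cshare
  cv2 <- force_curve(c(h, rev(h)), k * c(defl, rev(defl)),
                     rep(c("extend1", "retract_final"), each = 50),
                     spring_constant = k)
  sep <- tip_sample_distance(cv2)$separation[1:50]
  on <- h > z0
  expect_equal(sep[on] - z0, (1 - cshare) * (h[on] - z0), tolerance = 1e-12)
})

test_that("Sneddon fit recovers the generating modulus", {
  for (E in c(1e8, 5e8, 5e9, 5e10)) {
    ft <- fit_sneddon(generate_force_curve(curve_spec(E = E,
                                                      noise_sd = 0))$curve)
    expect_lt(abs(ft$E - E) / E, 1e-3)
    expect_lt(abs(ft$contact - 1e-6), 3e-9)
  }
})

test_that("fit is scale-consistent and tan(alpha) confounds with E", {
  gc <- generate_force_curve(curve_spec(E = 5e9, noise_sd = 0))
  f1 <- fit_sneddon(gc$curve)
  scaled <- gc$curve
  scaled$force <- 3 * scaled$force
  attr(scaled, "spring_constant") <- attr(gc$curve, "spring_constant") * 3
  f3 <- fit_sneddon(scaled)
  expect_equal(f3$E / f1$E, 3, tolerance = 1e-3)
  expect_lt(abs(f3$contact - f1$contact), 2e-9)
  # doubling tan(alpha): E * tan(alpha) is the identifiable product
  a2 <- atan(2 * tan(18 * pi / 180))
  f2 <- fit_sneddon(gc$curve, alpha = a2)
  expect_equal(f2$E, f1$E / 2, tolerance = 1e-6)
})

test_that("noisy fits stay within a few percent (seeded replicates)", {
  errs <- vapply(1:20, function(i) {
    ft <- fit_sneddon(generate_force_curve(
      curve_spec(E = 5e9, noise_sd = 0.02, seed = i))$curve)
    abs(ft$E - 5e9) / 5e9
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("adhesion filter partitions at the threshold", {
  specs <- c(100e-9, 200e-9, 150e-9, 161e-9, 159e-9, 40e-9)
  curves <- lapply(seq_along(specs), function(i)
    generate_force_curve(curve_spec(adhesion = specs[i], seed = i))$curve)
  out <- adhesion_filter(curves, threshold = 160e-9)
  brute <- sum(out$adhesion < 160e-9)
  expect_equal(length(out$retained), brute)
  expect_equal(length(out$retained) + length(out$rejected), length(curves))
  expect_equal(length(adhesion_filter(curves, threshold = 0)$retained), 0L)
  # recovered adhesion tracks the requested dip magnitude
  expect_equal(out$adhesion, specs, tolerance = 0.05)
})

test_that("per-region medians aggregate correctly", {
  mk <- function(E, region, sample = "s1")
    structure(list(E = E, region = region, sample = sample),
              class = "sneddon_fit")
  fits <- list(mk(1e9, "vasculature"), mk(2e9, "vasculature"),
               mk(9e9, "vasculature"), mk(4e9, "cortex"))
  med <- region_median_modulus(fits)
  expect_equal(med$median_E[med$region == "vasculature"], 2e9)
  expect_equal(med$median_E[med$region == "cortex"], 4e9)
  expect_equal(med$n[med$region == "vasculature"], 3)
  # sampling oracle: the sample median approaches the true median
  set.seed(2)
  fits2 <- lapply(rlnorm(31, log(5e9), 0.2), mk, region = "podium")
  med2 <- region_median_modulus(fits2)
  expect_lt(abs(med2$median_E / 5e9 - 1), 0.15)
})

test_that("force curves round-trip through the manifest reader", {
  dir <- tempfile(); dir.create(dir)
  gc <- generate_force_curve(curve_spec(E = 2e9, region = "side",
                                        sample = "s7"))
  write.csv(as.data.frame(gc$curve)[, c("height", "force", "segment")],
            file.path(dir, "c1.csv"), row.names = FALSE)
  write.csv(data.frame(file = "c1.csv", region = "side", sample = "s7",
                       spring_constant = 40, trigger_force = 3e-6),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  curves <- read_force_curves(file.path(dir, "manifest.csv"))
  expect_length(curves, 1L)
  ft <- fit_sneddon(curves[[1]])
  expect_equal(ft$E, 2e9, tolerance = 1e-3)
  expect_equal(ft$region, "side")
  unlink(dir, recursive = TRUE)
})
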