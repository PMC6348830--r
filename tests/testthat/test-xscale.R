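mouse_prof <- species_profile("mouse", 0.026,
                              organ_masses = c(kidneys = 4e-4, liver = 1.3e-3))
human_prof <- species_profile("human", 61,
                              organ_masses = c(kidneys = 0.31, liver = 1.8),
                              blood_volume_ml = 5300)

test_that("Method 1 passes values and units through unchanged", {
  t1 <- tiac_estimate(7.67, species = "pig", region = "kidneys")
  expect_equal(method1_same(t1)$value, 7.67)
  expect_equal(method1_same(tiac_estimate(0, region = "x"))$value, 0)
  tb <- tiac_estimate(2e-4, species = "pig", region = "blood",
                      unit = "h_per_ml")
  expect_identical(method1_same(tb)$unit, "h_per_ml")
})

test_that("Method 2 scales by the organ mass-fraction ratio", {
  # equal fractions -> unchanged
  a <- species_profile("a", 10, organ_masses = c(liver = 0.3))
  h <- species_profile("h", 70, organ_masses = c(liver = 2.1))
  t0 <- tiac_estimate(3.1, species = "a", region = "liver")
  expect_equal(method2_mass(t0, a, h)$value, 3.1)

  # human fraction double the animal fraction -> doubled
  h2 <- species_profile("h", 70, organ_masses = c(liver = 4.2))
  expect_equal(method2_mass(tiac_estimate(2, species = "a", region = "liver"),
                            a, h2)$value, 4.0)

  # direct arithmetic: 1.44 h, fractions 0.016 -> 0.0048 gives 0.432 h
  a3 <- species_profile("m", 1, organ_masses = c(kidneys = 0.016))
  h3 <- species_profile("h", 1, organ_masses = c(kidneys = 0.0048))
  t3 <- tiac_estimate(1.44, species = "m", region = "kidneys")
  expect_equal(method2_mass(t3, a3, h3)$value, 0.432, tolerance = 1e-12)
})

test_that("Method 2 refuses when masses or blood volume are missing", {
  bare <- species_profile("mouse", 0.026)
  t0 <- tiac_estimate(1.44, species = "mouse", region = "kidneys")
  expect_error(method2_mass(t0, bare, human_prof), "no organ mass")
  tb <- tiac_estimate(0.037, species = "mouse", region = "blood",
                      unit = "h_per_ml")
  expect_error(method2_mass(tb, mouse_prof, human_prof), "blood volume")
  # with a blood volume on both sides it works (volume as mass at 1 g/mL)
  mp <- species_profile("pig", 28, blood_volume_ml = 1850)
  tp <- tiac_estimate(2e-4, species = "pig", region = "blood",
                      unit = "h_per_ml")
  got <- method2_mass(tp, mp, human_prof)$value
  expect_equal(got, 2e-4 * (5.3 / 61) / (1.85 / 28), tolerance = 1e-12)
})

test_that("Method 3: identity at equal masses; exact c-factor when lambda_phys = 0", {
  m <- exp_model(c(10, 5), c(0.3, 0.01), 0)
  same <- method3_time(m, 28, 28)
  expect_equal(same$model$terms, m$terms)
  expect_equal(same$scaled$value, integrate_tiac(m)$value)

  single <- exp_model(40, 0.2, 0)
  out <- method3_time(single, 0.026, 61)
  cc <- (61 / 0.026)^0.25
  expect_equal(out$scaled$value, cc * 40 / 100 / 0.2, tolerance = 1e-12)
})

test_that("Method 3 with a decay floor lands strictly between TIAC and c*TIAC", {
  # term-wise bound: requires non-negative amplitudes (for an
  # uptake-washout pair only the upper bound c*TIAC is guaranteed)
  for (m in random_models(100, seed = 99, forms = c("mono", "bi"))) {
    t0 <- integrate_tiac(m)$value
    cc <- (61 / 28)^0.25
    ts <- method3_time(m, 28, 61)$scaled$value
    expect_gte(ts, t0 * (1 - 1e-12))
    expect_lte(ts, cc * t0 * (1 + 1e-12))
  }
})

test_that("Method 3 variants: physical-decay flag and invalid inputs", {
  m <- exp_model(c(10, 5), c(0.3, 0.01), lp177)
  naive <- method3_time(m, 0.026, 61, scaling_spec(scale_physical_decay = TRUE))
  cc <- (61 / 0.026)^0.25
  expect_equal(naive$scaled$value, cc * integrate_tiac(m)$value,
               tolerance = 1e-12)
  # default variant scales only the biological component
  def <- method3_time(m, 0.026, 61)
  expect_lt(def$scaled$value, naive$scaled$value)
  expect_equal(def$model$terms$lambda,
               lp177 + (m$terms$lambda - lp177) / cc, tolerance = 1e-12)

  bad <- m; bad$terms$lambda[1] <- lp177 / 2
  expect_error(method3_time(bad, 0.026, 61), "below lambda_phys")
  expect_error(method3_time(m, -1, 61), "positive")
})

test_that("Method 4 equals Method 3 composed with Method 2", {
  models <- random_models(100, seed = 123)
  regions <- rep(c("kidneys", "liver"), length.out = length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]; rg <- regions[i]
    m4 <- method4_combined(m, mouse_prof, human_prof, region = rg)
    m3 <- method3_time(m, mouse_prof, human_prof)
    t3 <- tiac_estimate(m3$scaled$value, species = "mouse", region = rg)
    m2 <- method2_mass(t3, mouse_prof, human_prof)
    expect_equal(m4$value, m2$value, tolerance = 1e-12)
  }
})

test_that("Method 5 applies the allometric mass-ratio power", {
  # b = 1 is the identity
  sp1 <- scaling_spec(allometric_b = c(liver = 1))
  t0 <- tiac_estimate(2.5, species = "pig", region = "liver")
  expect_equal(method5_allometric(t0, 28, 61, spec = sp1)$value, 2.5)

  # mass ratio 16 with b = 0.75: 16^(-0.25) = 1/2 exactly
  sp2 <- scaling_spec(allometric_b = c(liver = 0.75))
  expect_equal(method5_allometric(t0, 4, 64, spec = sp2)$value, 1.25)

  # mouse liver with the published TIAC: 0.75 h -> 0.40 h at 2 d.p.
  tm <- tiac_estimate(0.75, species = "mouse", region = "liver")
  expect_equal(round(method5_allometric(tm, 0.026, 61)$value, 2), 0.40)

  expect_error(method5_allometric(t0, 28, 61,
                                  spec = scaling_spec(allometric_b = c(kidneys = 0.85))),
               "no allometric exponent")
})

test_that("Methods 2 and 5 are linear in the TIAC; Method 3 is homogeneous", {
  t1 <- tiac_estimate(1.7, species = "mouse", region = "liver")
  t2 <- tiac_estimate(3.4, species = "mouse", region = "liver")
  expect_equal(2 * method2_mass(t1, mouse_prof, human_prof)$value,
               method2_mass(t2, mouse_prof, human_prof)$value)
  expect_equal(2 * method5_allometric(t1, mouse_prof, human_prof)$value,
               method5_allometric(t2, mouse_prof, human_prof)$value)
  m <- exp_model(c(4, 2), c(0.2, 0.01), lp177)
  m2x <- exp_model(2 * c(4, 2), c(0.2, 0.01), lp177)
  expect_equal(2 * method3_time(m, 0.026, 61)$scaled$value,
               method3_time(m2x, 0.026, 61)$scaled$value)
})

test_that("all methods reduce to Method 1 when animal equals human", {
  t0 <- tiac_estimate(4.2, species = "human", region = "liver")
  m <- exp_model(c(3, 1.5), c(0.25, 0.008), lp177)
  tm <- integrate_tiac(m)$value
  expect_equal(method2_mass(t0, human_prof, human_prof)$value, t0$value)
  expect_equal(method3_time(m, 61, 61)$scaled$value, tm)
  expect_equal(method4_combined(m, human_prof, human_prof,
                                region = "liver")$value, tm)
  expect_equal(method5_allometric(t0, 61, 61)$value, t0$value)
})

test_that("comparison report reproduces the headline factors", {
  ref <- list(tiac_estimate(5.85, region = "kidneys", species = "human"),
              tiac_estimate(5.32, region = "liver", species = "human"))
  scaled <- list(
    scaled_tiac(1, "mouse", "kidneys", 1.44),
    scaled_tiac(1, "mouse", "liver", 0.75),
    scaled_tiac(1, "pig", "kidneys", 7.67),
    scaled_tiac(1, "pig", "liver", 4.08)
  )
  rep <- compare_tiacs(scaled, ref)
  expect_equal(rep$factor_display, c(4, 7, 1.3, 1.3))
  expect_equal(rep$direction, c("under", "under", "over", "under"))

  # equality gives factor 1 and direction "equal"
  eq <- compare_tiacs(list(scaled_tiac(1, "pig", "kidneys", 5.85)), ref)
  expect_equal(eq$ratio, 1)
  expect_identical(eq$direction, "equal")

  expect_error(compare_tiacs(list(scaled_tiac(1, "pig", "spleen", 1)), ref),
               "no human reference")
})
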