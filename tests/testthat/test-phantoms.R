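test_that("single-annulus ground truth is analytic", {
  spec <- annulus_spec(outer = 275, lumen = 150, size = 600, noise = 0)
  ph <- render_phantom(spec)
  expect_equal(ph$truth$area_mm2, pi * 275^2 * 1e-6)
  expect_equal(ph$truth$diameter_um, 550)
  expect_equal(ph$truth$epithelial_height_um, 125)
  expect_true(ph$truth$has_lumen)
})

test_that("noise changes pixels but never the ground truth", {
  s1 <- annulus_spec(outer = 60, lumen = 30, size = 160, noise = 0.05,
                     seed = 1)
  s2 <- annulus_spec(outer = 60, lumen = 30, size = 160, noise = 0.05,
                     seed = 2)
  p1 <- render_phantom(s1); p2 <- render_phantom(s2)
  expect_identical(p1$truth, p2$truth)
  expect_false(identical(p1$image$pixels, p2$image$pixels))
  # same seed: bit-identical
  expect_identical(render_phantom(s1)$image$pixels, p1$image$pixels)
})

test_that("multi-tubule frame renders region sizes near analytic areas", {
  tub <- grid_tubules(8, size = c(512L, 512L), pixel_size = 1,
                      outer_um_range = c(50, 70), seed = 3)
  spec <- phantom_spec(size = c(512L, 512L), pixel_size = 1, tubules = tub,
                       noise_sd = 0, texture_amp = 0)
  ph <- render_phantom(spec)
  lum <- function(rgb) 0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3]
  gray <- 0.299 * ph$image$pixels[, , 1] + 0.587 * ph$image$pixels[, , 2] +
    0.114 * ph$image$pixels[, , 3]
  bg <- lum(spec$palette$interstitium)
  contrast <- abs(bg - lum(spec$palette$epithelium))
  # pixels that are majority tubule (darker than halfway to epithelium);
  # the pale lumen disc is fully enclosed, so only the annulus boundary counts
  for (i in seq_len(8)) {
    tb <- tub[i, ]
    r0 <- ceiling(tb$outer_um) + 3
    win <- gray[round(tb$center_r + 1) + (-r0:r0),
                round(tb$center_c + 1) + (-r0:r0)]
    epi_count <- sum(win < bg - 0.5 * contrast)
    lum_count <- sum(win > (lum(spec$palette$lumen) + bg) / 2)
    analytic <- pi * tb$outer_um^2       # outer disc = annulus + lumen
    expect_lt(abs((epi_count + lum_count) - analytic) / analytic, 0.02)
  }
})

test_that("invalid phantom specs are rejected", {
  base <- data.frame(center_r = c(100, 140), center_c = c(100, 120),
                     outer_um = c(60, 60), lumen_um = c(30, 30),
                     ellipticity = 0)
  expect_error(phantom_spec(size = c(300L, 300L), pixel_size = 1,
                            tubules = base), "overlap")
  one <- base[1, ]; one$lumen_um <- 70
  expect_error(phantom_spec(size = c(300L, 300L), pixel_size = 1,
                            tubules = one), "lumen")
  off <- base[1, ]; off$center_r <- 30
  expect_error(phantom_spec(size = c(300L, 300L), pixel_size = 1,
                            tubules = off), "outside")
})

test_that("study simulation is exact in the zero-noise limit", {
  d <- study_design(between_sd = c(area_mm2 = 0, diameter_um = 0,
                                   epithelial_height_um = 0),
                    within_sd = c(area_mm2 = 0, diameter_um = 0,
                                  epithelial_height_um = 0),
                    gross_sd = c(body_weight_kg = 0, testis_weight_g = 0,
                                 testis_length_cm = 0))
  sim <- simulate_study(d)
  for (g in d$groups) {
    sub <- sim$tubules[sim$tubules$group == g, ]
    expect_true(all(sub$epithelial_height_um ==
                      d$tubule_means[g, "epithelial_height_um"]))
    expect_true(all(sub$area_mm2 == d$tubule_means[g, "area_mm2"]))
  }
  expect_equal(nrow(sim$animals), 30L)  # 6 groups x 5 animals
})

test_that("simulation is deterministic and label-equivariant", {
  d1 <- study_design(seed = 11)
  expect_identical(simulate_study(d1), simulate_study(d1))
  # swapping two group labels permutes the rows accordingly
  g2 <- d1$groups; g2[c(1, 3)] <- g2[c(3, 1)]
  d2 <- study_design(groups = g2,
                     tubule_means = d1$tubule_means[g2, ],
                     gross_means = d1$gross_means[g2, ],
                     mean_tubule_counts = d1$mean_tubule_counts[g2],
                     seed = 11)
  s1 <- simulate_study(d1); s2 <- simulate_study(d2)
  m1 <- tapply(s1$tubules$diameter_um, s1$tubules$group, mean)
  m2 <- tapply(s2$tubules$diameter_um, s2$tubules$group, mean)
  expect_identical(sort(names(m1)), sort(names(m2)))
})

test_that("group sample means converge to the truth (law of large numbers)", {
  d <- study_design(groups = c("0h", "6h"), animals_per_group = 200L,
                    tubules_per_animal = 5L,
                    tubule_means = study_design()$tubule_means[1:2, ],
                    gross_means = study_design()$gross_means[1:2, ],
                    mean_tubule_counts = NA, seed = 21)
  sim <- simulate_study(d)
  for (g in d$groups) {
    sub <- sim$tubules[sim$tubules$group == g, ]
    z <- tapply(sub$epithelial_height_um, sub$animal_id, mean)
    se <- stats::sd(z) / sqrt(length(z))
    expect_lt(abs(mean(z) - d$tubule_means[g, "epithelial_height_um"]), 3 * se)
  }
})

test_that("sampled group means track the designed effect sizes", {
  # epithelial-height configuration at the study scale: SE of animal means
  # should come out near 12 um and sample means within 3 SE of truth
  d <- study_design(seed = 31)
  hits <- 0; ses <- c()
  for (rep in 1:40) {
    d$seed <- 31L + rep
    sim <- simulate_study(subset_design(d, c("0h", "6h", "18h", "30h", "42h")))
    tub <- sim$tubules
    for (g in unique(tub$group)) {
      z <- tapply(tub$epithelial_height_um[tub$group == g],
                  tub$animal_id[tub$group == g], mean)
      se <- stats::sd(z) / sqrt(length(z))
      ses <- c(ses, se)
      if (abs(mean(z) - d$tubule_means[g, "epithelial_height_um"]) <= 3 * se)
        hits <- hits + 1
    }
  }
  expect_gte(hits / 200, 0.95)
  expect_equal(mean(ses), 12, tolerance = 0.25)
})

test_that("phantom seeds land on the true boundary", {
  spec <- annulus_spec(outer = 80, lumen = 40, size = 220)
  s <- phantom_seeds(spec, 1, 16, "outer")
  dev <- abs(sqrt(rowSums(sweep(s, 2, c(110, 110))^2)) - 80)
  expect_lte(max(dev), 0.75)
  sl <- phantom_seeds(spec, 1, 12, "lumen")
  devl <- abs(sqrt(rowSums(sweep(sl, 2, c(110, 110))^2)) - 40)
  expect_lte(max(devl), 0.75)
})

test_that("pipeline recovers phantom ground truth end to end", {
  # trace + measure on three seeded annuli; see the acceptance suite for the
  # full 20-phantom sweep
  for (s in 1:3) {
    set.seed(500 + s)
    outer <- runif(1, 55, 100)
    spec <- annulus_spec(outer = outer, lumen = outer * runif(1, 0.4, 0.6),
                         size = 2 * ceiling(outer) + 100, noise = 0.03,
                         seed = 500 + s)
    ph <- render_phantom(spec)
    st <- compute_feature_stack(ph$image)
    ct <- trace_closed_contour(phantom_seeds(spec, 1, 16, "outer"), st)
    lm_ <- trace_closed_contour(phantom_seeds(spec, 1, 12, "lumen"), st)
    m <- measure_tubules(ct, lm_, 1, "t1")
    tr <- ph$truth
    expect_lt(abs(m$area_mm2 - tr$area_mm2) / tr$area_mm2, 0.02)
    expect_lt(abs(m$diameter_um - tr$diameter_um) / tr$diameter_um, 0.01)
    expect_lt(abs(m$epithelial_height_um - tr$epithelial_height_um) /
                tr$epithelial_height_um, 0.03)
  }
})
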