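# Synthetic template, cohort generator, and misregistration perturbations.

test_that("make_template builds the ellipsoid WM shell deterministically", {
  cfg <- sim_config(shape = c(32, 32, 32), outer_semiaxes = c(12, 11, 10),
                    inner_semiaxes = c(4, 3, 5))
  sp1 <- make_template(cfg)
  sp2 <- make_template(cfg)
  expect_identical(sp1$wm_mask, sp2$wm_mask)

  # membership oracle: exhaustive voxel scan
  ctr <- (c(32, 32, 32) + 1) / 2
  oracle <- array(0L, dim = c(32, 32, 32))
  for (i in 1:32) for (j in 1:32) for (k in 1:32) {
    qo <- ((i - ctr[1]) / 12)^2 + ((j - ctr[2]) / 11)^2 + ((k - ctr[3]) / 10)^2
    qi <- ((i - ctr[1]) / 4)^2 + ((j - ctr[2]) / 3)^2 + ((k - ctr[3]) / 5)^2
    oracle[i, j, k] <- as.integer(qo <= 1 && qi > 1)
  }
  expect_identical(sp1$wm_mask, oracle)

  # degenerate ventricle: solid ellipsoid
  solid <- make_template(sim_config(inner_semiaxes = c(0, 0, 0)))
  holed <- make_template(sim_config())
  expect_gt(sum(solid$wm_mask), sum(holed$wm_mask))
  expect_error(make_template(sim_config(outer_semiaxes = c(3, 3, 3),
                                        inner_semiaxes = c(4, 4, 4))),
               "inner ellipsoid")
})

test_that("simulate_cohort is seed-reproducible and respects invariants", {
  cfg <- sim_config(n_subjects = 30, seed = 77)
  sp <- make_template(cfg)
  ch1 <- simulate_cohort(sp, cfg)
  ch2 <- simulate_cohort(sp, cfg)
  expect_identical(ch1$masks, ch2$masks)
  expect_identical(ch1$subjects, ch2$subjects)
  ch3 <- simulate_cohort(sp, sim_config(n_subjects = 30, seed = 78))
  expect_false(identical(ch1$masks, ch3$masks))

  # EDSS on the half-point grid in [0, 10]; masks binary and inside WM
  e <- ch1$subjects$edss[!is.na(ch1$subjects$edss)]
  expect_true(all(e >= 0 & e <= 10))
  expect_true(all(abs(e * 2 - round(e * 2)) < 1e-12))
  for (m in ch1$masks) {
    expect_true(all(m %in% c(0L, 1L)))
    expect_true(all(m[sp$wm_mask == 0L] == 0L))
  }
})

test_that("lesions concentrate periventricularly when peak >> background", {
  cfg <- sim_config(n_subjects = 40, peak_rate = 5, background_rate = 0.05,
                    seed = 31)
  sp <- make_template(cfg)
  prev <- lesion_count_map(simulate_cohort(sp, cfg))
  q_in <- lesionmapr:::ellipsoid_q(sp$shape, cfg$inner_semiaxes)
  shell <- sp$wm_mask == 1L & q_in <= 2.25    # adjacent to the ventricle
  deep <- sp$wm_mask == 1L & q_in > 6
  expect_gt(mean(prev$counts[shell]), 2 * mean(prev$counts[deep]))
})

test_that("cohort marginals emulate the stated demographics", {
  cfg <- sim_config(seed = 19)   # n = 98, Table-like marginals
  ch <- simulate_cohort(make_template(cfg), cfg)
  s <- ch$subjects
  expect_identical(nrow(s), 98L)
  expect_identical(sum(is.na(s$edss)), 7L)
  expect_identical(sum(is.na(s$duration)), 3L)
  e <- s$edss[!is.na(s$edss)]
  expect_lt(abs(mean(e) - 3.9), 3 * 2.2 / sqrt(length(e)))
  expect_lt(abs(sd(e) - 2.2), 0.7)
  expect_lt(abs(mean(s$age) - 43.5), 3 * 12.5 / sqrt(98))
  expect_lt(abs(mean(s$duration, na.rm = TRUE) - 11.4), 3 * 9.2 / sqrt(95))
})

test_that("planted effect regions tie lesion status to the carrier draw", {
  cfg <- sim_config(n_subjects = 50, seed = 23,
                    effect = list(beta_lesion = 2, n_voxels = 20))
  sp <- make_template(cfg)
  ch <- simulate_cohort(sp, cfg)
  region <- attr(ch, "effect_voxels")
  carriers <- attr(ch, "carriers")
  expect_length(region, 20L)
  expect_true(all(sp$wm_mask[region] == 1L))
  for (i in seq_len(50)) {
    expect_identical(unique(ch$masks[[i]][region]), carriers[i])
  }
})

test_that("perturb_registration transforms masks as advertised", {
  cfg <- sim_config(n_subjects = 12, seed = 41)
  sp <- make_template(cfg)
  ch <- simulate_cohort(sp, cfg)

  ident <- perturb_registration(ch, "translate", c(0, 0, 0))
  expect_identical(ident$masks, ch$masks)

  dil <- perturb_registration(ch, "dilate", 2)
  for (i in seq_len(12)) {
    t0 <- sum(ch$masks[[i]])
    t1 <- sum(dil$masks[[i]])
    if (t0 > 0 && t0 < prod(sp$shape)) expect_gt(t1, t0)
    expect_true(all(dil$masks[[i]][ch$masks[[i]] == 1L] == 1L))
  }
  ero <- perturb_registration(ch, "erode", 1)
  for (i in seq_len(12)) {
    expect_lte(sum(ero$masks[[i]]), sum(ch$masks[[i]]))
  }

  # pushing lesions toward the ventricle raises mean GLSR (paired, same seed)
  shoved <- perturb_registration(ch, "translate", c(8, 0, 0))
  g0 <- mean(glsr_cohort(ch)$glsr, na.rm = TRUE)
  g1 <- mean(glsr_cohort(shoved)$glsr, na.rm = TRUE)
  expect_gt(g1, g0)
  expect_match(shoved$registration_label, "translate")

  # scaling up inflates TLV (volume-inflation failure mode)
  sc <- perturb_registration(ch, "scale", 1.5)
  expect_gt(mean(vapply(sc$masks, sum, integer(1))),
            mean(vapply(ch$masks, sum, integer(1))))

  expect_error(perturb_registration(ch, "translate", c(200, 0, 0)),
               "off-grid")
})
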