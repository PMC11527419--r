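test_that("masks have the stated geometry", {
  m <- make_mask(c(32, 32, 32), "ellipsoid")
  expect_true(any(m$data))
  # volume of the inscribed ellipsoid ~ pi/6 of the box
  expect_equal(sum(m$data) / 32^3, pi / 6, tolerance = 0.02)
  expect_true(all(make_mask(c(8, 8, 8), "box")$data))
  # connectivity: every in-mask voxel reachable from the center (flood fill)
  lab <- array(FALSE, dim(m$data)); lab[16, 16, 16] <- TRUE
  repeat {
    grown <- lab
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      grown <- grown | slgcss:::shift_array(lab, o, FALSE)
    grown <- grown & m$data
    if (identical(grown, lab)) break
    lab <- grown
  }
  expect_identical(lab, m$data)
})

test_that("cohort simulation is deterministic and respects its grid", {
  tr <- synthetic_truth(synth_region(c(0, 0, 0), role = "shared"))
  c1 <- simulate_contrast_maps(tr, n_subjects = 3, shape = c(16, 16, 16),
                               seed = 5)
  c2 <- simulate_contrast_maps(tr, n_subjects = 3, shape = c(16, 16, 16),
                               seed = 5)
  expect_identical(c1$vols$syllable[[2]]$data, c2$vols$syllable[[2]]$data)
  expect_identical(c1$participation, c2$participation)
  c3 <- simulate_contrast_maps(tr, n_subjects = 3, shape = c(16, 16, 16),
                               seed = 6)
  expect_false(identical(c1$vols$syllable[[1]]$data,
                         c3$vols$syllable[[1]]$data))
  check_common_grid(c(c1$vols$syllable, c1$vols$tone, list(c1$mask)))
  # a region planted outside the mask is refused
  far <- synthetic_truth(synth_region(c(60, 0, 0), role = "shared"))
  expect_error(simulate_contrast_maps(far, n_subjects = 3,
                                      shape = c(16, 16, 16)), "outside")
})

test_that("noise-only cohorts are calibrated: P(z > 2.326) ~ 0.01 in the
           interior", {
  co <- simulate_contrast_maps(synthetic_truth(), n_subjects = 10, seed = 8)
  # erode the mask so boundary attenuation does not bias the tally
  interior <- co$mask$data
  for (o in list(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                 c(0, 0, 3), c(0, 0, -3)))
    interior <- interior & slgcss:::shift_array(co$mask$data, o, FALSE)
  vals <- unlist(lapply(co$vols$syllable, function(v) v$data[interior]))
  p_hat <- mean(vals > 2.326)
  # smoothness correlates voxels: allow a generous multiple of the binomial SE
  expect_lt(abs(p_hat - 0.01), 0.004)
})

test_that("planted effects appear in the right task with the right
           amplitude", {
  regions <- rbind(synth_region(c(0, 0, 0), role = "taskA_only",
                                peak_effect_z = 4),
                   synth_region(c(-15, 0, 0), role = "taskB_only",
                                peak_effect_z = 3))
  tr <- synthetic_truth(regions, jitter_sd_vox = 0)
  co <- simulate_contrast_maps(tr, n_subjects = 20, seed = 9)
  ctr_a <- round(co$centers_vox[1, ])
  ctr_b <- round(co$centers_vox[2, ])
  at <- function(vols, c3) mean(vapply(vols, function(v)
    v$data[c3[1], c3[2], c3[3]], 0))
  expect_equal(at(co$vols$syllable, ctr_a), 4, tolerance = 0.8)
  expect_equal(at(co$vols$tone, ctr_a), 0, tolerance = 0.8)
  expect_equal(at(co$vols$tone, ctr_b), 3, tolerance = 0.8)
  # participation is an exact count
  tr2 <- synthetic_truth(synth_region(c(0, 0, 0), participation = 0.7))
  co2 <- simulate_contrast_maps(tr2, n_subjects = 27, seed = 10)
  expect_equal(sum(co2$participation[1, ]), round(0.7 * 27))
})

test_that("anticorrelated regions carry the target cross-task pattern
           correlation", {
  tr <- synthetic_truth(synth_region(c(0, 0, 0), radius_mm = 12,
                                     role = "anticorrelated_pattern",
                                     peak_effect_z = 3),
                        jitter_sd_vox = 0, anticorr_r = -0.5)
  co <- simulate_contrast_maps(tr, n_subjects = 20, seed = 11)
  vox <- slgcss:::ball_indices(co$centers_vox[1, ], 12, dim(co$mask$data),
                               co$mask$voxel_size)
  r <- vapply(1:20, function(s)
    cor(co$vols$syllable[[s]]$data[vox], co$vols$tone[[s]]$data[vox]), 0)
  # attenuation: patterns have SD 3 on unit noise -> r ~ -0.5 * 9/10
  expect_equal(mean(r), -0.5 * 9 / 10, tolerance = 0.06)
})

test_that("simulated responders compose with the behavioral scorer", {
  run <- assemble_run("syllable", seed = 12)
  tg <- assign_targets(seed = 12)
  perfect <- simulate_responses(run, list(p_hit = 1, p_fa = 0,
                                          rt_mean_ms = 400, rt_sd_ms = 50),
                                tg, seed = 13)
  sc <- score_behavior(perfect)
  pooled <- sc[is.na(sc$block_index), ]
  expect_true(all(pooled$aprime == 1))
  # p_hit == p_fa gives chance-level A-prime over many trials; a 450 ms
  # window keeps target windows clear of presses to neighbouring stimuli
  set.seed(14)
  chance_logs <- unlist(lapply(1:10, function(i)
    simulate_responses(assemble_run("syllable", seed = 100 + i),
                       list(p_hit = 0.3, p_fa = 0.3, rt_mean_ms = 300,
                            rt_sd_ms = 50),
                       tg, seed = 200 + i, window_ms = c(0, 450))),
    recursive = FALSE)
  cs <- score_behavior(chance_logs, c(0, 450))
  blk <- cs[!is.na(cs$block_index), ]
  expect_equal(mean(blk$aprime), 0.5, tolerance = 0.06)
  # a negative learning slope speeds structured responses across blocks
  fast <- unlist(lapply(1:20, function(i)
    simulate_responses(assemble_run("syllable", seed = 300 + i),
                       list(p_hit = 1, p_fa = 0, rt_mean_ms = 500,
                            rt_sd_ms = 20, learning_slope = -100),
                       tg, seed = 400 + i)), recursive = FALSE)
  fs <- score_behavior(fast)
  st <- fs[fs$condition == "structured" & !is.na(fs$block_index), ]
  b1 <- mean(st$mean_rt_ms[st$block_index == 1])
  b3 <- mean(st$mean_rt_ms[st$block_index == 3])
  expect_lt(b3, b1 - 100)
})

test_that("ground-truth recovery scoring uses peak hits and Dice", {
  tr <- synthetic_truth(synth_region(c(0, 0, 0), radius_mm = 10))
  co <- simulate_contrast_maps(tr, n_subjects = 3, seed = 15)
  support <- intersect(slgcss:::ball_indices(co$centers_vox[1, ], 10,
                                             dim(co$mask$data),
                                             co$mask$voxel_size),
                       which(co$mask$data))
  # parcel exactly equal to the region
  ps <- structure(list(labels = array(0L, dim(co$mask$data)),
                       parcels = data.frame(parcel_id = 1L,
                                            peak_index = support[1],
                                            peak_i = 1, peak_j = 1,
                                            peak_k = 1, peak_value = 1,
                                            n_voxels = length(support))),
                  class = "parcel_set")
  ps$labels[support] <- 1L
  rep1 <- ground_truth_report(co, ps)
  expect_true(rep1$hit)
  expect_equal(rep1$best_dice, 1)
  # half-overlapping equal-size parcel
  half <- length(support) %/% 2
  shift_vox <- setdiff(which(co$mask$data), support)[seq_len(half)]
  ps2 <- ps
  ps2$labels[] <- 0L
  ps2$labels[c(support[seq_len(half)], shift_vox)] <- 1L
  ps2$parcels$peak_index <- shift_vox[1]
  rep2 <- ground_truth_report(co, ps2)
  expect_false(rep2$hit)
  expect_equal(rep2$best_dice,
               2 * half / (length(support) + half + length(shift_vox)),
               tolerance = 1e-12)
  # no parcels at all
  ps0 <- structure(list(labels = array(0L, dim(co$mask$data)),
                        parcels = ps$parcels[0, ]), class = "parcel_set")
  rep0 <- ground_truth_report(co, ps0)
  expect_false(rep0$hit)
  expect_equal(rep0$best_dice, 0)
})
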