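# Imaginary coherence, z-connectivity, contralesional testing, tertiles.

sin_pair <- function(phase, fs = 200, dur = 60, f0 = 10) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  rbind(sin(2 * pi * f0 * t), sin(2 * pi * f0 * t - phase))
}

test_that("imaginary coherence hits its closed forms", {
  ic <- pairwise_imaginary_coherence(sin_pair(pi / 2), fs = 200)
  expect_gte(ic[1, 2], 0.95)  # |sin(pi/2)| = 1
  x <- sin_pair(pi / 2)[1, ]
  ic0 <- pairwise_imaginary_coherence(rbind(x, 2 * x), fs = 200)
  expect_lte(ic0[1, 2], 0.02)  # zero-lag real mixing has no imaginary part
})

test_that("IC matrix is symmetric, bounded, amplitude-invariant", {
  set.seed(5)
  x <- matrix(rnorm(6 * 4000), 6)
  ic <- pairwise_imaginary_coherence(x, fs = 100)
  expect_equal(ic, t(ic))
  expect_equal(diag(ic), rep(0, 6))
  expect_true(all(ic >= 0 & ic <= 1))
  ic_scaled <- pairwise_imaginary_coherence(x * c(1, 10, 0.1, 5, 2, 7),
                                            fs = 100)
  expect_equal(ic, ic_scaled, tolerance = 1e-10)
})

test_that("appending a zero-lag mixture leaves pairwise IC unchanged", {
  set.seed(6)
  vs <- generate_voxel_dataset(voxel_sim_spec(n_voxels_per_hemisphere = 8,
                                              duration = 30, seed = 6))
  x <- vs$series
  ic <- pairwise_imaginary_coherence(x, fs = vs$fs)
  mix <- 0.6 * x[1, ] + 0.4 * x[5, ]
  ic2 <- pairwise_imaginary_coherence(rbind(x, mix), fs = vs$fs)
  n <- nrow(x)
  expect_lte(max(abs(ic2[1:n, 1:n] - ic)), 0.02)
  # a pure rescaling of an existing voxel stays volume-conduction silent
  ic3 <- pairwise_imaginary_coherence(rbind(x, 2 * x[3, ]), fs = vs$fs)
  expect_lte(ic3[n + 1, 3], 0.02)
})

test_that("white-noise IC shrinks as segments accumulate", {
  mean_ic_at <- function(dur, seed) {
    set.seed(seed)
    x <- matrix(rnorm(2 * dur * 100), 2)
    mean(vapply(1:20, function(i) {
      set.seed(seed + i)
      x <- matrix(rnorm(2 * dur * 100), 2)
      pairwise_imaginary_coherence(x, fs = 100)[1, 2]
    }, numeric(1)))
  }
  short <- mean_ic_at(12, 100)   # ~23 segments
  long <- mean_ic_at(96, 200)    # ~191 segments
  expect_lt(long, short)
  expect_lt(long, 0.12)
})

test_that("z-connectivity standardises mean Fisher-transformed coupling", {
  ic <- matrix(0.3, 5, 5); diag(ic) <- 0
  expect_equal(voxel_connectivity_z(ic), rep(0, 5))
  ic2 <- ic
  ic2[2, ] <- ic2[, 2] <- 0.6; ic2[2, 2] <- 0
  z <- voxel_connectivity_z(ic2)
  expect_equal(which.max(z), 2)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(voxel_connectivity_z(matrix(0, 2, 2)), "3 voxels")
  ic3 <- ic; ic3[1, 2] <- ic3[2, 1] <- 1
  expect_warning(voxel_connectivity_z(ic3), "clipped")
})

test_that("contralesional test is calibrated and detects boosted coupling", {
  vs <- generate_voxel_dataset(voxel_sim_spec(n_voxels_per_hemisphere = 60,
                                              duration = 60,
                                              lesion_voxel_ids = 1:8,
                                              lesion_coupling_boost = 3,
                                              seed = 12))
  ic <- pairwise_imaginary_coherence(vs)
  ct <- contralesional_test(ic, vs$hemisphere, which(!vs$tumour_mask),
                            voxels = which(vs$tumour_mask))
  expect_true(all(ct$t_stat > 0))
  expect_gte(mean(ct$p_fdr < 0.05), 0.9)
})

test_that("identical index and contralateral profiles give t = 0, p = 1", {
  # all couplings equal -> A and B identical element-wise
  ic <- matrix(0.4, 6, 6); diag(ic) <- 0
  hemi <- rep(c("left", "right"), each = 3)
  ct <- contralesional_test(ic, hemi, seq_len(6), voxels = 1)
  expect_equal(ct$t_stat[1], 0, tolerance = 1e-10)
  expect_equal(ct$p_value[1], 1, tolerance = 1e-10)
  expect_error(contralesional_test(ic, hemi, integer(0)), "empty")
})

test_that("tertile classification splits floor(n/3) with deterministic ties", {
  z <- 1:9
  cls <- classify_tertiles(z, voxel_ids = paste0("v", 1:9))
  expect_equal(as.character(cls[1:3]), rep("LFC", 3))
  expect_equal(as.character(cls[7:9]), rep("HFC", 3))
  expect_equal(as.character(cls[4:6]), rep("intermediate", 3))

  # tie spanning the upper boundary: ids decide, exactly 3 HFC / 3 LFC
  z2 <- c(1, 2, 3, 5, 5, 5, 5, 5, 9, 10)
  cls2 <- classify_tertiles(z2, voxel_ids = 1:10)
  expect_equal(sum(cls2 == "HFC"), 3)
  expect_equal(sum(cls2 == "LFC"), 3)
  expect_equal(which(cls2 == "HFC"), c(8, 9, 10))  # highest id wins the tie
  expect_equal(which(cls2 == "LFC"), 1:3)

  expect_warning(cls3 <- classify_tertiles(rep(1, 5)), "constant")
  expect_true(all(cls3 == "intermediate"))
  expect_error(classify_tertiles(1:2), "3 voxels")
})

test_that("HFC counting inside the enhancing mask drives positivity", {
  cls <- factor(c("HFC", "LFC", "HFC", "intermediate", "HFC", "LFC"),
                levels = c("LFC", "intermediate", "HFC"))
  mask_none <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  out <- count_hfc_in_tumour(cls, mask_none)
  expect_equal(out$hfc_voxel_count, 0)
  expect_false(out$hfc_positive)
  mask_two <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  out2 <- count_hfc_in_tumour(cls, mask_two)
  expect_equal(out2$hfc_voxel_count, 2)
  expect_true(out2$hfc_positive)
  # full mask recovers the tertile invariant floor(n/3)
  cls10 <- classify_tertiles(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  out3 <- count_hfc_in_tumour(cls10, rep(TRUE, 10))
  expect_equal(out3$hfc_voxel_count, floor(10 / 3))
  expect_error(count_hfc_in_tumour(cls, rep(FALSE, 6)), "empty")
})
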