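test_that("resolving power requirement scales linearly with mass", {
  k <- sip_constants()
  sep <- mass_shift_d(k) - mass_shift_13c(k)
  expect_equal(required_resolving_power(182.0579), 182.0579 / sep)
  expect_equal(round(required_resolving_power(182.0579) / 100) * 100, 62300)
  expect_equal(required_resolving_power(0), 0)
  expect_equal(required_resolving_power(400) / required_resolving_power(200), 2)
})

test_that("isotopologue series matching assigns exact peaks to the right grid", {
  k <- sip_constants()
  base <- list(mz = 180, intensity = 100)
  peaks <- data.frame(mz = c(180, 180 + mass_shift_13c(k), 180 + mass_shift_d(k)),
                      intensity = c(100, 40, 35))
  s <- match_series(base, peaks, max_k = 3, tol_ppm = 2)
  expect_equal(nrow(s$members), 2)
  expect_setequal(paste(s$members$k13c, s$members$kd),
                  c("1 0", "0 1"))
  expect_equal(s$max_k13c, 1)
  expect_equal(s$max_kd, 1)
  # a peak midway between the two shifts matches neither window at 2 ppm
  s_mid <- match_series(base, data.frame(mz = c(180, 181.0049),
                                         intensity = c(100, 50)), 3, 2)
  expect_equal(nrow(s_mid$members), 0)
  # an empty series keeps zero max counts
  s_empty <- match_series(base, data.frame(mz = 180, intensity = 100), 3, 2)
  expect_equal(s_empty$max_k13c, 0)
  expect_equal(s_empty$max_kd, 0)
  expect_error(match_series(base, data.frame(mz = 250, intensity = 1), 3, 2),
               "missing-base")
})

test_that("ambiguous peaks are flagged and excluded from label counts", {
  k <- sip_constants()
  # at high mass and loose tolerance, a peak can sit within tol of two grid
  # points: (1,0) and (0,1) differ by 2.92 mDa = 4.9 ppm at 600 Da
  base <- list(mz = 600, intensity = 100)
  mid <- 600 + (mass_shift_13c(k) + mass_shift_d(k)) / 2
  s <- match_series(base, data.frame(mz = c(600, mid), intensity = c(100, 50)),
                    max_k = 2, tol_ppm = 5)
  expect_equal(nrow(s$members), 0)
  expect_equal(nrow(s$ambiguous), 1)
  expect_gte(s$ambiguous$n_candidates[1], 2)
})

test_that("matching is deterministic and permutation invariant", {
  k <- sip_constants()
  base <- list(mz = 250, intensity = 1000)
  mzs <- 250 + c(1, 2, 0) * mass_shift_13c(k) + c(0, 1, 3) * mass_shift_d(k)
  peaks <- data.frame(mz = c(250, mzs), intensity = c(1000, 300, 200, 150))
  s1 <- match_series(base, peaks, 12, 2)
  s2 <- match_series(base, peaks[c(3, 1, 4, 2), ], 12, 2)
  expect_identical(s1$members, s2$members)
  # common calibration offset below tol/2 does not change assignments
  peaks_off <- peaks
  peaks_off$mz <- peaks_off$mz * (1 + 0.9e-6) # +0.9 ppm, tol 2 ppm
  s3 <- match_series(list(mz = peaks_off$mz[1], intensity = 1000), peaks_off, 12, 2)
  expect_identical(s1$members[, c("k13c", "kd")], s3$members[, c("k13c", "kd")])
})

test_that("the CD3 rule fires exactly on deuterium counts divisible by three", {
  k <- sip_constants()
  mk <- function(kd, k13c = 0) {
    base <- list(mz = 200, intensity = 100)
    mzs <- c(200, 200 + k13c * mass_shift_13c(k) + kd * mass_shift_d(k))
    s <- match_series(base, data.frame(mz = mzs, intensity = c(100, 30)), 12, 2)
    assign_labels(s)
  }
  a3 <- mk(3)
  expect_true(a3$cd3_transfer)
  expect_equal(a3$n_cd3_groups, 1)
  a6 <- mk(6)
  expect_true(a6$cd3_transfer)
  expect_equal(a6$n_cd3_groups, 2)
  expect_false(mk(4)$cd3_transfer)
  expect_false(mk(5)$cd3_transfer)
  expect_equal(mk(4)$n_cd3_groups, 0)
  # an unlabeled feature (max_kd = 0) is not a CD3 transfer
  expect_false(mk(0, 0)$cd3_transfer)
  # intensity floor suppresses label flags
  base <- list(mz = 200, intensity = 100)
  s_low <- match_series(base, data.frame(
    mz = c(200, 200 + 3 * mass_shift_d(k)), intensity = c(100, 0.5)), 12, 2)
  a_low <- assign_labels(s_low, min_intensity_frac = 0.01)
  expect_false(a_low$labeled_d)
  expect_false(a_low$cd3_transfer)
})

test_that("label census counts species by flag, independent of order", {
  # constructed census: 18 D-labeled features of which 9 divisible by 3,
  # plus 5 13C-only and 7 unlabeled features
  kd_vals <- c(rep(c(3, 6, 9), 3), c(1, 2, 4, 5, 7, 8, 10, 11, 13))
  feats <- rbind(
    data.frame(feature_id = sprintf("d%02d", 1:18),
               base_mz = seq(150, 320, length.out = 18), k13c = 0, kd = kd_vals),
    data.frame(feature_id = sprintf("c%02d", 1:5),
               base_mz = seq(330, 370, length.out = 5), k13c = 1:5, kd = 0),
    data.frame(feature_id = sprintf("u%02d", 1:7),
               base_mz = seq(380, 440, length.out = 7), k13c = 0, kd = 0))
  g <- generate_peaklists(feats, ppm_noise = 0, seed = 1)
  res <- metab_label_table(g$peaks, max_k = 15, tol_ppm = 2)
  expect_equal(res$census$n_d_species, 18)
  expect_equal(res$census$n_13c_species, 5)
  expect_equal(res$census$n_divisible_by_3, 9)
  # order and chunking invariance
  perm <- res$assignments[sample(seq_along(res$assignments))]
  expect_equal(count_label_census(perm), res$census)
  split_counts <- lapply(split(seq_along(perm), rep(1:3, length.out = length(perm))),
                         function(i) count_label_census(perm[i]))
  expect_equal(Reduce(`+`, lapply(split_counts, unlist)), unlist(res$census))
  # a dual-labeled feature counts once in each census
  dual <- data.frame(feature_id = "dual", base_mz = 200, k13c = 2, kd = 3)
  gd <- generate_peaklists(dual, 0, 1)
  resd <- metab_label_table(gd$peaks)
  expect_equal(resd$census$n_13c_species, 1)
  expect_equal(resd$census$n_d_species, 1)
  expect_equal(resd$census$n_divisible_by_3, 1)
})

test_that("substrate consumption converts areas to percent consumed", {
  expect_equal(substrate_consumption(100, 100)$percent_consumed, 0)
  expect_equal(substrate_consumption(100, 25)$percent_consumed, 75)
  expect_equal(substrate_consumption(100, 0)$percent_consumed, 100)
  out <- substrate_consumption(100, 0.9, "veratric_acid")
  expect_lt(out$rel_conc, 0.01)
  expect_error(substrate_consumption(0, 10), "invalid baseline")
  expect_error(substrate_consumption(100, -1), ">= 0")
})

test_that("label counts are recovered from noisy peak lists at instrument accuracy", {
  set.seed(99)
  n <- 1000
  feats <- data.frame(feature_id = sprintf("f%04d", 1:n),
                      base_mz = runif(n, 100, 500),
                      k13c = sample(0:4, n, TRUE), kd = sample(0:6, n, TRUE))
  g <- generate_peaklists(feats, ppm_noise = 0.3, seed = 7)
  res <- metab_label_table(g$peaks, max_k = 12, tol_ppm = 2)
  tab <- res$table[match(feats$feature_id, res$table$feature_id), ]
  exact <- tab$max_k13c == feats$k13c & tab$max_kd == feats$kd
  expect_gte(mean(exact), 0.99)
  # and the masses involved are within the instrument regime the separation needs
  expect_true(all(required_resolving_power(feats$base_mz) < 2e5))
})
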