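test_that("heavy/light split rules partition fractions correctly", {
  b <- make_bottle(five_fraction_densities, list(t = rep(10, 5)))
  s <- split_heavy_light(b, split_rule("density_threshold", 1.715))
  expect_setequal(s$heavy_ids, c("4", "5"))
  expect_setequal(s$light_ids, c("1", "2", "3"))
  s2 <- split_heavy_light(b, split_rule("top_k", k = 2))
  expect_setequal(s2$heavy_ids, s$heavy_ids)
  # uniform density cannot be split
  bu <- make_bottle(rep(1.70, 5), list(t = rep(10, 5)))
  expect_error(split_heavy_light(bu), "degenerate")
  # threshold beyond the range puts everything on one side
  expect_error(split_heavy_light(b, split_rule("density_threshold", 1.80)),
               "degenerate")
})

test_that("taxon odds match brute-force 2x2 arithmetic", {
  b <- make_2x2_bottle(20, 80, 5, 95)
  s <- split_heavy_light(b, split_rule("density_threshold", 1.715))
  expect_equal(taxon_odds("focal", s, b, pseudocount = 0), (20 / 80) / (5 / 95))
  b_sym <- make_2x2_bottle(10, 10, 10, 10)
  s_sym <- split_heavy_light(b_sym, split_rule("density_threshold", 1.715))
  expect_equal(taxon_odds("focal", s_sym, b_sym, pseudocount = 0), 1)
  # Haldane-Anscombe correction on a zero cell
  bz <- make_2x2_bottle(0, 100, 10, 90)
  sz <- split_heavy_light(bz, split_rule("density_threshold", 1.715))
  expect_equal(taxon_odds("focal", sz, bz, pseudocount = 0.5),
               ((0.5) / (100.5)) / ((10.5) / (90.5)))
  expect_equal(taxon_odds("focal", sz, bz), # policy default kicks in
               ((0.5) / (100.5)) / ((10.5) / (90.5)))
  expect_error(taxon_odds("focal", sz, bz, pseudocount = 0), "division-domain")
  # policy leaves zero-free tables untouched
  expect_equal(taxon_odds("focal", s, b), (20 / 80) / (5 / 95))
})

test_that("odds-ratio symmetry: swapping heavy and light inverts the OR", {
  set.seed(11)
  for (i in 1:20) {
    cells <- sample(1:200, 4)
    b <- make_2x2_bottle(cells[1], cells[2], cells[3], cells[4])
    s <- split_heavy_light(b, split_rule("density_threshold", 1.715))
    or <- taxon_odds("focal", s, b, pseudocount = 0)
    b_sw <- make_2x2_bottle(cells[3], cells[4], cells[1], cells[2])
    s_sw <- split_heavy_light(b_sw, split_rule("density_threshold", 1.715))
    expect_equal(taxon_odds("focal", s_sw, b_sw, pseudocount = 0), 1 / or,
                 tolerance = 1e-12)
  }
})

test_that("RoOR composes labeled and control odds with the read filter", {
  lab <- make_2x2_bottle(20, 80, 5, 95)
  ctl <- make_2x2_bottle(10, 90, 10, 90)
  r <- roor("focal", lab, ctl, pseudocount = 0)
  expect_equal(r$roor, 4.75)
  expect_true(r$passes_read_filter)
  expect_true(r$called_labeled)
  # identical tables give RoOR 1, not called
  r1 <- roor("focal", lab, lab, pseudocount = 0)
  expect_equal(r1$roor, 1)
  expect_false(r1$called_labeled)
  # the strict per-pool filter rejects a 4-read control-heavy pool
  ctl4 <- make_2x2_bottle(4, 96, 10, 90)
  r4 <- roor("focal", lab, ctl4, filter_scope = "per_pool")
  expect_false(r4$passes_read_filter)
  expect_false(r4$called_labeled)
  # the pooled-side filter accepts it (20 + 4 heavy reads)
  r4s <- roor("focal", lab, ctl4, filter_scope = "per_side")
  expect_true(r4s$passes_read_filter)
  # per_side still rejects genuinely sparse taxa
  lab_sparse <- make_2x2_bottle(2, 98, 1, 99)
  ctl_sparse <- make_2x2_bottle(1, 99, 1, 99)
  expect_false(roor("focal", lab_sparse, ctl_sparse)$passes_read_filter)
})

test_that("RoOR is invariant to sequencing depth of either bottle", {
  lab <- make_2x2_bottle(120, 800, 100, 900)
  ctl <- make_2x2_bottle(110, 850, 105, 880)
  r <- roor("focal", lab, ctl, pseudocount = 0)
  lab10 <- lab; lab10$reads <- lab10$reads * 10
  ctl3 <- ctl; ctl3$reads <- ctl3$reads * 3
  r_scaled <- roor("focal", lab10, ctl3, pseudocount = 0)
  expect_equal(r_scaled$roor, r$roor, tolerance = 1e-12)
  # and under the pseudocount policy the perturbation stays tiny at counts >= 100
  r_pol <- roor("focal", lab10, ctl3)
  expect_equal(r_pol$roor, r$roor, tolerance = 1e-3)
})

test_that("consensus calls follow the 2/2 and 2/3 replicate rules", {
  expect_true(consensus_call(c(TRUE, TRUE), "duplicates"))
  expect_false(consensus_call(c(TRUE, FALSE), "duplicates"))
  expect_true(consensus_call(c(TRUE, TRUE, FALSE), "triplicates"))
  expect_false(consensus_call(c(TRUE, FALSE, FALSE), "triplicates"))
  expect_error(consensus_call(c(TRUE, TRUE), "triplicates"), "design mismatch")
  expect_error(consensus_call(rep(TRUE, 3), "duplicates"), "design mismatch")
})

test_that("labeled community table folds rare taxa into 'other'", {
  counts <- c(A = 50, B = 30, C = 20)
  tab <- labeled_community_table(c("A", "B", "C"), counts)
  expect_equal(tab$rel_abundance[match(c("A", "B", "C"), tab$taxon)],
               c(0.5, 0.3, 0.2))
  expect_equal(sum(tab$rel_abundance), 1)
  # single labeled taxon
  tab1 <- labeled_community_table("A", counts)
  expect_equal(tab1$rel_abundance, 1)
  # 0.8% taxon at a 1% threshold goes to "other"
  counts2 <- c(A = 992, B = 8)
  tab2 <- labeled_community_table(c("A", "B"), counts2, 0.01)
  expect_true("other" %in% tab2$taxon)
  expect_false("B" %in% tab2$taxon)
  expect_equal(sum(tab2$rel_abundance), 1)
  expect_warning(labeled_community_table(character(0), counts), "no labeled taxa")
})

test_that("a fully labeled low-abundance taxon is recovered from gradients", {
  spec <- labeled_taxon_spec()
  hits <- 0; fps <- numeric(0)
  for (s in 1:50) {
    g <- generate_gradient(spec, s)
    rt <- roor_table(g$labeled, g$control)
    ct <- consensus_table(rt, "duplicates")
    hits <- hits + ct$consensus[ct$taxon == "labeled_taxon"]
    fps <- c(fps, ct$consensus[ct$taxon != "labeled_taxon"])
  }
  expect_gte(hits / 50, 0.9)   # sensitivity
  expect_lte(mean(fps), 0.1)   # false positives among unlabeled taxa
})

test_that("null communities have RoOR distributions centred on 1", {
  spec <- community_spec(null_community(20), n_labeled_replicates = 2)
  meds <- vapply(1:50, function(s) {
    g <- generate_gradient(spec, s)
    rt <- roor_table(g$labeled, g$control)
    stats::median(rt$roor)
  }, numeric(1))
  expect_true(all(meds >= 0.8 & meds <= 1.25))
})

test_that("gradient tables round-trip through the TSV reader", {
  spec <- labeled_taxon_spec()
  g <- generate_gradient(spec, 1)
  path <- tempfile(fileext = ".tsv")
  dualsip:::write_provenance_table(g$long_table, path,
                                   list(rule = "density_threshold(1.715)"))
  back <- read_gradient_tsv(path)
  expect_equal(nrow(back), nrow(g$long_table))
  expect_equal(sum(back$reads), sum(g$long_table$reads))
  expect_true(any(grepl("density_threshold", attr(back, "provenance"))))
  bottles <- dualsip:::split_bottles(back)
  expect_setequal(names(bottles), c("L1", "L2", "C"))
})
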