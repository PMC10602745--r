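# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk.

# Build a one-bottle long gradient table from per-taxon read vectors
# (one element per fraction).
make_bottle <- function(densities, counts_by_taxon) {
  taxa <- names(counts_by_taxon)
  do.call(rbind, lapply(seq_along(densities), function(f)
    data.frame(fraction_id = f, density_g_ml = densities[f], taxon = taxa,
               reads = vapply(counts_by_taxon, `[`, numeric(1), f),
               stringsAsFactors = FALSE)))
}

# Two-fraction bottle realizing an exact 2x2 table: taxon has a heavy /
# c light reads, the rest of the community b heavy / d light.
make_2x2_bottle <- function(a, b, c, d) {
  make_bottle(c(1.70, 1.73), list(focal = c(c, a), rest = c(d, b)))
}

five_fraction_densities <- c(1.69, 1.70, 1.71, 1.72, 1.73)

# Community with one fully labeled low-abundance taxon over a background of
# unlabeled taxa of graded abundance (the detection-scenario fixture).
labeled_taxon_spec <- function(abundance = 0.05, read_depth = 2000,
                               n_replicates = 2) {
  bg <- null_community(9, decay = 0.8)
  bg$abundance <- bg$abundance * (1 - abundance)
  bg$name <- sprintf("bg_%d", seq_len(nrow(bg)))
  taxa <- rbind(data.frame(name = "labeled_taxon", abundance = abundance,
                           gc = 0.50, label_af = 1, stringsAsFactors = FALSE),
                bg)
  community_spec(taxa, read_depth = read_depth,
                 n_labeled_replicates = n_replicates)
}

het_producer <- list(list(name = "het", profile = c("18:1w7" = 0.7, "a15:0" = 0.3),
                          growth = 40, trophic_mode = "heterotroph"))
aut_producer <- list(list(name = "aut", profile = c("16:0" = 1),
                          growth = 12, trophic_mode = "autotroph"))
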