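#' Community specification for gradient simulation
#'
#' Describes the community and gradient design emulated by
#' [generate_gradient()]: taxa with relative abundances, GC contents and a
#' per-taxon heavy-label atom fraction, plus the fraction grid and read
#' depth. Defaults mirror a typical CsCl DNA-SIP run: 12 collected fractions
#' spanning 1.690-1.768 g/mL, buoyant density
#' `rho = 1.66 + 0.098 * GC` g/mL, a full-labeling density shift of
#' 0.036 g/mL, and within-taxon density dispersion `sigma_rho = 0.006`.
#'
#' @param taxa Data.frame with columns `name`, `abundance` (summing to 1),
#'   `gc` (fraction), `label_af` (0-1 heavy-label atom fraction; this is a
#'   single composite density-shift parameter, since DNA-SIP cannot tell
#'   13C from D labeling).
#' @param read_depth Reads per bottle (multinomial total).
#' @param n_fractions Number of gradient fractions (default 12).
#' @param density_range Range of the fraction density grid, g/mL.
#' @param sigma_rho Density dispersion of one taxon's DNA across fractions.
#' @param shift_full Density shift at full labeling, g/mL.
#' @param rho_intercept,rho_gc_slope Buoyant-density model coefficients.
#' @param n_labeled_replicates Number of labeled bottles (1 control always).
#' @param overdispersion Optional Dirichlet-multinomial precision; `NULL`
#'   (default) draws plain multinomial reads, smaller values = noisier.
#' @param treatment,well Labels carried into generated tables.
#' @return A `community_spec` list.
#' @export
community_spec <- function(taxa, read_depth = 2000, n_fractions = 12,
                           density_range = c(1.690, 1.768),
                           sigma_rho = 0.006, shift_full = 0.036,
                           rho_intercept = 1.66, rho_gc_slope = 0.098,
                           n_labeled_replicates = 2, overdispersion = NULL,
                           treatment = "13C-VA", well = NA_character_) {
  need <- c("name", "abundance", "gc", "label_af")
  miss <- setdiff(need, names(taxa))
  if (length(miss))
    stop("taxa table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (abs(sum(taxa$abundance) - 1) > 1e-8)
    stop("taxon abundances must sum to 1", call. = FALSE)
  if (any(taxa$label_af < 0 | taxa$label_af > 1))
    stop("label_af must lie in [0, 1]", call. = FALSE)
  if (n_fractions < 2) stop("need at least 2 fractions", call. = FALSE)
  if (diff(range(density_range)) <= 0)
    stop("degenerate density grid", call. = FALSE)
  structure(list(taxa = taxa, read_depth = read_depth,
                 n_fractions = as.integer(n_fractions),
                 density_range = density_range, sigma_rho = sigma_rho,
                 shift_full = shift_full, rho_intercept = rho_intercept,
                 rho_gc_slope = rho_gc_slope,
                 n_labeled_replicates = as.integer(n_labeled_replicates),
                 overdispersion = overdispersion,
                 treatment = treatment, well = well),
            class = "community_spec")
}

.gen_bottle <- function(spec, labeled, bottle_id, replicate_role, replicate) {
  dens <- seq(spec$density_range[1], spec$density_range[2],
              length.out = spec$n_fractions)
  af <- if (labeled) spec$taxa$label_af else 0
  rho <- spec$rho_intercept + spec$rho_gc_slope * spec$taxa$gc +
    spec$shift_full * af
  w <- outer(seq_len(nrow(spec$taxa)), seq_along(dens),
             function(i, j) spec$taxa$abundance[i] *
               stats::dnorm(dens[j], rho[i], spec$sigma_rho))
  p <- as.vector(w / sum(w))
  if (!is.null(spec$overdispersion)) {
    g <- stats::rgamma(length(p), shape = p * spec$overdispersion)
    p <- if (sum(g) > 0) g / sum(g) else p
  }
  counts <- matrix(stats::rmultinom(1, spec$read_depth, p),
                   nrow = nrow(spec$taxa))
  dna <- colSums(w / sum(w)) * 250 # ng, arbitrary total per gradient
  data.frame(bottle_id = bottle_id, treatment = spec$treatment,
             replicate_role = replicate_role, replicate = replicate,
             fraction_id = rep(seq_along(dens), each = nrow(spec$taxa)),
             density_g_ml = rep(dens, each = nrow(spec$taxa)),
             dna_ng = round(rep(dna, each = nrow(spec$taxa)), 4),
             taxon = rep(spec$taxa$name, times = length(dens)),
             reads = as.vector(counts), stringsAsFactors = FALSE)
}

#' Simulate DNA-SIP density gradients with known labeling truth
#'
#' Draws per-fraction, per-taxon read counts for `n_labeled_replicates`
#' labeled bottles plus one control bottle. Each taxon's DNA is spread over
#' the fraction grid as a Gaussian centred on its buoyant density
#' (`rho_intercept + rho_gc_slope * GC`, shifted by
#' `shift_full * label_af` in labeled bottles only); reads are drawn
#' multinomially at the configured depth. Output is byte-reproducible from
#' `(spec, seed)` and the caller's RNG state is left untouched.
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed.
#' @return List with `labeled` (list of long bottle tables), `control`
#'   (one long table), `long_table` (all bottles row-bound, the on-disk
#'   schema), and `truth` (taxa with `label_af`, model constants, seed).
#' @export
generate_gradient <- function(spec, seed) {
  stopifnot(inherits(spec, "community_spec"))
  with_rng_seed(seed, {
    labeled <- lapply(seq_len(spec$n_labeled_replicates), function(i)
      .gen_bottle(spec, TRUE, sprintf("L%d", i), "labeled", i))
    control <- .gen_bottle(spec, FALSE, "C", "control", 1L)
    truth <- list(stage = "dna", taxa = spec$taxa,
                  labeled_taxa = spec$taxa$name[spec$taxa$label_af > 0],
                  rho_unlabeled = spec$rho_intercept +
                    spec$rho_gc_slope * spec$taxa$gc,
                  shift = spec$shift_full * spec$taxa$label_af,
                  sigma_rho = spec$sigma_rho, read_depth = spec$read_depth,
                  seed = seed)
    list(labeled = labeled, control = control,
         long_table = rbind(do.call(rbind, labeled), control),
         truth = truth)
  })
}

.phi_from_mode <- function(mode) {
  if (is.numeric(mode)) {
    if (mode < 0 || mode > 1) stop("phi must lie in [0, 1]", call. = FALSE)
    return(mode)
  }
  switch(mode, heterotroph = 0, autotroph = 1, acetogen = 0.5,
         stop("unknown trophic_mode '", mode,
              "' (use heterotroph/autotroph/acetogen or a numeric phi)",
              call. = FALSE))
}

#' Simulate dual-label PLFA measurement tables
#'
#' Builds T0/Tend concentration and isotope tables for a set of lipid
#' producers, inverting the incorporation-rate model so that at zero noise
#' [incorporation_rate()] recovers the configured rates exactly. Each
#' producer contributes carbon to its lipid profile at `growth` pmol C/L/day;
#' a fraction `phi` of that new carbon comes from the 13C-labeled DIC pool
#' (`phi` = 0 heterotroph, 1 autotroph, 0.5 acetogen), while deuterium from
#' the labeled substrate enters in proportion to total production
#' (`d_uptake`, default 1) — this is what lets the D rate track total lipid
#' production across trophic modes. Gaussian noise of sd `noise_sd_delta`
#' permil is added to every delta measurement.
#'
#' @param producers List of producers; each a list with `name`, `profile`
#'   (named weights over PLFA names), `growth` (pmol C/L/day), and
#'   `trophic_mode` (`"heterotroph"`, `"autotroph"`, `"acetogen"` or a
#'   numeric `phi`), optionally `d_uptake`.
#' @param pools List with source-pool label strengths `f13c_dic` and
#'   `fd_substrate` (atom fractions); see [sip_pools()].
#' @param duration Incubation length in days.
#' @param noise_sd_delta Measurement noise sd on deltas, permil.
#' @param seed Integer seed.
#' @param t0_conc Named T0 concentrations (pmol/L) per lipid; lipids missing
#'   from it start at 100 pmol/L.
#' @param baseline_delta13c,baseline_deltad Unlabeled isotope baselines,
#'   permil.
#' @param consts A [sip_constants()] object.
#' @return List with `measurements` (long table in the [plfa_rate_table()]
#'   schema) and `truth` (per-lipid true rates, phi, carbon produced).
#' @export
generate_plfa <- function(producers, pools = sip_pools(), duration = 84,
                          noise_sd_delta = 2, seed = 1,
                          t0_conc = NULL, baseline_delta13c = -30,
                          baseline_deltad = -150, consts = sip_constants()) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  lipids <- sort(unique(unlist(lapply(producers, function(p) names(p$profile)))))
  with_rng_seed(seed, {
    rows <- list(); truth <- list()
    for (lip in lipids) {
      nm <- parse_plfa_name(lip)
      alloc <- vapply(producers, function(p) {
        w <- p$profile[lip]
        if (is.na(w)) 0 else p$growth * w / sum(p$profile)
      }, numeric(1))
      phi <- vapply(producers, function(p) .phi_from_mode(p$trophic_mode), numeric(1))
      dup <- vapply(producers, function(p) p$d_uptake %||% 1, numeric(1))
      c_prod <- sum(alloc) * duration
      phi_eff <- if (sum(alloc) > 0) sum(alloc * phi) / sum(alloc) else 0
      d_eff <- if (sum(alloc) > 0) sum(alloc * dup) / sum(alloc) else 0
      r13_true <- phi_eff * pools$f13c_dic * c_prod / duration
      rd_true <- d_eff * pools$fd_substrate * c_prod / duration
      df_c <- if (c_prod > 0) r13_true * duration / c_prod else 0
      df_d <- if (c_prod > 0) rd_true * duration / c_prod else 0
      f0c <- delta_to_atom_fraction(delta_value(baseline_delta13c, "C"), consts)
      f0d <- delta_to_atom_fraction(delta_value(baseline_deltad, "H"), consts)
      d13_end <- .atom_fraction_to_delta(f0c + df_c, "C", consts)$value
      dd_end <- .atom_fraction_to_delta(f0d + df_d, "H", consts)$value
      conc0 <- if (!is.null(t0_conc) && lip %in% names(t0_conc))
        t0_conc[[lip]] else 100
      conc1 <- conc0 + c_prod / nm$n_carbons
      noise <- stats::rnorm(4, 0, noise_sd_delta)
      rows[[lip]] <- data.frame(
        timepoint = c("T0", "Tend"), plfa_name = lip,
        conc_pmol_per_l = c(conc0, conc1),
        delta13c_permil = c(baseline_delta13c + noise[1], d13_end + noise[2]),
        deltad_permil = c(baseline_deltad + noise[3], dd_end + noise[4]),
        stringsAsFactors = FALSE)
      truth[[lip]] <- data.frame(
        plfa_name = lip, c_produced = c_prod, phi = phi_eff,
        rate_13c_true = r13_true, rate_d_true = rd_true,
        delta_f_13c_true = df_c, delta_f_d_true = df_d,
        stringsAsFactors = FALSE)
    }
    meas <- do.call(rbind, rows)
    rownames(meas) <- NULL
    tr <- do.call(rbind, truth)
    rownames(tr) <- NULL
    list(measurements = meas,
         truth = list(stage = "plfa", lipids = tr, pools = pools,
                      duration = duration, noise_sd_delta = noise_sd_delta,
                      seed = seed))
  })
}

#' Source-pool label strengths for dual-SIP rate normalization
#'
#' `dic_label_fraction()` computes the 13C atom fraction of the dissolved
#' inorganic carbon pool after spiking labeled bicarbonate into groundwater:
#' 500 mg of 99 atom% NaH13CO3 into 1 L containing 4.5 mmol ambient DIC
#' (a typical carbonate-aquifer value) gives ~0.57. `sip_pools()` bundles it
#' with the deuterium fraction of the substrate's labile hydrogen: veratric
#' acid carries 10 H of which the two trideuterated methoxy groups
#' contribute 6, hence 0.6.
#'
#' @param mg_bicarbonate Labeled NaHCO3 added, mg.
#' @param atom_percent_13c Isotopic purity of the spike, atom %.
#' @param volume_l Incubation volume, L.
#' @param ambient_dic_mmol_l Ambient DIC concentration, mmol/L.
#' @param consts A [sip_constants()] used for the natural 13C abundance.
#' @return Atom fraction (numeric).
#' @export
dic_label_fraction <- function(mg_bicarbonate = 500, atom_percent_13c = 99,
                               volume_l = 1, ambient_dic_mmol_l = 4.5,
                               consts = sip_constants()) {
  spike_mmol <- mg_bicarbonate / 84.007 # NaHCO3 molar mass
  ambient_mmol <- ambient_dic_mmol_l * volume_l
  f_nat <- ratio_to_atom_fraction(consts$r_vpdb_13c)
  (spike_mmol * atom_percent_13c / 100 + ambient_mmol * f_nat) /
    (spike_mmol + ambient_mmol)
}

#' @rdname dic_label_fraction
#' @param f13c_dic,fd_substrate Override either pool directly.
#' @export
sip_pools <- function(f13c_dic = dic_label_fraction(), fd_substrate = 0.6) {
  if (f13c_dic <= 0 || f13c_dic > 1 || fd_substrate <= 0 || fd_substrate > 1)
    stop("pool atom fractions must lie in (0, 1]", call. = FALSE)
  list(f13c_dic = f13c_dic, fd_substrate = fd_substrate)
}

#' Simulate centroided peak lists with known isotopologue truth
#'
#' For each feature, emits the monoisotopic base peak plus isotopologue
#' peaks at the configured label counts: `(k13c, 0)` when `k13c > 0`,
#' `(0, kd)` when `kd > 0`, and the combined `(k13c, kd)` peak when both are
#' positive, at fixed intensity fractions of the base peak (0.4, 0.35,
#' 0.15). Every m/z receives multiplicative Gaussian jitter of sd
#' `ppm_noise` ppm (default 0.3 ppm, routine lock-mass orbitrap accuracy).
#'
#' @param features Data.frame with columns `feature_id`, `base_mz`, `k13c`,
#'   `kd`, and optionally `base_intensity` (default 1e6).
#' @param ppm_noise m/z jitter sd in ppm (>= 0).
#' @param seed Integer seed.
#' @param consts A [sip_constants()] object.
#' @return List with `peaks` (data.frame `feature_id`, `mz`, `intensity`)
#'   and `truth` (the feature table plus parameters).
#' @export
generate_peaklists <- function(features, ppm_noise = 0.3, seed = 1,
                               consts = sip_constants()) {
  need <- c("feature_id", "base_mz", "k13c", "kd")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (ppm_noise < 0) stop("ppm_noise must be >= 0", call. = FALSE)
  if (!"base_intensity" %in% names(features)) features$base_intensity <- 1e6
  dm_c <- mass_shift_13c(consts)
  dm_d <- mass_shift_d(consts)
  with_rng_seed(seed, {
    rows <- lapply(seq_len(nrow(features)), function(i) {
      f <- features[i, ]
      mz <- f$base_mz
      int <- f$base_intensity
      out <- data.frame(mz = mz, intensity = int)
      if (f$k13c > 0)
        out <- rbind(out, data.frame(mz = mz + f$k13c * dm_c, intensity = 0.40 * int))
      if (f$kd > 0)
        out <- rbind(out, data.frame(mz = mz + f$kd * dm_d, intensity = 0.35 * int))
      if (f$k13c > 0 && f$kd > 0)
        out <- rbind(out, data.frame(mz = mz + f$k13c * dm_c + f$kd * dm_d,
                                     intensity = 0.15 * int))
      out$mz <- out$mz * (1 + stats::rnorm(nrow(out), 0, ppm_noise * 1e-6))
      out$feature_id <- f$feature_id
      out[, c("feature_id", "mz", "intensity")]
    })
    peaks <- do.call(rbind, rows)
    rownames(peaks) <- NULL
    list(peaks = peaks,
         truth = list(stage = "metab", features = features,
                      ppm_noise = ppm_noise, seed = seed))
  })
}

#' A deterministic background community for null simulations
#'
#' Geometric rank-abundance community (abundance proportional to
#' `decay^rank`) with GC contents scattered over `gc_range`, all taxa
#' unlabeled. Used as the exchangeable-null fixture for false-positive
#' characterization of the RoOR rule.
#'
#' @param n_taxa Number of taxa.
#' @param decay Geometric decay of the rank-abundance curve.
#' @param gc_range Range of GC contents.
#' @return Taxa data.frame suitable for [community_spec()].
#' @export
null_community <- function(n_taxa = 40, decay = 0.85, gc_range = c(0.35, 0.65)) {
  ab <- decay^(seq_len(n_taxa) - 1)
  # deterministic low-discrepancy GC scatter, unrelated to abundance rank
  gc <- gc_range[1] + diff(gc_range) * (((seq_len(n_taxa) - 1) * 7) %% n_taxa) / (n_taxa - 1)
  data.frame(name = sprintf("taxon_%02d", seq_len(n_taxa)),
             abundance = ab / sum(ab), gc = pmin(gc, gc_range[2]),
             label_af = 0, stringsAsFactors = FALSE)
}

#' Scenario presets for the four incubation designs
#'
#' Ready-made synthetic study designs named after the sampled wells:
#' `"h41-va"` (13C-veratric acid, duplicate bottles, 12 weeks),
#' `"h43-dual"` (13CO2 + D-VA, triplicates, 12 weeks, acetogen-dominated),
#' `"h51-dual"` (13CO2 + D-VA, triplicates, 5 weeks) and `"h52-co2"`
#' (13CO2, duplicates, 5 weeks). Taxon and lipid names follow the organisms
#' each design is meant to evoke; all abundances, growth rates and label
#' assignments are invented fixture values with recorded ground truth, not
#' measurements.
#'
#' @param name Scenario name.
#' @return List with `well`, `treatment`, `design`, `duration_days`,
#'   `community` (a [community_spec()]), `producers` (for
#'   [generate_plfa()]), `features` (for [generate_peaklists()]) and
#'   `pools`.
#' @export
sip_scenario <- function(name = c("h41-va", "h43-dual", "h51-dual", "h52-co2")) {
  name <- match.arg(name)
  mk_taxa <- function(names, ab, gc, af)
    data.frame(name = names, abundance = ab / sum(ab), gc = gc,
               label_af = af, stringsAsFactors = FALSE)
  va_features <- function(prefix, specs)
    data.frame(feature_id = sprintf("%s_f%02d", prefix, seq_len(nrow(specs))),
               base_mz = specs$mz, k13c = specs$k13c, kd = specs$kd,
               stringsAsFactors = FALSE)
  switch(name,
    "h41-va" = {
      taxa <- mk_taxa(
        c("Hyphomicrobium", "Sphingobium", "Pseudomonas", "Nitrospira",
          "Caulobacteraceae", "Chloroflexi", "Sediminibacterium", "Nevskia"),
        ab = c(8, 6, 6, 25, 20, 18, 10, 7) / 100,
        gc = c(0.62, 0.63, 0.61, 0.56, 0.64, 0.55, 0.38, 0.60),
        af = c(1, 1, 0.8, 0, 0, 0, 0, 0))
      producers <- list(
        list(name = "Hyphomicrobium", profile = c("18:1w7" = 0.75, "16:0" = 0.15,
                                                  "18:0" = 0.10),
             growth = 40, trophic_mode = "heterotroph"),
        list(name = "Microbacteriaceae", profile = c("a15:0" = 0.5, "a17:0" = 0.5),
             growth = 15, trophic_mode = "heterotroph"))
      feats <- va_features("h41", data.frame(
        mz = c(182.0579, 168.0423, 154.0266, 196.0372, 212.0321,
               240.0634, 198.0528, 226.0841),
        k13c = c(9, 0, 0, 2, 0, 0, 0, 0),
        kd = c(0, 3, 0, 3, 6, 3, 3, 6)))
      list(well = "H41", treatment = "13C-VA", design = "duplicates",
           duration_days = 84,
           community = community_spec(taxa, treatment = "13C-VA",
                                      well = "H41", n_labeled_replicates = 2),
           producers = producers, features = feats, pools = sip_pools())
    },
    "h43-dual" = {
      taxa <- mk_taxa(
        c("Acetobacterium", "Ferribacterium", "Curvibacter", "Thermodesulfovibrionia",
          "Chloroflexi", "Nitrospira", "Vicinamibacteraceae"),
        ab = c(12, 8, 8, 22, 20, 18, 12) / 100,
        gc = c(0.44, 0.60, 0.62, 0.50, 0.55, 0.56, 0.63),
        af = c(1, 0.6, 0.6, 0, 0, 0, 0))
      producers <- list(
        list(name = "Acetobacterium", profile = c("16:0" = 0.5, "16:1w7" = 0.3,
                                                  "18:1w7" = 0.2),
             growth = 60, trophic_mode = "acetogen"))
      feats <- va_features("h43", data.frame(
        mz = c(182.0579, 168.0423, 61.0284, 154.0266, 196.0372, 212.0321),
        k13c = c(9, 2, 1, 0, 0, 2),
        kd = c(0, 3, 3, 3, 4, 6)))
      list(well = "H43", treatment = "13CO2+D-VA", design = "triplicates",
           duration_days = 84,
           community = community_spec(taxa, treatment = "13CO2+D-VA",
                                      well = "H43", n_labeled_replicates = 3),
           producers = producers, features = feats, pools = sip_pools())
    },
    "h51-dual" = {
      taxa <- mk_taxa(
        c("Microbacterium", "Vicinamibacteraceae", "Hyphomicrobium", "Sphingobium",
          "Nitrospira", "Caulobacteraceae", "Chloroflexi"),
        ab = c(10, 9, 7, 6, 26, 22, 20) / 100,
        gc = c(0.69, 0.63, 0.62, 0.63, 0.56, 0.64, 0.55),
        af = c(1, 0.8, 0.7, 0.7, 0, 0, 0))
      producers <- list(
        list(name = "Microbacterium", profile = c("a15:0" = 0.45, "a17:0" = 0.35,
                                                  "18:1w7" = 0.20),
             growth = 80, trophic_mode = 0.15),
        list(name = "autotroph-minor", profile = c("16:0" = 1),
             growth = 8, trophic_mode = "autotroph"))
      feats <- va_features("h51", data.frame(
        mz = c(182.0579, 168.0423, 154.0266),
        k13c = c(0, 0, 0), kd = c(0, 0, 0)))
      list(well = "H51", treatment = "13CO2+D-VA", design = "triplicates",
           duration_days = 35,
           community = community_spec(taxa, treatment = "13CO2+D-VA",
                                      well = "H51", n_labeled_replicates = 3),
           producers = producers, features = feats, pools = sip_pools())
    },
    "h52-co2" = {
      taxa <- mk_taxa(
        c("Sulfuritalea", "Ahniella", "Thermodesulfovibrionia", "Gallionellaceae",
          "Chloroflexi", "Nitrospira"),
        ab = c(10, 8, 20, 16, 24, 22) / 100,
        gc = c(0.55, 0.66, 0.50, 0.53, 0.55, 0.56),
        af = c(0.8, 0.6, 0, 0, 0, 0))
      producers <- list(
        list(name = "Sulfuritalea", profile = c("10Me16:0" = 0.5, "16:1w7" = 0.3,
                                                "16:0" = 0.2),
             growth = 12, trophic_mode = "autotroph"))
      feats <- va_features("h52", data.frame(
        mz = c(182.0579, 154.0266), k13c = c(0, 0), kd = c(0, 0)))
      list(well = "H52", treatment = "13CO2", design = "duplicates",
           duration_days = 35,
           community = community_spec(taxa, treatment = "13CO2",
                                      well = "H52", n_labeled_replicates = 2),
           producers = producers, features = feats, pools = sip_pools())
    })
}
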