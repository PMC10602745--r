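#' Resolving power needed to separate 13C from D isotopologues
#'
#' A 13C substitution shifts a molecule's mass by ~1.00336 Da and a
#' deuterium substitution by ~1.00628 Da; telling one from the other at mass
#' M requires a resolving power of at least `M / (dm_D - dm_C)` (~M/0.0029),
#' which is what makes the dual-label readout an orbitrap-class measurement.
#'
#' @param mass Neutral or ion mass in Da (> 0), vectorized.
#' @param consts A [sip_constants()] object.
#' @return Required resolving power (dimensionless).
#' @examples
#' required_resolving_power(182.079) # veratric acid, ~62,000
#' @export
required_resolving_power <- function(mass, consts = sip_constants()) {
  if (any(mass < 0)) stop("mass must be >= 0", call. = FALSE)
  mass / (mass_shift_d(consts) - mass_shift_13c(consts))
}

#' Match a 13C/D isotopologue series around a base peak
#'
#' Searches a centroided peak list for isotopologues of `base` on the
#' `(k13c, kd)` grid with `k13c + kd <= max_k` (the unlabeled point (0,0)
#' excluded), at expected masses
#' `base_mz + k13c * dm_C + kd * dm_D`. A peak is assigned to a grid point
#' when it lies within `tol_ppm` of its expected mass; if it lies within
#' tolerance of two or more grid points it is flagged ambiguous and assigned
#' to none (preventing resolution-limited misreads of the label counts).
#' Each grid point keeps only its closest-ppm peak; ties are broken by lower
#' ppm error, then lower m/z, so matching is deterministic and independent
#' of peak-list order.
#'
#' @param base List or one-row data.frame with `mz` and `intensity` of the
#'   unlabeled (monoisotopic) feature peak.
#' @param peaks Data.frame of centroided peaks with columns `mz`,
#'   `intensity` (and optionally `rt`). Must contain the base peak itself
#'   (within `tol_ppm`).
#' @param max_k Maximum total label atoms searched (default 12).
#' @param tol_ppm Match tolerance in ppm (default 2).
#' @param consts A [sip_constants()] object (provides the exact shifts).
#' @return An `isotopologue_series`: `base_mz`, `base_intensity`, `members`
#'   (data.frame `k13c`, `kd`, `mz`, `intensity`, `ppm_error`), `ambiguous`
#'   (data.frame of flagged peaks), `max_k13c`, `max_kd`.
#' @export
match_series <- function(base, peaks, max_k = 12, tol_ppm = 2,
                         consts = sip_constants()) {
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  if (!is.numeric(max_k) || max_k < 1) stop("max_k must be >= 1", call. = FALSE)
  base_mz <- base$mz[1]
  base_int <- base$intensity[1]
  if (!is.numeric(base_mz) || base_mz <= 0) stop("base mz must be > 0", call. = FALSE)
  if (nrow(peaks) == 0L || !any(abs(peaks$mz - base_mz) / base_mz * 1e6 <= tol_ppm))
    stop("missing-base error: no peak within ", tol_ppm,
         " ppm of the base m/z", call. = FALSE)
  dm_c <- mass_shift_13c(consts)
  dm_d <- mass_shift_d(consts)
  grid <- expand.grid(k13c = 0:max_k, kd = 0:max_k)
  grid <- grid[grid$k13c + grid$kd >= 1 & grid$k13c + grid$kd <= max_k, ]
  grid$mz <- base_mz + grid$k13c * dm_c + grid$kd * dm_d

  # candidate grid points per peak, within tolerance
  members <- data.frame(k13c = integer(0), kd = integer(0), mz = numeric(0),
                        intensity = numeric(0), ppm_error = numeric(0))
  ambiguous <- data.frame(mz = numeric(0), intensity = numeric(0),
                          n_candidates = integer(0))
  assign <- vector("list", nrow(grid))
  for (i in seq_len(nrow(peaks))) {
    pmz <- peaks$mz[i]
    ppm <- abs(pmz - grid$mz) / grid$mz * 1e6
    hits <- which(ppm <= tol_ppm)
    if (length(hits) == 0L) next
    if (length(hits) >= 2L) {
      ambiguous <- rbind(ambiguous,
                         data.frame(mz = pmz, intensity = peaks$intensity[i],
                                    n_candidates = length(hits)))
      next
    }
    g <- hits
    cand <- data.frame(k13c = grid$k13c[g], kd = grid$kd[g], mz = pmz,
                       intensity = peaks$intensity[i], ppm_error = ppm[g])
    prev <- assign[[g]]
    if (is.null(prev) || cand$ppm_error < prev$ppm_error ||
        (cand$ppm_error == prev$ppm_error && cand$mz < prev$mz))
      assign[[g]] <- cand
  }
  kept <- do.call(rbind, assign[!vapply(assign, is.null, logical(1))])
  if (!is.null(kept)) {
    kept <- kept[order(kept$k13c + kept$kd, kept$k13c), ]
    rownames(kept) <- NULL
    members <- kept
  }
  structure(list(base_mz = base_mz, base_intensity = base_int,
                 members = members, ambiguous = ambiguous,
                 max_k13c = if (nrow(members)) max(members$k13c) else 0L,
                 max_kd = if (nrow(members)) max(members$kd) else 0L,
                 tol_ppm = tol_ppm, max_k = max_k),
            class = "isotopologue_series")
}

#' @export
print.isotopologue_series <- function(x, ...) {
  cat(sprintf("Isotopologue series at m/z %.4f: %d member(s), %d ambiguous; max k13C = %d, max kD = %d\n",
              x$base_mz, nrow(x$members), nrow(x$ambiguous),
              x$max_k13c, x$max_kd))
  invisible(x)
}

#' Label flags and the CD3 methyl-transfer rule
#'
#' Declares a feature 13C- or D-labeled when its series contains at least
#' one isotopologue of that type with intensity at least
#' `min_intensity_frac` of the base peak. The CD3 rule then inspects the
#' deuterium count: a maximum D count that is positive and divisible by
#' three is the signature of intact transfer of a trideuterated methyl group
#' (e.g. from a CD3-methoxy donor via methyltransferase), and
#' `n_cd3_groups = max_kd / 3`.
#'
#' @param series An `isotopologue_series` from [match_series()].
#' @param min_intensity_frac Intensity floor as a fraction of the base-peak
#'   intensity, in `[0, 1)`; default 0.01.
#' @return A `label_assignment`: `labeled_13c`, `labeled_d`, `max_k13c`,
#'   `max_kd` (recomputed over retained members), `cd3_transfer`,
#'   `n_cd3_groups`.
#' @export
assign_labels <- function(series, min_intensity_frac = 0.01) {
  stopifnot(inherits(series, "isotopologue_series"))
  if (min_intensity_frac < 0 || min_intensity_frac >= 1)
    stop("min_intensity_frac must lie in [0, 1)", call. = FALSE)
  m <- series$members
  keep <- m[m$intensity >= min_intensity_frac * series$base_intensity, , drop = FALSE]
  max_k13c <- if (nrow(keep)) max(keep$k13c) else 0L
  max_kd <- if (nrow(keep)) max(keep$kd) else 0L
  labeled_13c <- any(keep$k13c > 0)
  labeled_d <- any(keep$kd > 0)
  cd3 <- max_kd > 0 && max_kd %% 3 == 0
  structure(list(series = series, labeled_13c = labeled_13c,
                 labeled_d = labeled_d, max_k13c = max_k13c, max_kd = max_kd,
                 cd3_transfer = cd3,
                 n_cd3_groups = if (cd3) max_kd %/% 3 else 0L,
                 min_intensity_frac = min_intensity_frac),
            class = "label_assignment")
}

#' @export
print.label_assignment <- function(x, ...) {
  cat(sprintf("m/z %.4f: 13C %s (max %d), D %s (max %d)%s\n",
              x$series$base_mz, if (x$labeled_13c) "labeled" else "-",
              x$max_k13c, if (x$labeled_d) "labeled" else "-", x$max_kd,
              if (x$cd3_transfer)
                sprintf(", CD3 transfer (%d group%s)", x$n_cd3_groups,
                        if (x$n_cd3_groups > 1) "s" else "") else ""))
  invisible(x)
}

#' Census of labeled exometabolite species
#'
#' Counts, over distinct base features, how many are 13C-labeled, how many
#' are D-labeled, and how many of the D-labeled have a deuterium count
#' divisible by three (the CD3 methyl-transfer signature).
#'
#' @param assignments List of `label_assignment` objects.
#' @return Named list `n_13c_species`, `n_d_species`, `n_divisible_by_3`.
#' @export
count_label_census <- function(assignments) {
  stopifnot(all(vapply(assignments, inherits, logical(1), "label_assignment")))
  n13 <- sum(vapply(assignments, `[[`, logical(1), "labeled_13c"))
  nd <- sum(vapply(assignments, `[[`, logical(1), "labeled_d"))
  n3 <- sum(vapply(assignments, function(a) a$labeled_d && a$cd3_transfer,
                   logical(1)))
  list(n_13c_species = n13, n_d_species = nd, n_divisible_by_3 = n3)
}

#' Substrate consumption from peak areas
#'
#' Relative concentration of a tracked substrate (e.g. veratric or vanillic
#' acid) at the end of the incubation versus the start:
#' `rel_conc = area_tend / area_t0`, `percent_consumed = 100 * (1 - rel_conc)`.
#'
#' @param areas_t0 Initial peak area(s) (> 0).
#' @param areas_tend Final peak area(s) (>= 0).
#' @param compound Optional compound label(s) carried into the result.
#' @return Data.frame `compound`, `rel_conc`, `percent_consumed`.
#' @examples
#' substrate_consumption(100, 25) # 75% consumed
#' @export
substrate_consumption <- function(areas_t0, areas_tend, compound = NA_character_) {
  if (any(!is.finite(areas_t0)) || any(areas_t0 <= 0))
    stop("invalid baseline: initial areas must be > 0", call. = FALSE)
  if (any(areas_tend < 0))
    stop("final areas must be >= 0", call. = FALSE)
  rel <- areas_tend / areas_t0
  data.frame(compound = compound, rel_conc = rel,
             percent_consumed = 100 * (1 - rel), stringsAsFactors = FALSE)
}

#' Run the label search over a per-feature peak-list table
#'
#' @param peaks Data.frame with columns `feature_id`, `mz`, `intensity`
#'   (optionally `rt`); within each feature the lowest-m/z peak is taken as
#'   the base (monoisotopic) peak.
#' @param max_k,tol_ppm,consts Passed to [match_series()].
#' @param min_intensity_frac Passed to [assign_labels()].
#' @return List with `assignments` (list of `label_assignment`), `table`
#'   (one row per feature) and `census`.
#' @export
metab_label_table <- function(peaks, max_k = 12, tol_ppm = 2,
                              min_intensity_frac = 0.01,
                              consts = sip_constants()) {
  need <- c("feature_id", "mz", "intensity")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  feats <- split(peaks, peaks$feature_id)
  assignments <- lapply(feats, function(p) {
    p <- p[order(p$mz), ]
    s <- match_series(list(mz = p$mz[1], intensity = p$intensity[1]), p,
                      max_k = max_k, tol_ppm = tol_ppm, consts = consts)
    assign_labels(s, min_intensity_frac)
  })
  tab <- do.call(rbind, lapply(names(assignments), function(id) {
    a <- assignments[[id]]
    data.frame(feature_id = id, base_mz = a$series$base_mz,
               max_k13c = a$max_k13c, max_kd = a$max_kd,
               labeled_13c = a$labeled_13c, labeled_d = a$labeled_d,
               cd3_transfer = a$cd3_transfer, n_cd3_groups = a$n_cd3_groups,
               n_ambiguous = nrow(a$series$ambiguous),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(assignments = assignments, table = tab,
       census = count_label_census(assignments))
}
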