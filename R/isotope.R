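#' Isotope reference constants
#'
#' Bundles the isotope-ratio reference standards and exact atomic masses used
#' throughout the package: the VPDB 13C/12C ratio for carbon, the VSMOW D/H
#' ratio for hydrogen, and the exact masses of 12C, 13C, 1H and 2H. The
#' defaults are the IUPAC values; every field can be overridden, e.g. to study
#' the sensitivity of downstream results to the reference choice.
#'
#' The two heavy-light mass differences implied by the defaults are
#' 1.0034 Da (13C - 12C) and 1.0063 Da (2H - 1H) when rounded to four
#' decimals; these are the shifts used to separate carbon from deuterium
#' isotopologues in high-resolution MS data (see [match_series()]).
#'
#' @param r_vpdb_13c 13C/12C ratio of the VPDB standard (dimensionless).
#' @param r_vsmow_d D/H ratio of the VSMOW standard (dimensionless).
#' @param mass_12c,mass_13c,mass_1h,mass_2h Exact atomic masses in Da.
#' @return An object of class `sip_constants` (a validated list).
#' @examples
#' k <- sip_constants()
#' mass_shift_13c(k) # ~1.0034
#' mass_shift_d(k)   # ~1.0063
#' @export
sip_constants <- function(r_vpdb_13c = 0.0111802,
                          r_vsmow_d = 1.5576e-4,
                          mass_12c = 12,
                          mass_13c = 13.0033548,
                          mass_1h = 1.0078250,
                          mass_2h = 2.0141018) {
  x <- list(r_vpdb_13c = r_vpdb_13c, r_vsmow_d = r_vsmow_d,
            mass_12c = mass_12c, mass_13c = mass_13c,
            mass_1h = mass_1h, mass_2h = mass_2h)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("sip_constants: '", nm, "' must be a single positive number", call. = FALSE)
  }
  dc <- mass_13c - mass_12c
  dh <- mass_2h - mass_1h
  if (dc <= 1.0030 || dc >= 1.0037)
    stop("sip_constants: 13C-12C mass difference out of range (1.0030, 1.0037)", call. = FALSE)
  if (dh <= 1.0059 || dh >= 1.0066)
    stop("sip_constants: 2H-1H mass difference out of range (1.0059, 1.0066)", call. = FALSE)
  structure(x, class = "sip_constants")
}

#' @rdname sip_constants
#' @export
mass_shift_13c <- function(consts = sip_constants()) consts$mass_13c - consts$mass_12c

#' @rdname sip_constants
#' @export
mass_shift_d <- function(consts = sip_constants()) consts$mass_2h - consts$mass_1h

#' @export
print.sip_constants <- function(x, ...) {
  cat("Isotope constants:\n")
  cat(sprintf("  R(13C/12C) VPDB : %.7g\n", x$r_vpdb_13c))
  cat(sprintf("  R(D/H) VSMOW    : %.7g\n", x$r_vsmow_d))
  cat(sprintf("  mass shift 13C  : %.7f Da\n", mass_shift_13c(x)))
  cat(sprintf("  mass shift D    : %.7f Da\n", mass_shift_d(x)))
  invisible(x)
}

.std_for_element <- function(element) {
  switch(element, C = "VPDB", H = "VSMOW",
         stop("element must be 'C' or 'H'", call. = FALSE))
}

.r_standard <- function(element, consts) {
  switch(element, C = consts$r_vpdb_13c, H = consts$r_vsmow_d)
}

#' Delta notation value
#'
#' A per-mil isotope delta against a named reference standard (VPDB for
#' carbon, VSMOW for hydrogen). Values at or below -1000 permil are rejected
#' because they would imply a non-positive isotope ratio.
#'
#' @param value Numeric vector of delta values in permil.
#' @param element `"C"` or `"H"`.
#' @param standard Reference standard; defaults to the conventional standard
#'   for the element (`"VPDB"` for C, `"VSMOW"` for H).
#' @return An object of class `delta_value`.
#' @examples
#' delta_value(-25, "C")
#' @export
delta_value <- function(value, element = c("C", "H"), standard = NULL) {
  element <- match.arg(element)
  if (is.null(standard)) standard <- .std_for_element(element)
  if (!standard %in% c("VPDB", "VSMOW"))
    stop("standard must be 'VPDB' or 'VSMOW'", call. = FALSE)
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("delta value must be finite numeric", call. = FALSE)
  if (any(value <= -1000))
    stop("invalid delta: value <= -1000 permil implies a non-positive isotope ratio",
         call. = FALSE)
  structure(list(value = as.numeric(value), element = element, standard = standard),
            class = "delta_value")
}

#' @export
print.delta_value <- function(x, ...) {
  cat(sprintf("delta%s vs %s: %s permil\n",
              if (x$element == "C") "13C" else "D", x$standard,
              paste(signif(x$value, 6), collapse = ", ")))
  invisible(x)
}

#' Atom fraction of the heavy isotope
#'
#' @param value Fraction of heavy-isotope atoms among all atoms of the
#'   element, in `[0, 1]`.
#' @param element `"C"` or `"H"`.
#' @return An object of class `atom_fraction`.
#' @export
atom_fraction <- function(value, element = c("C", "H")) {
  element <- match.arg(element)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0) || any(value > 1))
    stop("atom fraction must lie in [0, 1]", call. = FALSE)
  structure(list(value = as.numeric(value), element = element),
            class = "atom_fraction")
}

#' Convert between delta, isotope ratio and atom fraction
#'
#' `delta_to_ratio()` applies R = R_standard * (1 + delta/1000).
#' `ratio_to_delta()` is its inverse. `ratio_to_atom_fraction()` computes
#' F = R/(1+R) and `atom_fraction_to_ratio()` inverts it.
#' `delta_to_atom_fraction()` composes the two forward steps.
#'
#' Atom fraction, not delta, is the linear currency for all mixing and rate
#' arithmetic in this package; deltas appear only at I/O boundaries.
#'
#' @param d A [delta_value()].
#' @param r Non-negative isotope ratio (heavy/light), numeric vector.
#' @param f Atom fraction in `[0, 1)`, numeric vector or [atom_fraction()].
#' @param element `"C"` or `"H"` (for `ratio_to_delta`).
#' @param consts A [sip_constants()] object.
#' @return Numeric vector (ratios, atom fractions) or a [delta_value()].
#' @examples
#' k <- sip_constants()
#' delta_to_ratio(delta_value(0, "C"), k)     # R_VPDB
#' ratio_to_atom_fraction(1)                  # 0.5
#' @export
delta_to_ratio <- function(d, consts = sip_constants()) {
  stopifnot(inherits(d, "delta_value"))
  .r_standard(d$element, consts) * (1 + d$value / 1000)
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(r, element = c("C", "H"), consts = sip_constants()) {
  element <- match.arg(element)
  if (any(r <= 0)) stop("invalid ratio: must be positive", call. = FALSE)
  delta_value((r / .r_standard(element, consts) - 1) * 1000, element)
}

#' @rdname delta_to_ratio
#' @export
ratio_to_atom_fraction <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("invalid ratio: must be finite and >= 0", call. = FALSE)
  r / (1 + r)
}

#' @rdname delta_to_ratio
#' @export
atom_fraction_to_ratio <- function(f) {
  if (inherits(f, "atom_fraction")) f <- f$value
  if (any(f < 0) || any(f >= 1))
    stop("atom fraction must lie in [0, 1) to convert to a ratio", call. = FALSE)
  f / (1 - f)
}

#' @rdname delta_to_ratio
#' @export
delta_to_atom_fraction <- function(d, consts = sip_constants()) {
  ratio_to_atom_fraction(delta_to_ratio(d, consts))
}

#' Correct a FAME delta for the derivatization methyl group
#'
#' PLFAs are measured as fatty-acid methyl esters (FAMEs); methylation adds
#' one carbon (and three hydrogens) from the derivatizing agent whose isotopic
#' signature must be removed by elemental mass balance:
#' `delta_FA = ((n + a) * delta_FAME - a * delta_agent) / n`,
#' where `n` is the number of analyte atoms of the element in the fatty acid
#' and `a` the number of added atoms (1 for C, 3 for H).
#'
#' @param delta_fame Measured FAME delta, a [delta_value()].
#' @param n_fa_atoms Number of atoms of the element in the underivatized
#'   fatty acid (carbons for C, hydrogens for H); must be >= 1.
#' @param delta_agent Delta of the derivatizing agent's contributed atoms,
#'   a [delta_value()] with the same element and standard.
#' @return The corrected fatty-acid delta as a [delta_value()].
#' @examples
#' methylation_correct(delta_value(-25, "C"), 16, delta_value(-40, "C"))
#' @export
methylation_correct <- function(delta_fame, n_fa_atoms, delta_agent) {
  stopifnot(inherits(delta_fame, "delta_value"), inherits(delta_agent, "delta_value"))
  if (delta_fame$element != delta_agent$element ||
      delta_fame$standard != delta_agent$standard)
    stop("incompatible deltas: element/standard of FAME and agent must match",
         call. = FALSE)
  if (!is.numeric(n_fa_atoms) || n_fa_atoms < 1)
    stop("n_fa_atoms must be >= 1", call. = FALSE)
  a <- if (delta_fame$element == "C") 1 else 3
  corrected <- ((n_fa_atoms + a) * delta_fame$value - a * delta_agent$value) / n_fa_atoms
  delta_value(corrected, delta_fame$element, delta_fame$standard)
}

#' Excess atom fraction between a labeled and a baseline measurement
#'
#' Computes `F(labeled) - F(baseline)`, the increase in heavy-isotope atom
#' fraction attributable to label uptake. The result may be negative (e.g.
#' from measurement noise in unlabeled material) and is returned as-is;
#' callers such as [incorporation_rate()] decide whether to clamp.
#'
#' @param labeled,baseline [delta_value()] objects with matching element and
#'   standard (typically Tend and T0 of the same analyte).
#' @param consts A [sip_constants()] object.
#' @return Numeric excess atom fraction (can be negative).
#' @export
excess_atom_fraction <- function(labeled, baseline, consts = sip_constants()) {
  stopifnot(inherits(labeled, "delta_value"), inherits(baseline, "delta_value"))
  if (labeled$element != baseline$element || labeled$standard != baseline$standard)
    stop("incompatible deltas: element/standard must match", call. = FALSE)
  delta_to_atom_fraction(labeled, consts) - delta_to_atom_fraction(baseline, consts)
}

# atom fraction -> delta, used when synthesising measurements
.atom_fraction_to_delta <- function(f, element, consts = sip_constants()) {
  ratio_to_delta(atom_fraction_to_ratio(f), element, consts)
}
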