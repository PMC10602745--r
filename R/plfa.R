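#' Parse standard PLFA nomenclature
#'
#' Parses fatty-acid names of the form `[cy][i|a][<pos>Me]C<n>:<d>[w<pos>][c|t]`,
#' e.g. `"16:0"`, `"a15:0"`, `"i15:0"`, `"cy17:0"`, `"10Me16:0"`,
#' `"C18:1w7"` (unicode omega accepted and canonicalized to `w`). The number
#' before the colon is the chain length; the number after it the count of
#' double bonds, optionally followed by the omega position of the first one.
#' Prefixes: `i` iso-branched, `a` anteiso-branched, `cy` cyclopropane,
#' `<pos>Me` a mid-chain methyl branch.
#'
#' Carbon-count convention: mid-chain methyl branches add to the total carbon
#' count, so `10Me16:0` has 17 carbons (16-carbon chain plus the branch
#' methyl); `i`/`a` branches are already counted in the chain number. The
#' hydrogen inventory of the free acid is `2*n_carbons - 2*n_double_bonds -
#' 2*(cyclopropane rings)` (formula CnH2nO2 for a saturated acyclic acid).
#'
#' @param raw A single PLFA name string.
#' @return An object of class `plfa_name` with fields `raw`, `n_carbons`
#'   (total, including methyl branches), `chain_length`, `n_double_bonds`,
#'   `omega_position` (NA when unspecified), `prefixes` (character vector),
#'   `methyl_positions` (integer vector), `cyclopropane` (logical).
#' @examples
#' parse_plfa_name("16:0")
#' parse_plfa_name("10Me16:0")$n_carbons # 17
#' format(parse_plfa_name("C18:1ω7")) # "18:1w7"
#' @export
parse_plfa_name <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("PLFA name must be a single non-empty string", call. = FALSE)
  x <- gsub("ω", "w", trimws(raw))
  x <- gsub("Δ", "d", x)
  rx <- "^(cy)?((?:[0-9]+Me)*)(i|a)?C?([0-9]+):([0-9]+)(?:w([0-9]+))?([ct])?$"
  m <- regmatches(x, regexec(rx, x))[[1]]
  if (length(m) == 0L)
    stop("unparseable PLFA name '", raw, "'; accepted grammar: ",
         "[cy][<pos>Me...][i|a][C]<chain>:<double bonds>[w<pos>][c|t]",
         call. = FALSE)
  cy <- nzchar(m[2])
  me <- m[3]
  iso <- m[4]
  chain <- as.integer(m[5])
  ndb <- as.integer(m[6])
  omega <- if (nzchar(m[7])) as.integer(m[7]) else NA_integer_
  geom <- if (nzchar(m[8])) m[8] else NA_character_
  methyl_positions <- if (nzchar(me))
    as.integer(regmatches(me, gregexpr("[0-9]+", me))[[1]]) else integer(0)
  n_carbons <- chain + length(methyl_positions)
  if (n_carbons < 10 || n_carbons > 24)
    stop("PLFA '", raw, "': total carbon count ", n_carbons,
         " outside the supported range [10, 24]", call. = FALSE)
  if (ndb < 0 || ndb > 6)
    stop("PLFA '", raw, "': double-bond count outside [0, 6]", call. = FALSE)
  if (!is.na(omega) && ndb < 1)
    stop("PLFA '", raw, "': omega position given but no double bond", call. = FALSE)
  prefixes <- c(if (cy) "cy",
                if (length(methyl_positions)) paste0(methyl_positions, "Me"),
                if (nzchar(iso)) iso)
  structure(list(raw = raw, n_carbons = n_carbons, chain_length = chain,
                 n_double_bonds = ndb, omega_position = omega,
                 geometry = geom, prefixes = prefixes %||% character(0),
                 methyl_positions = methyl_positions, cyclopropane = cy),
            class = "plfa_name")
}

#' @export
format.plfa_name <- function(x, ...) {
  paste0(if (x$cyclopropane) "cy",
         if (length(x$methyl_positions)) paste0(x$methyl_positions, "Me", collapse = ""),
         if (any(x$prefixes %in% c("i", "a"))) intersect(x$prefixes, c("i", "a")),
         x$chain_length, ":", x$n_double_bonds,
         if (!is.na(x$omega_position)) paste0("w", x$omega_position),
         if (!is.na(x$geometry)) x$geometry)
}

#' @export
print.plfa_name <- function(x, ...) {
  cat(sprintf("PLFA %s (%d C, %d H, %d double bond%s)\n", format(x),
              x$n_carbons, plfa_hydrogen_count(x), x$n_double_bonds,
              if (x$n_double_bonds == 1) "" else "s"))
  invisible(x)
}

#' Atom inventories of a parsed PLFA
#'
#' @param x A `plfa_name` (or a string, parsed on the fly).
#' @return Integer atom count of the free fatty acid.
#' @export
plfa_carbon_count <- function(x) {
  if (is.character(x)) x <- parse_plfa_name(x)
  x$n_carbons
}

#' @rdname plfa_carbon_count
#' @export
plfa_hydrogen_count <- function(x) {
  if (is.character(x)) x <- parse_plfa_name(x)
  2L * x$n_carbons - 2L * x$n_double_bonds - 2L * as.integer(x$cyclopropane)
}

#' One PLFA measurement at one timepoint
#'
#' @param name PLFA name string or `plfa_name`.
#' @param timepoint `"T0"` or `"Tend"`.
#' @param concentration Lipid concentration, pmol/L (>= 0).
#' @param delta_13c,delta_d Numeric permil values or [delta_value()]s.
#' @param treatment,well Optional labels carried through to outputs.
#' @return An object of class `plfa_measurement`.
#' @export
plfa_measurement <- function(name, timepoint = c("T0", "Tend"), concentration,
                             delta_13c, delta_d, treatment = NA_character_,
                             well = NA_character_) {
  timepoint <- match.arg(timepoint)
  if (is.character(name)) name <- parse_plfa_name(name)
  stopifnot(inherits(name, "plfa_name"))
  if (!is.numeric(concentration) || concentration < 0)
    stop("concentration must be >= 0 pmol/L", call. = FALSE)
  if (is.numeric(delta_13c)) delta_13c <- delta_value(delta_13c, "C")
  if (is.numeric(delta_d)) delta_d <- delta_value(delta_d, "H")
  structure(list(name = name, timepoint = timepoint,
                 concentration = concentration, delta_13c = delta_13c,
                 delta_d = delta_d, treatment = treatment, well = well),
            class = "plfa_measurement")
}

.check_pair <- function(t0, tend) {
  stopifnot(inherits(t0, "plfa_measurement"), inherits(tend, "plfa_measurement"))
  if (format(t0$name) != format(tend$name))
    stop("pairing error: T0 is ", format(t0$name), " but Tend is ",
         format(tend$name), call. = FALSE)
  if (t0$timepoint != "T0" || tend$timepoint != "Tend")
    stop("pairing error: expected one T0 and one Tend measurement", call. = FALSE)
}

#' Carbon produced between two timepoints
#'
#' `(conc_Tend - conc_T0) * n_carbons`, in pmol C/L. Negative values
#' (net lipid loss) are returned as-is at this layer.
#'
#' @param t0,tend [plfa_measurement()]s of the same lipid.
#' @return Numeric, pmol C/L.
#' @export
carbon_produced <- function(t0, tend) {
  .check_pair(t0, tend)
  (tend$concentration - t0$concentration) * t0$name$n_carbons
}

#' Label incorporation rate of a PLFA
#'
#' The amount of 13C or deuterium incorporated into a lipid per day:
#' `rate = deltaF * produced / duration`, where `deltaF` is the excess
#' heavy-isotope atom fraction between Tend and T0 (see
#' [excess_atom_fraction()]) and `produced` is the new-biomass atom inventory
#' over the incubation. For 13C, `produced` is always the carbon produced.
#' For deuterium two conventions are offered: `d_inventory = "carbon"`
#' (default) multiplies the deuterium excess by the carbon produced, treating
#' carbon as the common biomass currency for both tracers; `"hydrogen"` uses
#' the lipid's hydrogen inventory instead ([plfa_hydrogen_count()]). The mode
#' used is recorded in the result.
#'
#' @param t0,tend [plfa_measurement()]s of the same lipid.
#' @param isotope `"13C"` or `"D"`.
#' @param duration Incubation length in days (> 0).
#' @param clamp If `TRUE` (default) negative rates (isotope dilution or lipid
#'   loss) are reported as 0 with `clamped = TRUE`.
#' @param d_inventory Deuterium inventory convention, see Details.
#' @param consts A [sip_constants()] object.
#' @return An object of class `production_rate`: fields `name`, `isotope`,
#'   `rate` (pmol isotope/L/day), `c_produced` (pmol C/L), `delta_f`,
#'   `clamped`, `d_inventory`.
#' @export
incorporation_rate <- function(t0, tend, isotope = c("13C", "D"), duration,
                               clamp = TRUE, d_inventory = c("carbon", "hydrogen"),
                               consts = sip_constants()) {
  isotope <- match.arg(isotope)
  d_inventory <- match.arg(d_inventory)
  .check_pair(t0, tend)
  if (!is.numeric(duration) || duration <= 0)
    stop("invalid duration: must be > 0 days", call. = FALSE)
  c_prod <- carbon_produced(t0, tend)
  if (isotope == "13C") {
    df <- excess_atom_fraction(tend$delta_13c, t0$delta_13c, consts)
    produced <- c_prod
  } else {
    df <- excess_atom_fraction(tend$delta_d, t0$delta_d, consts)
    produced <- if (d_inventory == "carbon") c_prod
    else (tend$concentration - t0$concentration) * plfa_hydrogen_count(t0$name)
  }
  rate <- df * produced / duration
  clamped <- FALSE
  if (clamp && rate < 0) {
    rate <- 0
    clamped <- TRUE
  }
  structure(list(name = t0$name, isotope = isotope, rate = rate,
                 c_produced = c_prod, delta_f = df, clamped = clamped,
                 d_inventory = if (isotope == "D") d_inventory else NA_character_,
                 duration = duration),
            class = "production_rate")
}

#' @export
print.production_rate <- function(x, ...) {
  cat(sprintf("%s %s incorporation: %.4g pmol/L/day (deltaF = %.4g, C produced = %.4g)%s\n",
              format(x$name), x$isotope, x$rate, x$delta_f, x$c_produced,
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Ra/Rt trophic discriminant for a dual-labeled lipid
#'
#' In a dual 13CO2 + deuterated-substrate incubation, the 13C incorporation
#' rate tracks inorganic-carbon assimilation into lipids (Ra) while the
#' deuterium rate tracks total lipid production (Rt). Their ratio separates
#' predominantly heterotrophic (<= 0.3) from completely autotrophic (~1)
#' lipid production.
#'
#' Because the two tracers enter at different pool label strengths, both
#' rates are by default divided by the heavy-atom fraction of their source
#' pool (the 13C fraction of dissolved inorganic carbon, and the deuterium
#' fraction of the labile substrate hydrogen) before the ratio is formed.
#' Set `normalize = FALSE` to compare raw rates.
#'
#' @param ra A `production_rate` for isotope `"13C"`.
#' @param rt A `production_rate` for isotope `"D"`.
#' @param f13c_dic 13C atom fraction of the DIC pool, in (0, 1].
#' @param fd_substrate Deuterium atom fraction of the labeled substrate
#'   hydrogen pool, in (0, 1].
#' @param normalize Divide each rate by its source-pool atom fraction first.
#' @param thresholds Named numeric: `heterotrophic` upper bound (default 0.3)
#'   and `autotrophic` lower bound (default 0.8); ratios in between are
#'   called `"mixed"`.
#' @return An object of class `trophic_call` with fields `name`, `ra`, `rt`
#'   (normalized values actually used), `ra_rt`, `call`, `normalized`,
#'   `thresholds`.
#' @export
ra_rt <- function(ra, rt, f13c_dic, fd_substrate, normalize = TRUE,
                  thresholds = c(heterotrophic = 0.3, autotrophic = 0.8)) {
  stopifnot(inherits(ra, "production_rate"), inherits(rt, "production_rate"))
  if (ra$isotope != "13C" || rt$isotope != "D")
    stop("ra must be a 13C rate and rt a D rate", call. = FALSE)
  if (!is.numeric(f13c_dic) || f13c_dic <= 0 || f13c_dic > 1 ||
      !is.numeric(fd_substrate) || fd_substrate <= 0 || fd_substrate > 1)
    stop("source-pool atom fractions must lie in (0, 1]", call. = FALSE)
  if (thresholds[["heterotrophic"]] >= thresholds[["autotrophic"]])
    stop("heterotrophic threshold must be below the autotrophic threshold",
         call. = FALSE)
  ra_val <- if (normalize) ra$rate / f13c_dic else ra$rate
  rt_val <- if (normalize) rt$rate / fd_substrate else rt$rate
  if (rt_val <= 0)
    stop("undefined ratio: total production rate Rt is zero", call. = FALSE)
  ratio <- ra_val / rt_val
  call <- if (ratio <= thresholds[["heterotrophic"]]) "heterotrophic"
  else if (ratio >= thresholds[["autotrophic"]]) "autotrophic"
  else "mixed"
  structure(list(name = ra$name, ra = ra_val, rt = rt_val, ra_rt = ratio,
                 call = call, normalized = normalize, thresholds = thresholds),
            class = "trophic_call")
}

#' @export
print.trophic_call <- function(x, ...) {
  cat(sprintf("%s Ra/Rt = %.3g -> %s\n", format(x$name), x$ra_rt, x$call))
  invisible(x)
}

#' Expected Ra/Rt of an acetogen using a methyl-transferring pathway
#'
#' During acetogenesis via the Wood-Ljungdahl pathway combined with a methyl
#' transferase acting on a methoxy-derived C1 group, one carbon of acetyl-CoA
#' comes from the CH3 group (heterotrophic origin) and one from CO2. Under
#' this two-carbon model the expected Ra/Rt is `1 - fraction_c1`, where
#' `fraction_c1` is the fraction of acetyl carbon drawn from the methyl
#' group; the canonical 50/50 split gives 0.5.
#'
#' @param fraction_c1 Fraction of acetyl carbon derived from the methyl
#'   group, in `[0, 1]`.
#' @return Expected Ra/Rt (numeric).
#' @examples
#' acetogen_expectation(0.5) # 0.5
#' acetogen_expectation(c(0.6, 0.7)) # 0.4, 0.3
#' @export
acetogen_expectation <- function(fraction_c1) {
  if (!is.numeric(fraction_c1) || any(fraction_c1 < 0) || any(fraction_c1 > 1))
    stop("fraction_c1 must lie in [0, 1]", call. = FALSE)
  1 - fraction_c1
}

#' Per-lipid rates and trophic calls from a long measurement table
#'
#' Table-level driver over [incorporation_rate()] and [ra_rt()]. The input
#' is one row per (lipid, timepoint) with columns `plfa_name`, `timepoint`
#' (`T0`/`Tend`), `conc_pmol_per_l`, `delta13c_permil`, `deltad_permil`, and
#' optionally `well`/`treatment`.
#'
#' @param measurements Long-form data.frame as described above.
#' @param duration Incubation duration in days.
#' @param pools List with `f13c_dic` and `fd_substrate` source-pool atom
#'   fractions (needed for trophic calls; set `trophic = FALSE` to skip).
#' @param clamp,d_inventory,consts Passed to [incorporation_rate()].
#' @param normalize,thresholds Passed to [ra_rt()].
#' @param trophic Compute Ra/Rt per lipid (requires both isotope deltas).
#' @return A data.frame with one row per lipid: both rates, deltaF values,
#'   carbon produced, and (if `trophic`) `ra_rt` and `call`.
#' @export
plfa_rate_table <- function(measurements, duration,
                            pools = list(f13c_dic = NULL, fd_substrate = NULL),
                            clamp = TRUE, d_inventory = "carbon",
                            normalize = TRUE,
                            thresholds = c(heterotrophic = 0.3, autotrophic = 0.8),
                            trophic = TRUE, consts = sip_constants()) {
  need <- c("plfa_name", "timepoint", "conc_pmol_per_l",
            "delta13c_permil", "deltad_permil")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(measurements, measurements$plfa_name), function(g) {
    r0 <- g[g$timepoint == "T0", , drop = FALSE]
    r1 <- g[g$timepoint == "Tend", , drop = FALSE]
    if (nrow(r0) != 1L || nrow(r1) != 1L)
      stop("lipid '", g$plfa_name[1],
           "' needs exactly one T0 and one Tend row", call. = FALSE)
    m0 <- plfa_measurement(g$plfa_name[1], "T0", r0$conc_pmol_per_l,
                           r0$delta13c_permil, r0$deltad_permil)
    m1 <- plfa_measurement(g$plfa_name[1], "Tend", r1$conc_pmol_per_l,
                           r1$delta13c_permil, r1$deltad_permil)
    rc <- incorporation_rate(m0, m1, "13C", duration, clamp, d_inventory, consts)
    rd <- incorporation_rate(m0, m1, "D", duration, clamp, d_inventory, consts)
    row <- data.frame(plfa_name = g$plfa_name[1],
                      n_carbons = m0$name$n_carbons,
                      c_produced_pmol_l = rc$c_produced,
                      delta_f_13c = rc$delta_f, rate_13c = rc$rate,
                      delta_f_d = rd$delta_f, rate_d = rd$rate,
                      clamped_13c = rc$clamped, clamped_d = rd$clamped,
                      stringsAsFactors = FALSE)
    if (trophic) {
      if (is.null(pools$f13c_dic) || is.null(pools$fd_substrate))
        stop("pools$f13c_dic and pools$fd_substrate are required for trophic calls",
             call. = FALSE)
      tc <- tryCatch(ra_rt(rc, rd, pools$f13c_dic, pools$fd_substrate,
                           normalize, thresholds),
                     error = function(e) NULL)
      row$ra_rt <- if (is.null(tc)) NA_real_ else tc$ra_rt
      row$trophic_call <- if (is.null(tc)) NA_character_ else tc$call
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
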