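#' Heavy/light split rules for gradient fractions
#'
#' DNA-SIP divides the CsCl gradient into a "heavy" pool (enriched,
#' isotopically labeled DNA) and a "light" pool. Two rules are supported:
#' `density_threshold` assigns fractions with density strictly above the
#' threshold to the heavy pool (default cut 1.715 g/mL), and `top_k` takes
#' the `k` densest fractions. The rule used is recorded in every downstream
#' result for provenance.
#'
#' @param type `"density_threshold"` or `"top_k"`.
#' @param threshold Density cut in g/mL (for `density_threshold`).
#' @param k Number of heavy fractions (for `top_k`).
#' @return A `split_rule` list.
#' @export
split_rule <- function(type = c("density_threshold", "top_k"),
                       threshold = 1.715, k = NULL) {
  type <- match.arg(type)
  if (type == "density_threshold") {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      stop("threshold must be a single density in g/mL", call. = FALSE)
    structure(list(type = type, threshold = threshold), class = "split_rule")
  } else {
    if (is.null(k) || !is.numeric(k) || k < 1)
      stop("top_k rule needs k >= 1", call. = FALSE)
    structure(list(type = type, k = as.integer(k)), class = "split_rule")
  }
}

.rule_label <- function(rule) {
  if (rule$type == "density_threshold")
    sprintf("density_threshold(%.4f)", rule$threshold)
  else sprintf("top_k(%d)", rule$k)
}

# A "bottle" is a long data.frame with one row per (fraction, taxon):
# columns fraction_id, density_g_ml, taxon, reads (dna_ng optional).
.check_bottle <- function(bottle) {
  need <- c("fraction_id", "density_g_ml", "taxon", "reads")
  miss <- setdiff(need, names(bottle))
  if (length(miss))
    stop("bottle table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(bottle$reads < 0)) stop("read counts must be >= 0", call. = FALSE)
  dens <- tapply(bottle$density_g_ml, bottle$fraction_id, unique)
  if (any(lengths(dens) != 1L))
    stop("each fraction_id must have a single density", call. = FALSE)
  dens <- vapply(dens, identity, numeric(1))
  if (any(dens < 1.60 | dens > 1.80))
    stop("fraction densities must lie in [1.60, 1.80] g/mL", call. = FALSE)
  if (length(dens) < 2L || diff(range(dens)) < 0.01)
    stop("degenerate gradient: bottle must span >= 2 fractions over >= 0.01 g/mL",
         call. = FALSE)
  invisible(dens)
}

#' Partition gradient fractions into heavy and light pools
#'
#' @param bottle Long data.frame with columns `fraction_id`, `density_g_ml`,
#'   `taxon`, `reads` (one bottle's gradient).
#' @param rule A [split_rule()].
#' @return A `heavy_light_split` list with `heavy_ids`, `light_ids` and the
#'   rule applied. Errors if either side would be empty (degenerate split)
#'   or if fraction densities cannot be strictly ordered.
#' @examples
#' b <- data.frame(fraction_id = 1:5,
#'                 density_g_ml = c(1.69, 1.70, 1.71, 1.72, 1.73),
#'                 taxon = "t", reads = 10)
#' split_heavy_light(b, split_rule("density_threshold", 1.715))$heavy_ids
#' @export
split_heavy_light <- function(bottle, rule = split_rule()) {
  stopifnot(inherits(rule, "split_rule"))
  dens <- .check_bottle(bottle)
  if (anyDuplicated(dens))
    stop("degenerate split: fraction densities are not strictly ordered",
         call. = FALSE)
  ids <- names(dens)[order(dens)]
  dens <- sort(dens)
  heavy <- if (rule$type == "density_threshold") ids[dens > rule$threshold]
  else utils::tail(ids, rule$k)
  light <- setdiff(ids, heavy)
  if (length(heavy) == 0L || length(light) == 0L)
    stop("degenerate split: all fractions fall on one side (rule ",
         .rule_label(rule), ")", call. = FALSE)
  structure(list(heavy_ids = heavy, light_ids = light, rule = rule),
            class = "heavy_light_split")
}

# Pooled heavy/light read counts: taxon x c(heavy, light) matrix.
.pool_counts <- function(bottle, split) {
  side <- ifelse(bottle$fraction_id %in% split$heavy_ids, "heavy", "light")
  tab <- tapply(bottle$reads, list(bottle$taxon, factor(side, c("heavy", "light"))),
                sum, default = 0L)
  tab[is.na(tab)] <- 0L
  tab
}

.odds_from_cells <- function(a, b, c, d, pseudocount = NULL) {
  # NULL pseudocount = Haldane-Anscombe policy: add 0.5 only if any cell is 0
  p <- if (is.null(pseudocount)) {
    if (min(a, b, c, d) == 0) 0.5 else 0
  } else pseudocount
  if (p < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (p == 0 && min(a, b, c, d) == 0)
    stop("division-domain error: zero cell with pseudocount 0", call. = FALSE)
  ((a + p) / (b + p)) / ((c + p) / (d + p))
}

#' Heavy-vs-light odds ratio for one taxon
#'
#' Forms the 2x2 table (taxon vs all other taxa) x (heavy vs light pool),
#' summing reads over each side's fractions, and returns
#' `OR = ((a+p)/(b+p)) / ((c+p)/(d+p))` where `a` = taxon reads in the heavy
#' pool, `b` = other taxa in heavy, `c` = taxon in light, `d` = other in
#' light.
#'
#' @param taxon Taxon label.
#' @param split A `heavy_light_split` for this bottle.
#' @param bottle Long fraction table (see [split_heavy_light()]).
#' @param pseudocount `NULL` (default) applies the Haldane-Anscombe policy:
#'   0.5 added to all cells only when some cell is zero, raw counts
#'   otherwise. A numeric value is applied unconditionally; 0 with a zero
#'   cell is an error.
#' @return The odds ratio (positive, finite for positive pseudocount).
#' @export
taxon_odds <- function(taxon, split, bottle, pseudocount = NULL) {
  stopifnot(inherits(split, "heavy_light_split"))
  tab <- .pool_counts(bottle, split)
  if (!taxon %in% rownames(tab))
    stop("taxon '", taxon, "' absent from bottle counts", call. = FALSE)
  a <- tab[taxon, "heavy"]
  c_ <- tab[taxon, "light"]
  b <- sum(tab[, "heavy"]) - a
  d <- sum(tab[, "light"]) - c_
  .odds_from_cells(a, b, c_, d, pseudocount)
}

#' Ratio of odds ratios (RoOR) for one taxon in one labeled replicate
#'
#' The RoOR statistic compares a taxon's heavy-vs-light read odds in a
#' labeled bottle against the same odds in the unlabeled control bottle:
#' `RoOR = OR_labeled / OR_control`. RoOR > 1 indicates the taxon is more
#' enriched in the heavy pool of the labeled incubation than expected from
#' its buoyant density alone, i.e. isotope labeling.
#'
#' A minimum-read filter guards against calls driven by sparse counts. Two
#' scopes are available: `"per_side"` (default) requires the taxon to have
#' at least `min_reads` reads in the heavy pool and in the light pool, each
#' pooled over the labeled and control bottles; `"per_pool"` requires
#' `min_reads` in all four pools separately (heavy/light x labeled/control),
#' the strictest reading. A taxon is `called_labeled` only when RoOR > 1
#' and the filter passes.
#'
#' @param taxon Taxon label (must occur in at least one of the two bottles).
#' @param labeled_bottle,control_bottle Long fraction tables.
#' @param rule A [split_rule()] applied to both bottles.
#' @param pseudocount See [taxon_odds()].
#' @param min_reads Read filter threshold (default 5).
#' @param filter_scope `"per_side"` or `"per_pool"`.
#' @return An object of class `roor_result`: `taxon`, `or_labeled`,
#'   `or_control`, `roor`, the four pooled read counts, `passes_read_filter`,
#'   `called_labeled`, and the rule/filter provenance.
#' @export
roor <- function(taxon, labeled_bottle, control_bottle, rule = split_rule(),
                 pseudocount = NULL, min_reads = 5,
                 filter_scope = c("per_side", "per_pool")) {
  filter_scope <- match.arg(filter_scope)
  split_l <- split_heavy_light(labeled_bottle, rule)
  split_c <- split_heavy_light(control_bottle, rule)
  tab_l <- .pool_counts(labeled_bottle, split_l)
  tab_c <- .pool_counts(control_bottle, split_c)
  if (!taxon %in% union(rownames(tab_l), rownames(tab_c)))
    stop("taxon '", taxon, "' absent from both bottles", call. = FALSE)
  cell <- function(tab, side) if (taxon %in% rownames(tab)) tab[taxon, side] else 0
  a_l <- cell(tab_l, "heavy"); c_l <- cell(tab_l, "light")
  a_c <- cell(tab_c, "heavy"); c_c <- cell(tab_c, "light")
  or_l <- .odds_from_cells(a_l, sum(tab_l[, "heavy"]) - a_l,
                           c_l, sum(tab_l[, "light"]) - c_l, pseudocount)
  or_c <- .odds_from_cells(a_c, sum(tab_c[, "heavy"]) - a_c,
                           c_c, sum(tab_c[, "light"]) - c_c, pseudocount)
  passes <- if (filter_scope == "per_pool")
    min(a_l, c_l, a_c, c_c) >= min_reads
  else (a_l + a_c) >= min_reads && (c_l + c_c) >= min_reads
  val <- or_l / or_c
  structure(list(taxon = taxon, or_labeled = or_l, or_control = or_c,
                 roor = val,
                 reads = c(heavy_labeled = a_l, light_labeled = c_l,
                           heavy_control = a_c, light_control = c_c),
                 passes_read_filter = passes,
                 called_labeled = passes && val > 1,
                 rule = .rule_label(rule), min_reads = min_reads,
                 filter_scope = filter_scope),
            class = "roor_result")
}

#' @export
print.roor_result <- function(x, ...) {
  cat(sprintf("RoOR[%s] = %.3g (OR labeled %.3g / control %.3g)%s%s\n",
              x$taxon, x$roor, x$or_labeled, x$or_control,
              if (!x$passes_read_filter) " [fails read filter]" else "",
              if (x$called_labeled) " -> labeled" else ""))
  invisible(x)
}

#' RoOR for every taxon across labeled replicates
#'
#' @param labeled_bottles List of long fraction tables, one per labeled
#'   replicate bottle.
#' @param control_bottle Long fraction table of the control bottle.
#' @param rule,pseudocount,min_reads,filter_scope See [roor()].
#' @return Data.frame with one row per taxon x replicate.
#' @export
roor_table <- function(labeled_bottles, control_bottle, rule = split_rule(),
                       pseudocount = NULL, min_reads = 5,
                       filter_scope = "per_side") {
  if (is.data.frame(labeled_bottles)) labeled_bottles <- list(labeled_bottles)
  taxa <- sort(unique(c(unlist(lapply(labeled_bottles, function(b) b$taxon)),
                        control_bottle$taxon)))
  rows <- list()
  for (i in seq_along(labeled_bottles)) {
    for (tx in taxa) {
      r <- roor(tx, labeled_bottles[[i]], control_bottle, rule,
                pseudocount, min_reads, filter_scope)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, replicate = i, or_labeled = r$or_labeled,
        or_control = r$or_control, roor = r$roor,
        heavy_labeled = r$reads[["heavy_labeled"]],
        light_labeled = r$reads[["light_labeled"]],
        heavy_control = r$reads[["heavy_control"]],
        light_control = r$reads[["light_control"]],
        passes_read_filter = r$passes_read_filter,
        called_labeled = r$called_labeled, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rule") <- .rule_label(rule)
  attr(out, "filter") <- sprintf("min_reads=%d scope=%s", min_reads, filter_scope)
  out
}

#' Replicate-consensus labeling call
#'
#' A taxon is accepted as labeled when it is called in both bottles of a
#' duplicate design, or in at least two of three bottles of a triplicate
#' design.
#'
#' @param per_replicate Logical vector of per-replicate `called_labeled`
#'   flags, or a list of `roor_result`s.
#' @param design `"duplicates"` or `"triplicates"`.
#' @return Single logical consensus call.
#' @export
consensus_call <- function(per_replicate, design = c("duplicates", "triplicates")) {
  design <- match.arg(design)
  if (is.list(per_replicate))
    per_replicate <- vapply(per_replicate, function(r) {
      if (inherits(r, "roor_result")) r$called_labeled else as.logical(r)
    }, logical(1))
  n_needed <- if (design == "duplicates") 2L else 3L
  if (length(per_replicate) != n_needed)
    stop("design mismatch: ", design, " expects ", n_needed,
         " replicate calls, got ", length(per_replicate), call. = FALSE)
  if (design == "duplicates") all(per_replicate) else sum(per_replicate) >= 2L
}

#' Consensus calls for a whole RoOR table
#'
#' @param roor_df Output of [roor_table()].
#' @param design `"duplicates"` or `"triplicates"`.
#' @return Data.frame with one row per taxon: `n_called`, `consensus`.
#' @export
consensus_table <- function(roor_df, design = c("duplicates", "triplicates")) {
  design <- match.arg(design)
  out <- do.call(rbind, lapply(split(roor_df, roor_df$taxon), function(g) {
    g <- g[order(g$replicate), ]
    data.frame(taxon = g$taxon[1], n_called = sum(g$called_labeled),
               consensus = consensus_call(g$called_labeled, design),
               median_roor = stats::median(g$roor), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Relative abundance of the labeled community in the heavy pool
#'
#' Restricts the community to consensus-labeled taxa, computes their
#' relative abundances among heavy-pool reads, and folds taxa below
#' `min_rel_abundance` into an `"other"` row so the table mirrors the usual
#' "taxa above 1% of sequences" presentation. Abundances sum to 1 over shown
#' taxa plus `"other"`.
#'
#' @param labeled_taxa Character vector of consensus-labeled taxa (or a
#'   [consensus_table()] data.frame, from which `consensus == TRUE` rows are
#'   taken).
#' @param heavy_counts Named numeric vector of heavy-pool reads per taxon
#'   (labeled bottles pooled).
#' @param min_rel_abundance Display threshold in `[0, 1)`; default 0.01.
#' @return Data.frame `taxon`, `reads`, `rel_abundance`. Zero labeled taxa
#'   yields an empty table with a warning.
#' @export
labeled_community_table <- function(labeled_taxa, heavy_counts,
                                    min_rel_abundance = 0.01) {
  if (is.data.frame(labeled_taxa))
    labeled_taxa <- labeled_taxa$taxon[labeled_taxa$consensus]
  if (min_rel_abundance < 0 || min_rel_abundance >= 1)
    stop("min_rel_abundance must lie in [0, 1)", call. = FALSE)
  keep <- intersect(labeled_taxa, names(heavy_counts))
  if (length(keep) == 0L) {
    warning("no labeled taxa; returning empty community table")
    return(data.frame(taxon = character(0), reads = numeric(0),
                      rel_abundance = numeric(0)))
  }
  reads <- heavy_counts[keep]
  rel <- reads / sum(reads)
  small <- rel < min_rel_abundance
  out <- data.frame(taxon = names(rel)[!small], reads = as.numeric(reads[!small]),
                    rel_abundance = as.numeric(rel[!small]),
                    stringsAsFactors = FALSE)
  if (any(small))
    out <- rbind(out, data.frame(taxon = "other",
                                 reads = sum(reads[small]),
                                 rel_abundance = sum(rel[small])))
  out <- out[order(-out$rel_abundance), ]
  rownames(out) <- NULL
  out
}

#' Read a long-form DNA-SIP gradient table
#'
#' Expects tab-separated columns `bottle_id`, `treatment`, `replicate_role`,
#' `fraction_id`, `density_g_ml`, `dna_ng`, `taxon`, `reads`; lines starting
#' with `#` are treated as provenance comments.
#'
#' @param path File path.
#' @return Data.frame in the package's long gradient format.
#' @export
read_gradient_tsv <- function(path) {
  df <- read_provenance_table(path, sep = "\t")
  need <- c("bottle_id", "fraction_id", "density_g_ml", "taxon", "reads")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gradient table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

# Split a multi-bottle long table into per-bottle tables keyed by bottle_id.
split_bottles <- function(gradient_df) {
  split(gradient_df, gradient_df$bottle_id)
}

#' Heavy-pool read counts pooled over labeled bottles
#'
#' @param labeled_bottles List of long fraction tables.
#' @param rule A [split_rule()].
#' @return Named numeric vector of reads per taxon in the heavy pool.
#' @export
heavy_pool_counts <- function(labeled_bottles, rule = split_rule()) {
  if (is.data.frame(labeled_bottles)) labeled_bottles <- list(labeled_bottles)
  counts <- lapply(labeled_bottles, function(b) {
    tab <- .pool_counts(b, split_heavy_light(b, rule))
    stats::setNames(tab[, "heavy"], rownames(tab))
  })
  taxa <- sort(unique(unlist(lapply(counts, names))))
  out <- stats::setNames(numeric(length(taxa)), taxa)
  for (ct in counts) out[names(ct)] <- out[names(ct)] + ct
  out
}
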