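# Published study values used as inputs: the SurR site arrangements found
# upstream of the T. barophilus energy-metabolism clusters, and the
# strain x condition growth rates and qualitative growth classes. These
# are the reconstruction targets for the synthetic generator and the
# calibration inputs for the growth classifier.

#' Reported SurR site arrangements of the energy-metabolism clusters
#'
#' One row per binding site reported upstream of the first CDS of each
#' cluster: the variant motif string as matched on its strand, the
#' upstream distance (bases between the motif edge nearest the CDS and
#' the start codon), the matched orientation and the promoter window used
#' for reconstruction. Clusters in genomic report order; occurrence
#' counts per cluster are 4, 2, 1, 1, 3, 4, 2, 2.
#'
#' @return Data frame with columns `cluster`, `read_direction`,
#'   `window_len`, `variant`, `upstream_distance`, `orientation`.
#' @export
surr_site_arrangements <- function() {
  row <- function(cluster, dir, win, variant, dist, ori)
    data.frame(cluster = cluster, read_direction = dir, window_len = win,
               variant = variant, upstream_distance = dist,
               orientation = ori, stringsAsFactors = FALSE)
  rbind(
    row("Mrp-Mbh 1", "reverse", 300L, "ATTn3AAC", 21L, "forward"),
    row("Mrp-Mbh 1", "reverse", 300L, "GTAn3AACn5TTT", 119L, "forward"),
    row("Mrp-Mbh 1", "reverse", 300L, "GTTn3AATn5GTT", 139L, "reverse"),
    row("Mrp-Mbh 1", "reverse", 300L, "ATTn3AACn5GTT", 147L, "forward"),
    row("Mrp-Mbh 2", "reverse", 300L, "GTTn3AACn5GTT", 11L, "reverse"),
    row("Mrp-Mbh 2", "reverse", 300L, "GTTn3AACn5GTT", 96L, "reverse"),
    row("Mrp-Mbh-Codh", "reverse", 300L, "GTTn3ACC", 2L, "forward"),
    row("SHII", "forward", 200L, "GTTn3AACn5GTT", 67L, "forward"),
    row("SHI", "reverse", 320L, "GTTn3AAGn5GTT", 94L, "reverse"),
    row("SHI", "reverse", 320L, "GTTn3ATGn5GTT", 116L, "forward"),
    row("SHI", "reverse", 320L, "GTTn3AAAn5GTT", 257L, "forward"),
    row("Mrp-Mbs", "reverse", 300L, "GTTn2AACn6GTT", 17L, "forward"),
    row("Mrp-Mbs", "reverse", 300L, "GTTn3AAT", 53L, "forward"),
    row("Mrp-Mbs", "reverse", 300L, "GTTn3AACn5GTT", 87L, "reverse"),
    row("Mrp-Mbs", "reverse", 300L, "GTTn3AACn5GTT", 95L, "forward"),
    row("SurR", "reverse", 300L, "GTTn3AACn5GTT", 52L, "reverse"),
    row("SurR", "reverse", 300L, "GTTn3AAC", 108L, "forward"),
    row("Pdo/Glutaredoxin", "forward", 200L, "GTTn3AAC", 31L, "forward"),
    row("Pdo/Glutaredoxin", "forward", 200L, "GTTn3AACn5GTT", 80L, "reverse"))
}

#' Promoter plans for the reported site arrangements
#'
#' One [promoter_plan()] per cluster of [surr_site_arrangements()], with
#' per-cluster seeds derived from `base_seed`.
#'
#' @param arrangements Site table (default [surr_site_arrangements()]).
#' @param base_seed Base RNG seed; cluster i uses `base_seed + 97 * i`.
#' @return Named list of plans in table order.
#' @export
reported_promoter_plans <- function(arrangements = surr_site_arrangements(),
                                    base_seed = 1L) {
  names_ord <- unique(arrangements$cluster)
  plans <- lapply(seq_along(names_ord), function(i) {
    sub <- arrangements[arrangements$cluster == names_ord[[i]], , drop = FALSE]
    promoter_plan(names_ord[[i]],
                  sub[c("variant", "upstream_distance", "orientation")],
                  window_len = sub$window_len[[1]],
                  background_seed = base_seed + 97L * i)
  })
  stats::setNames(plans, names_ord)
}

#' Reported specific growth rates by strain and condition
#'
#' The published strain x pressure x sulfur growth-rate grid (h^-1) from
#' the two batch-culture experiment series: the membrane-complex series
#' (parental D517 with Dmbh and Dmbs at 0.1 and 40 MPa) and the surR
#' series (parental D517 with DsurR at 0.1, 40 and 70 MPa).
#'
#' @return Data frame `experiment`, `strain`, `pressure_MPa`, `sulfur`,
#'   `mu` with `mu_mean` duplicated for [classify_grid()] compatibility.
#' @export
reported_growth_rates <- function() {
  g <- function(exp, strain, p, s, mu)
    data.frame(experiment = exp, strain = strain, pressure_MPa = p,
               sulfur = s, mu = mu, stringsAsFactors = FALSE)
  out <- rbind(
    g("membrane", "D517", 0.1, TRUE, 0.45),
    g("membrane", "D517", 0.1, FALSE, 0.38),
    g("membrane", "D517", 40, TRUE, 0.51),
    g("membrane", "D517", 40, FALSE, 0.45),
    g("membrane", "Dmbh", 0.1, TRUE, 0.45),
    g("membrane", "Dmbh", 0.1, FALSE, 0.023),
    g("membrane", "Dmbh", 40, TRUE, 0.19),
    g("membrane", "Dmbh", 40, FALSE, 0.21),
    g("membrane", "Dmbs", 0.1, TRUE, 0.065),
    g("membrane", "Dmbs", 0.1, FALSE, 0.032),
    g("membrane", "Dmbs", 40, TRUE, 0.10),
    g("membrane", "Dmbs", 40, FALSE, 0.20),
    g("surr", "D517", 0.1, TRUE, 0.43),
    g("surr", "D517", 0.1, FALSE, 0.36),
    g("surr", "D517", 40, TRUE, 0.58),
    g("surr", "D517", 40, FALSE, 0.41),
    g("surr", "D517", 70, TRUE, 0.44),
    g("surr", "D517", 70, FALSE, 0.37),
    g("surr", "DsurR", 0.1, TRUE, 0.21),
    g("surr", "DsurR", 0.1, FALSE, 0.0041),
    g("surr", "DsurR", 40, TRUE, 0.56),
    g("surr", "DsurR", 40, FALSE, 0.10),
    g("surr", "DsurR", 70, TRUE, 0.38),
    g("surr", "DsurR", 70, FALSE, 0.13))
  out$mu_mean <- out$mu
  out
}

#' Reported qualitative growth classes
#'
#' The published summary classes for the T. barophilus mutants relative
#' to the parental strain, per pressure and sulfur regime.
#'
#' @return Data frame `strain`, `pressure_MPa`, `sulfur`, `class`.
#' @export
reported_growth_classes <- function() {
  cl <- function(strain, p, s, class)
    data.frame(strain = strain, pressure_MPa = p, sulfur = s, class = class,
               stringsAsFactors = FALSE)
  rbind(
    cl("Dmbh", 0.1, TRUE, "+++"), cl("Dmbh", 0.1, FALSE, "-"),
    cl("Dmbh", 40, TRUE, "++"), cl("Dmbh", 40, FALSE, "+"),
    cl("Dmbs", 0.1, TRUE, "++"), cl("Dmbs", 0.1, FALSE, "-"),
    cl("Dmbs", 40, TRUE, "++"), cl("Dmbs", 40, FALSE, "+"),
    cl("DsurR", 0.1, TRUE, "++"), cl("DsurR", 0.1, FALSE, "-"),
    cl("DsurR", 40, TRUE, "++"), cl("DsurR", 40, FALSE, "+"),
    cl("DsurR", 70, TRUE, "++"), cl("DsurR", 70, FALSE, "+"))
}

#' Calibrate the growth classifier against the reported classes
#'
#' Applies the default (or overridden) [classify_growth()] rule to the
#' reported rate grid, pairing each mutant with its series' parental
#' rate under the same condition, and compares against the reported
#' classes. Final-density ratios are not published, so 1 is assumed; the
#' comparison column records where the rule and the published class
#' disagree.
#'
#' @param rates Rate grid (default [reported_growth_rates()]).
#' @param classes Reported classes (default [reported_growth_classes()]).
#' @param ... Threshold overrides for [classify_growth()].
#' @return Data frame with `predicted_class`, `reported_class`, `agree`.
#' @export
calibrate_growth_classes <- function(rates = reported_growth_rates(),
                                     classes = reported_growth_classes(),
                                     ...) {
  preds <- lapply(split(rates, rates$experiment), function(sub)
    classify_grid(sub, "D517", ...))
  pred <- do.call(rbind, preds)
  out <- merge(pred, classes, by = c("strain", "pressure_MPa", "sulfur"))
  names(out)[names(out) == "growth_class"] <- "predicted_class"
  names(out)[names(out) == "class"] <- "reported_class"
  out$agree <- out$predicted_class == out$reported_class
  out <- out[order(out$strain, out$pressure_MPa, !out$sulfur), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[c("strain", "pressure_MPa", "sulfur", "mu_mean", "predicted_class",
        "reported_class", "agree")]
}
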