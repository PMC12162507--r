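# Relative expression from qPCR cycle-threshold tables.
#
# Classic 2^-ddCt quantification at 100% amplification efficiency: a
# gene's expression relative to a reference gene in one group is
# 2^-(Ct_gene - Ct_ref); the fold change between two groups is
# 2^-(dCt_num - dCt_den). Technical replicates are averaged to one Ct per
# biological replicate; per-replicate ratios are combined by geometric
# mean, since dCt is the natural additive scale. Amplification efficiency
# is exposed as a configuration scalar (fold base = 1 + E) for
# sensitivity checks.

ct_group_cols <- c("strain", "pressure_MPa", "sulfur", "sulfur_conc_g_per_L")

#' Read a Ct table
#'
#' Tab-separated with columns `gene`, `strain`, `pressure_MPa`, `sulfur`,
#' `sulfur_conc_g_per_L`, `bio_replicate`, `tech_replicate`, `ct`.
#'
#' @param path TSV path.
#' @return Data frame of Ct records.
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_records(df)
  df
}

validate_ct_records <- function(records) {
  need <- c("gene", "strain", "pressure_MPa", "sulfur", "sulfur_conc_g_per_L",
            "bio_replicate", "tech_replicate", "ct")
  missing_cols <- setdiff(need, names(records))
  assert_that(length(missing_cols) == 0L, "Ct table lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  assert_that(all(is.finite(records$ct)), "non-finite Ct value(s)")
  invisible(records)
}

# Restrict records to one group (a named list/one-row df over the group
# columns; NULL components are wildcards).
filter_group <- function(records, group) {
  keep <- rep(TRUE, nrow(records))
  for (col in intersect(names(group), c(ct_group_cols, "gene"))) {
    val <- group[[col]]
    if (is.null(val) || (length(val) == 1L && is.na(val))) next
    keep <- keep & (records[[col]] == val)
  }
  records[keep, , drop = FALSE]
}

#' Rank candidate reference genes by Ct stability
#'
#' For each candidate, computes the mean Ct of every strain x condition
#' group (biological and technical replicates averaged) and ranks
#' candidates by the standard deviation of those group means, most stable
#' first. Ties are broken alphabetically and flagged.
#'
#' @param records Ct table (see [read_ct_tsv()]).
#' @param candidate_genes Character vector of candidate reference genes;
#'   each must be observed in at least two groups.
#' @return Data frame `gene`, `ct_sd`, `n_groups`, `tied`, sorted
#'   ascending by `ct_sd`.
#' @export
reference_stability <- function(records, candidate_genes) {
  validate_ct_records(records)
  absent <- setdiff(candidate_genes, unique(records$gene))
  assert_that(length(absent) == 0L, "candidate gene(s) absent from records: ",
              paste(absent, collapse = ", "))
  rows <- lapply(candidate_genes, function(g) {
    sub <- records[records$gene == g, , drop = FALSE]
    key <- interaction(sub[ct_group_cols], drop = TRUE)
    group_means <- vapply(split(sub$ct, key), mean, 1)
    assert_that(length(group_means) >= 2L, "candidate '", g,
                "' observed in fewer than 2 groups")
    data.frame(gene = g, ct_sd = stats::sd(group_means),
               n_groups = length(group_means), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ct_sd, out$gene), , drop = FALSE]
  out$tied <- duplicated(out$ct_sd) | duplicated(out$ct_sd, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

# Per-biological-replicate dCt (gene minus reference, technical replicates
# averaged first). Replicates missing the reference are dropped with a
# warning; missing the gene likewise.
delta_ct_by_bio <- function(records, gene, reference_gene, group) {
  sub <- filter_group(records, group)
  assert_that(nrow(sub) > 0, "no Ct records for the requested group")
  gsub_ <- sub[sub$gene == gene, , drop = FALSE]
  rsub <- sub[sub$gene == reference_gene, , drop = FALSE]
  assert_that(nrow(gsub_) > 0, "gene '", gene, "' not measured in the group")
  assert_that(nrow(rsub) > 0, "reference '", reference_gene,
              "' not measured in the group")
  g_ct <- vapply(split(gsub_$ct, gsub_$bio_replicate), mean, 1)
  r_ct <- vapply(split(rsub$ct, rsub$bio_replicate), mean, 1)
  common <- intersect(names(g_ct), names(r_ct))
  dropped <- setdiff(union(names(g_ct), names(r_ct)), common)
  if (length(dropped))
    warning("dropping biological replicate(s) without paired ", gene, "/",
            reference_gene, " measurements: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  assert_that(length(common) > 0, "no biological replicate has both '",
              gene, "' and '", reference_gene, "'")
  g_ct[common] - r_ct[common]
}

#' Expression ratio of a gene relative to a reference gene
#'
#' Within one strain x condition group: technical replicates are averaged
#' to one Ct per biological replicate; the reported ratio is the geometric
#' mean over biological replicates of `base^-(Ct_gene - Ct_ref)`. Two
#' dispersion figures are carried: the SD of the per-replicate ratios
#' (`sd`) and the SD of the per-replicate dCt values (`sd_log`, on the
#' log-base scale).
#'
#' @param records Ct table.
#' @param gene Target gene.
#' @param reference_gene Reference (housekeeping) gene.
#' @param group Named list selecting the group, e.g.
#'   `list(strain = "D517", pressure_MPa = 0.1, sulfur = TRUE)`.
#' @param efficiency Amplification efficiency E in [0, 1]; the fold base
#'   is `1 + E` (default 1, the classic base-2 method).
#' @return One-row data frame `gene`, `ratio`, `sd`, `sd_log`, `n_bio`.
#' @export
expression_ratio <- function(records, gene, reference_gene, group,
                             efficiency = 1) {
  validate_ct_records(records)
  base <- 1 + efficiency
  dct <- delta_ct_by_bio(records, gene, reference_gene, group)
  ratios <- base^(-dct)
  data.frame(gene = gene, ratio = exp(mean(log(ratios))),
             sd = if (length(ratios) > 1L) stats::sd(ratios) else 0,
             sd_log = if (length(dct) > 1L) stats::sd(dct) else 0,
             n_bio = length(dct), stringsAsFactors = FALSE)
}

#' ddCt fold change of a gene between two groups
#'
#' `fold = base^-(mean dCt_num - mean dCt_den)` with dCt = Ct_gene -
#' Ct_ref per biological replicate. The direction label uses a
#' configurable unchanged band on the fold scale.
#'
#' @inheritParams expression_ratio
#' @param group_num,group_den Numerator and denominator groups (named
#'   lists as in [expression_ratio()]).
#' @param unchanged_band Fold interval reported as `"unchanged"`
#'   (default `c(0.5, 2)`).
#' @return One-row data frame `gene`, `fold`, `ddct`, `direction`,
#'   `n_bio_num`, `n_bio_den`.
#' @export
ddct_fold <- function(records, gene, reference_gene, group_num, group_den,
                      efficiency = 1, unchanged_band = c(0.5, 2)) {
  validate_ct_records(records)
  base <- 1 + efficiency
  dct_num <- delta_ct_by_bio(records, gene, reference_gene, group_num)
  dct_den <- delta_ct_by_bio(records, gene, reference_gene, group_den)
  ddct <- mean(dct_num) - mean(dct_den)
  fold <- base^(-ddct)
  direction <- if (fold >= unchanged_band[[1]] && fold <= unchanged_band[[2]])
    "unchanged" else if (fold > 1) "up" else "down"
  data.frame(gene = gene, fold = fold, ddct = ddct, direction = direction,
             n_bio_num = length(dct_num), n_bio_den = length(dct_den),
             stringsAsFactors = FALSE)
}

#' Fold-change table for a sulfur-induction (before/after) comparison
#'
#' Per-gene [ddct_fold()] of the post-addition group against the
#' pre-addition group. Genes missing from either group yield a row of NA
#' markers and the run continues.
#'
#' @inheritParams ddct_fold
#' @param genes Character vector of target genes.
#' @param pre_group,post_group Groups before and after sulfur addition.
#' @return Data frame with one row per gene.
#' @export
induction_response <- function(records, genes, reference_gene, pre_group,
                               post_group, efficiency = 1,
                               unchanged_band = c(0.5, 2)) {
  rows <- lapply(genes, function(g) {
    res <- tryCatch(
      ddct_fold(records, g, reference_gene, post_group, pre_group,
                efficiency, unchanged_band),
      error = function(e) {
        warning("gene '", g, "': ", conditionMessage(e), call. = FALSE)
        data.frame(gene = g, fold = NA_real_, ddct = NA_real_,
                   direction = NA_character_, n_bio_num = NA_integer_,
                   n_bio_den = NA_integer_, stringsAsFactors = FALSE)
      })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
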