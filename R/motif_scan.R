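# Exhaustive scanning of regions and genomes for block-and-spacer motifs.
#
# Every offset x realized-spacer combination x orientation is tested; a
# candidate is a hit when its edit cost (block mismatches + absolute spacer
# deviations) is within the pattern's budget. The same genomic span and
# spacer realization matched in both orientations is one hit: an exact
# match in both (possible only for structurally palindromic patterns such
# as the short SurR site) is labelled forward_and_reverse, otherwise the
# cheaper orientation is reported, ties going to forward.

# Vectorized candidate enumeration for one pattern over one sequence.
# Returns a data.frame of candidates at cost <= budget, genome frame.
scan_candidates <- function(seqc, pattern) {
  L <- length(seqc)
  orientations <- if (is_self_rc(pattern)) "forward" else c("forward", "reverse")
  out <- list()
  for (ori in orientations) {
    gpat <- if (ori == "forward") pattern else revcomp_pattern(pattern)
    reals <- spacer_realizations(gpat$spacer_lens, gpat$spacer_flex)
    for (i in seq_len(nrow(reals))) {
      r <- reals[i, ]
      blens <- nchar(gpat$blocks)
      span <- sum(blens) + sum(r)
      if (span > L) next
      offsets <- 0:(L - span)
      mm <- integer(length(offsets))
      rel <- 0L
      for (j in seq_along(gpat$blocks)) {
        bc <- strsplit(gpat$blocks[[j]], "")[[1]]
        for (k in seq_along(bc))
          mm <- mm + (seqc[offsets + rel + k] != bc[[k]])
        rel <- rel + blens[[j]] + if (j <= length(r)) r[[j]] else 0L
      }
      dev <- sum(abs(r - gpat$spacer_lens))
      cost <- mm + dev
      keep <- which(cost <= pattern$edit_budget)
      if (!length(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        pattern_name = pattern$name, orientation = ori,
        region_offset = offsets[keep], span = span,
        genome_spacers = paste(r, collapse = ","),
        mismatch_count = as.integer(mm[keep]), spacer_dev = as.integer(dev),
        edit_cost = as.integer(cost[keep]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

empty_candidates <- function() {
  data.frame(pattern_name = character(), orientation = character(),
             region_offset = integer(), span = integer(),
             genome_spacers = character(), mismatch_count = integer(),
             spacer_dev = integer(), edit_cost = integer(),
             stringsAsFactors = FALSE)
}

# Merge per-orientation candidates that describe the same genomic placement
# (same pattern, offset and genome-frame spacer realization) into single
# hits with a strand label.
merge_orientations <- function(cand, pattern) {
  if (!nrow(cand)) return(cbind(cand, strand_label = character()))
  key <- paste(cand$region_offset, cand$genome_spacers, sep = "|")
  rows <- lapply(split(seq_len(nrow(cand)), key), function(idx) {
    sub <- cand[idx, , drop = FALSE]
    if (is_self_rc(pattern)) {
      # forward and reverse readings coincide position-by-position
      hit <- sub[1L, , drop = FALSE]
      hit$strand_label <- if (hit$edit_cost == 0L) "forward_and_reverse"
                          else "forward"
    } else if (nrow(sub) == 2L) {
      cf <- sub$edit_cost[sub$orientation == "forward"]
      cr <- sub$edit_cost[sub$orientation == "reverse"]
      if (cf == 0L && cr == 0L) {
        hit <- sub[sub$orientation == "forward", , drop = FALSE]
        hit$strand_label <- "forward_and_reverse"
      } else if (cf <= cr) {
        hit <- sub[sub$orientation == "forward", , drop = FALSE]
        hit$strand_label <- "forward"
      } else {
        hit <- sub[sub$orientation == "reverse", , drop = FALSE]
        hit$strand_label <- "reverse"
      }
    } else {
      hit <- sub
      hit$strand_label <- sub$orientation
    }
    hit
  })
  do.call(rbind, rows)
}

# Genome-frame 0-based block start offsets and lengths of a hit.
hit_block_geometry <- function(hit, patterns) {
  pattern <- patterns[[hit$pattern_name]]
  gpat <- if (hit$strand_label == "reverse") revcomp_pattern(pattern) else pattern
  r <- as.integer(strsplit(hit$genome_spacers, ",")[[1]])
  blens <- nchar(gpat$blocks)
  starts <- integer(length(blens))
  rel <- 0L
  for (j in seq_along(blens)) {
    starts[[j]] <- hit$region_offset + rel
    rel <- rel + blens[[j]] + if (j <= length(r)) r[[j]] else 0L
  }
  list(starts = starts, lens = blens)
}

#' Scan a region for motif hits
#'
#' Tests every offset, spacer realization and orientation of each pattern
#' against the region, deduplicates placements matched in both
#' orientations, collapses alternative spacer realizations of one pattern
#' sharing an endpoint to the minimal-cost alignment (a single physical
#' occurrence), optionally suppresses short hits embedded in long
#' hits (see [resolve_nesting()]) and computes each hit's upstream
#' distance from the region geometry (the region's last base abuts the
#' start codon).
#'
#' @param region A `promoter_region` from [extract_upstream()], or a plain
#'   DNA string (then treated as a forward-strand sequence whose end abuts
#'   the start codon for the purpose of upstream distances).
#' @param patterns Named list of [compile_pattern()] results
#'   (default [surr_patterns()]).
#' @param params List: `nesting` (default `TRUE`) applies
#'   [resolve_nesting()].
#' @return Data frame of hits sorted by `upstream_distance`, with 0-based
#'   `region_offset`, 1-based inclusive `genome_start`/`genome_end`,
#'   `strand_label`, `mismatch_count`, `spacer_devs` (signed, pattern
#'   frame), `edit_cost`, `exact`, `annotation` and block geometry columns.
#' @export
scan_region <- function(region, patterns = surr_patterns(), params = list()) {
  seq <- if (inherits(region, "promoter_region")) region$sequence else region
  assert_that(is.character(seq) && length(seq) == 1L && nzchar(seq),
              "region must be non-empty")
  seqc <- strsplit(toupper(seq), "")[[1]]
  L <- length(seqc)
  hits <- do.call(rbind, lapply(patterns, function(p)
    merge_orientations(scan_candidates(seqc, p), p)))
  if (is.null(hits) || !nrow(hits)) return(empty_hits())
  rownames(hits) <- NULL
  hits <- collapse_alignments(hits)
  hits$n_blocks <- vapply(hits$pattern_name, function(nm)
    length(patterns[[nm]]$blocks), 1L)
  geo <- lapply(seq_len(nrow(hits)), function(i)
    hit_block_geometry(hits[i, ], patterns))
  hits$block_starts <- vapply(geo, function(g) paste(g$starts, collapse = ","), "")
  hits$block_lens <- vapply(geo, function(g) paste(g$lens, collapse = ","), "")
  hits$upstream_distance <- L - hits$region_offset - hits$span
  hits$exact <- hits$edit_cost == 0L
  ann <- annotate_hits(hits, seqc, patterns)
  hits$pattern_spacers <- ann$pattern_spacers
  hits$spacer_devs <- ann$spacer_devs
  hits$motif <- ann$motif
  hits$annotation <- ann$annotation
  if (isTRUE(params$nesting %||% TRUE)) hits <- resolve_nesting(hits)
  gsp <- if (inherits(region, "promoter_region")) {
    t(vapply(seq_len(nrow(hits)), function(i)
      region_span_to_genome(region, hits$region_offset[[i]], hits$span[[i]]),
      integer(2)))
  } else {
    cbind(hits$region_offset + 1L, hits$region_offset + hits$span)
  }
  hits$genome_start <- as.integer(gsp[, 1])
  hits$genome_end <- as.integer(gsp[, 2])
  hits <- hits[order(hits$upstream_distance, hits$region_offset,
                     hits$pattern_name), , drop = FALSE]
  rownames(hits) <- NULL
  hits$orientation <- NULL
  hits
}

# Alternative spacer realizations of one pattern that share an endpoint
# are alternative alignments of the same physical occurrence, not
# distinct sites: alignments of the same pattern sharing a start or an
# end are grouped (transitively) and the group's minimal-cost alignment
# is kept, ties broken toward fewer block mismatches (a spacer shift that
# preserves every block contact is the more faithful reading of a site,
# which is also how the published variant annotations read). Grouping by
# either endpoint keeps the rule symmetric under reverse complementation.
collapse_alignments <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (pat in unique(hits$pattern_name)) {
    sub <- hits[hits$pattern_name == pat, , drop = FALSE]
    n <- nrow(sub)
    starts <- sub$region_offset
    ends <- sub$region_offset + sub$span
    comp <- seq_len(n)
    if (n > 1L) repeat {
      changed <- FALSE
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (comp[[i]] != comp[[j]] &&
            (starts[[i]] == starts[[j]] || ends[[i]] == ends[[j]])) {
          comp[comp == comp[[j]]] <- comp[[i]]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cid in unique(comp)) {
      grp <- sub[comp == cid, , drop = FALSE]
      grp <- grp[order(grp$edit_cost, grp$mismatch_count,
                       grp$genome_spacers), , drop = FALSE]
      out[[length(out) + 1L]] <- grp[1L, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(pattern_name = character(), region_offset = integer(),
             span = integer(), genome_spacers = character(),
             mismatch_count = integer(), spacer_dev = integer(),
             edit_cost = integer(), strand_label = character(),
             n_blocks = integer(), block_starts = character(),
             block_lens = character(), upstream_distance = integer(),
             exact = logical(), pattern_spacers = character(),
             spacer_devs = character(), motif = character(),
             annotation = character(), genome_start = integer(),
             genome_end = integer(), stringsAsFactors = FALSE)
}

# Pattern-frame rendering data for each hit: realized spacers, signed
# deviations, matched-block motif string and the full annotation.
annotate_hits <- function(hits, seqc, patterns) {
  n <- nrow(hits)
  pattern_spacers <- spacer_devs <- motif <- annotation <- character(n)
  for (i in seq_len(n)) {
    h <- hits[i, ]
    pattern <- patterns[[h$pattern_name]]
    geo <- hit_block_geometry(h, patterns)
    obs <- vapply(seq_along(geo$starts), function(j)
      paste(seqc[(geo$starts[[j]] + 1L):(geo$starts[[j]] + geo$lens[[j]])],
            collapse = ""), "")
    gsp <- as.integer(strsplit(h$genome_spacers, ",")[[1]])
    if (h$strand_label == "reverse") {
      pf_blocks <- rev(vapply(obs, reverse_complement, ""))
      pf_spacers <- rev(gsp)
    } else {
      pf_blocks <- obs
      pf_spacers <- gsp
    }
    devs <- pf_spacers - pattern$spacer_lens
    pattern_spacers[[i]] <- paste(pf_spacers, collapse = ",")
    spacer_devs[[i]] <- paste(devs, collapse = ",")
    motif[[i]] <- render_pattern_string(pf_blocks, pf_spacers)
    prefix <- paste0(toupper(substr(pattern$name, 1, 1)),
                     substr(pattern$name, 2, nchar(pattern$name)))
    annotation[[i]] <- if (h$edit_cost == 0L) prefix else
      sprintf("%s with mutation%s: %s", prefix,
              if (h$mismatch_count > 1L) "s" else "", motif[[i]])
  }
  list(pattern_spacers = pattern_spacers, spacer_devs = spacer_devs,
       motif = motif, annotation = annotation)
}

#' Render a hit's report annotation
#'
#' Rebuilds the report string for one hit row: the pattern name
#' (capitalised) for an exact hit, else `"<Name> with mutation(s): <motif>"`
#' with blocks printed as matched (substituted bases included) and spacers
#' as `nK` with realized lengths.
#'
#' @param hit One row of a [scan_region()] hit table.
#' @return A string such as `"Long with mutation: GTTn3AATn5GTT"`.
#' @export
render_annotation <- function(hit) {
  if (is.data.frame(hit)) {
    assert_that(nrow(hit) == 1L, "render_annotation expects a single hit")
    hit <- as.list(hit)
  }
  hit$annotation
}

#' Suppress short hits embedded in long hits
#'
#' The canonical long pattern begins with a full short-pattern instance, so
#' every long occurrence would otherwise be double-counted as an additional
#' short occurrence. A short hit is suppressed when its span lies entirely
#' within a retained long hit and its two blocks coincide with two
#' consecutive blocks of that long hit (the embedded prefix in the hit's
#' own orientation); all other hits are retained.
#'
#' @param hits Hit table from one region (see [scan_region()]).
#' @return The hit table with embedded short hits removed.
#' @export
resolve_nesting <- function(hits) {
  if (!nrow(hits)) return(hits)
  longs <- hits[hits$n_blocks >= 3L, , drop = FALSE]
  if (!nrow(longs)) return(hits)
  long_geo <- lapply(seq_len(nrow(longs)), function(i) {
    s <- as.integer(strsplit(longs$block_starts[[i]], ",")[[1]])
    l <- as.integer(strsplit(longs$block_lens[[i]], ",")[[1]])
    list(start = longs$region_offset[[i]],
         end = longs$region_offset[[i]] + longs$span[[i]] - 1L,
         pairs = paste(s, l, sep = ":"))
  })
  drop <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (hits$n_blocks[[i]] != 2L) next
    s <- as.integer(strsplit(hits$block_starts[[i]], ",")[[1]])
    l <- as.integer(strsplit(hits$block_lens[[i]], ",")[[1]])
    pairs <- paste(s, l, sep = ":")
    h_start <- hits$region_offset[[i]]
    h_end <- h_start + hits$span[[i]] - 1L
    for (g in long_geo) {
      if (h_start < g$start || h_end > g$end) next
      idx <- match(pairs, g$pairs)
      if (anyNA(idx)) next
      if (abs(idx[[2]] - idx[[1]]) == 1L) { drop[[i]] <- TRUE; break }
    }
  }
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Expected chance hits in a window of length L under a uniform i.i.d.
# background, Poisson approximation; used only to flag suspiciously busy
# regions, never to change counts.
expected_chance_hits <- function(patterns, L) {
  lambda <- 0
  for (pattern in patterns) {
    n_ori <- if (is_self_rc(pattern)) 1L else 2L
    reals <- spacer_realizations(pattern$spacer_lens, pattern$spacer_flex)
    B <- sum(nchar(pattern$blocks))
    for (i in seq_len(nrow(reals))) {
      r <- reals[i, ]
      dev <- sum(abs(r - pattern$spacer_lens))
      m <- pattern$edit_budget - dev
      if (m < 0) next
      span <- B + sum(r)
      n_off <- max(0L, L - span + 1L)
      p <- sum(choose(B, 0:m) * 3^(0:m)) / 4^B
      lambda <- lambda + n_ori * n_off * p
    }
  }
  lambda
}

#' Promoter scan report across gene clusters
#'
#' Extracts the upstream region of each cluster, scans it, and assembles a
#' long-format report with one row per hit (clusters without hits keep one
#' row with an occurrence count of zero). Regions whose hit count exceeds
#' the 99th percentile of the Poisson chance-hit background are flagged
#' (`background_flag`); flags never alter counts, they mark windows where
#' unconstrained scanning at these budgets is expected to be noisy.
#'
#' @param genome [genome_record()] or named list of them.
#' @param features Feature table from [read_features()].
#' @param clusters Cluster definitions from [read_clusters()].
#' @param patterns Pattern set (default [surr_patterns()]).
#' @param params List: `window_len` (default 300), `nesting` (default
#'   `TRUE`), `flag_quantile` (default 0.99).
#' @return A `scan_report` data frame with columns `cluster`,
#'   `first_cds_locus`, `read_direction`, `occurrence_count`,
#'   `upstream_distance`, `annotation`, `strand`, `edit_cost`,
#'   `genome_start`, `genome_end`, `truncated`, `background_flag`.
#' @export
promoter_report <- function(genome, features, clusters,
                            patterns = surr_patterns(), params = list()) {
  window_len <- params$window_len %||% 300L
  missing_loci <- setdiff(clusters$first_cds_locus, c(
    features$locus_tag, names(attr(features, "alias_map") %||% character())))
  assert_that(length(missing_loci) == 0L,
              "unresolvable cluster locus/loci: ",
              paste(missing_loci, collapse = ", "))
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    region <- extract_upstream(genome, features, cl, window_len = window_len)
    hits <- scan_region(region, patterns, params)
    lambda <- expected_chance_hits(patterns, nchar(region$sequence))
    flag <- nrow(hits) > stats::qpois(params$flag_quantile %||% 0.99, lambda)
    if (!nrow(hits))
      return(data.frame(cluster = cl$name,
                        first_cds_locus = region$first_cds_locus,
                        read_direction = cl$read_direction,
                        occurrence_count = 0L,
                        upstream_distance = NA_integer_,
                        annotation = NA_character_, strand = NA_character_,
                        edit_cost = NA_integer_, genome_start = NA_integer_,
                        genome_end = NA_integer_,
                        truncated = region$truncated,
                        background_flag = flag, stringsAsFactors = FALSE))
    data.frame(cluster = cl$name, first_cds_locus = region$first_cds_locus,
               read_direction = cl$read_direction,
               occurrence_count = nrow(hits),
               upstream_distance = hits$upstream_distance,
               annotation = hits$annotation, strand = hits$strand_label,
               edit_cost = hits$edit_cost, genome_start = hits$genome_start,
               genome_end = hits$genome_end, truncated = region$truncated,
               background_flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scan_report", class(out))
  out
}

#' Write a promoter scan report as TSV
#'
#' @param report A [promoter_report()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genome-wide motif scan as a BED6 track
#'
#' Scans each contig in both orientations and emits every hit as one BED6
#' line: 0-based half-open coordinates, score = edit budget minus edit cost
#' (higher is a better match), strand `+`/`-` from the label with
#' forward_and_reverse emitted as `.`. Deterministic coordinate ordering.
#' Nesting suppression is off by default so the track carries every raw
#' hit.
#'
#' @param genome [genome_record()] or named list of them.
#' @param patterns Pattern set.
#' @param params List; `nesting` defaults to `FALSE` here.
#' @return Data frame with BED6 columns `chrom`, `chromStart`, `chromEnd`,
#'   `name`, `score`, `strand`.
#' @export
genome_scan <- function(genome, patterns = surr_patterns(), params = list()) {
  if (inherits(genome, "genome_record")) genome <- list(genome)
  params$nesting <- params$nesting %||% FALSE
  tracks <- lapply(genome, function(g) {
    hits <- scan_region(g$sequence, patterns, params)
    if (!nrow(hits))
      return(data.frame(chrom = character(), chromStart = integer(),
                        chromEnd = integer(), name = character(),
                        score = integer(), strand = character(),
                        stringsAsFactors = FALSE))
    budgets <- vapply(hits$pattern_name, function(nm)
      patterns[[nm]]$edit_budget, 1L)
    data.frame(chrom = g$id, chromStart = hits$genome_start - 1L,
               chromEnd = hits$genome_end,
               name = gsub("[ :]+", "_", hits$annotation),
               score = as.integer(budgets - hits$edit_cost),
               strand = c(forward = "+", reverse = "-",
                          forward_and_reverse = ".")[hits$strand_label],
               stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, tracks)
  bed <- bed[order(bed$chrom, bed$chromStart, bed$chromEnd, bed$name), ,
             drop = FALSE]
  rownames(bed) <- NULL
  bed
}

#' Write a BED6 track
#'
#' @param bed A [genome_scan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
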