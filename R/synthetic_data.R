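# Synthetic fixtures with machine-readable ground truth: motif-planted
# promoters and genomes on verified hit-free backgrounds, exponential
# growth curves, and Ct tables with planted expression structure.
#
# Backgrounds are uniform i.i.d. {A,C,G,T}. At the default budgets a
# random 300 bp window is expected to contain several chance hits, so a
# hit-free background cannot realistically be obtained by redrawing whole
# windows; instead the generator scans, mutates one base inside each
# remaining hit and rescans until the window is clean (seed-deterministic,
# bounded). After planting, the same scan-verify-repair loop guarantees
# that the hits found are exactly the hits planted, which is the property
# underpinning every count-based check built on these fixtures.

DNA_BASES <- c("A", "C", "G", "T")

# Geometry of a variant string such as "GTTn2AACn6GTT": blocks, spacer
# lengths, span.
variant_geometry <- function(variant) {
  s <- toupper(variant)
  assert_that(grepl("^[ACGT]+(N[0-9]+[ACGT]+)+$", s),
              "malformed variant string '", variant, "'")
  blocks <- strsplit(s, "N[0-9]+")[[1]]
  spacers <- as.integer(gsub("N", "", regmatches(s, gregexpr("N[0-9]+", s))[[1]]))
  list(blocks = blocks, spacers = spacers,
       span = sum(nchar(blocks)) + sum(spacers))
}

# Which pattern a planted variant instantiates, and at what nominal edit
# cost. Errors when no pattern admits the variant within its budget.
variant_pattern <- function(variant, patterns) {
  geo <- variant_geometry(variant)
  for (p in patterns) {
    if (length(p$blocks) != length(geo$blocks)) next
    if (any(nchar(p$blocks) != nchar(geo$blocks))) next
    devs <- geo$spacers - p$spacer_lens
    if (any(abs(devs) > p$spacer_flex)) next
    mm <- sum(mapply(function(a, b)
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
      geo$blocks, p$blocks))
    if (mm + sum(abs(devs)) <= p$edit_budget)
      return(list(pattern = p$name, nominal_cost = mm + sum(abs(devs)),
                  geometry = geo))
  }
  stop("variant '", variant, "' matches no pattern within its edit budget",
       call. = FALSE)
}

#' Define a promoter plan
#'
#' A plan states which motif variants to plant, at which upstream
#' distances (bases strictly between the motif edge nearest the start
#' codon and the start codon) and in which orientation, on a verified
#' hit-free background of `window_len` bases.
#'
#' @param cluster_name Label for the planned promoter.
#' @param plants Data frame with columns `variant` (e.g. `"GTTn3AATn5GTT"`),
#'   `upstream_distance` (bp) and `orientation` (`"forward"`/`"reverse"`).
#' @param window_len Window length in bp (default 300).
#' @param background_seed RNG seed for the background and spacer fill.
#' @return A `promoter_plan` object.
#' @export
promoter_plan <- function(cluster_name, plants, window_len = 300L,
                          background_seed = 1L) {
  assert_that(is.data.frame(plants) &&
              all(c("variant", "upstream_distance", "orientation") %in%
                  names(plants)),
              "plants needs columns variant, upstream_distance, orientation")
  assert_that(all(plants$orientation %in% c("forward", "reverse")),
              "plant orientation must be 'forward' or 'reverse'")
  for (i in seq_len(nrow(plants))) {
    span <- variant_geometry(plants$variant[[i]])$span
    assert_that(plants$upstream_distance[[i]] >= 0 &&
                plants$upstream_distance[[i]] + span <= window_len,
                "plant '", plants$variant[[i]], "' at distance ",
                plants$upstream_distance[[i]],
                " does not fit in a ", window_len, " bp window")
  }
  structure(list(cluster_name = cluster_name, plants = plants,
                 window_len = as.integer(window_len),
                 background_seed = as.integer(background_seed)),
            class = "promoter_plan")
}

# Draw a background and repair it until an exhaustive scan at the pattern
# set's budgets finds zero raw hits.
draw_hitfree_background <- function(window_len, patterns, max_repair = 400L) {
  seqc <- sample(DNA_BASES, window_len, replace = TRUE)
  for (iter in seq_len(max_repair)) {
    hits <- scan_region(paste(seqc, collapse = ""), patterns,
                        params = list(nesting = FALSE))
    if (!nrow(hits)) return(seqc)
    for (i in seq_len(nrow(hits))) {
      bs <- as.integer(strsplit(hits$block_starts[[i]], ",")[[1]])
      bl <- as.integer(strsplit(hits$block_lens[[i]], ",")[[1]])
      positions <- unlist(mapply(function(s, l) (s + 1L):(s + l), bs, bl,
                                 SIMPLIFY = FALSE))
      pos <- if (length(positions) == 1L) positions else sample(positions, 1L)
      seqc[[pos]] <- sample(setdiff(DNA_BASES, seqc[[pos]]), 1L)
    }
  }
  stop("could not obtain a hit-free background after ", max_repair,
       " repair passes; consider a longer window or tighter budgets",
       call. = FALSE)
}

# Mutate one base per stray hit, preferring the stray hit's own block
# positions outside the protected plant-block mask (spacer content never
# affects a hit's cost, so mutating it cannot break the hit). Returns the
# mutated sequence vector, or NULL when no stray hit could be touched.
repair_extras <- function(seqc, hits, extra_idx, protected) {
  mutated <- FALSE
  for (i in extra_idx) {
    bs <- as.integer(strsplit(hits$block_starts[[i]], ",")[[1]])
    bl <- as.integer(strsplit(hits$block_lens[[i]], ",")[[1]])
    block_pos <- unlist(mapply(function(s, l) (s + 1L):(s + l), bs, bl,
                               SIMPLIFY = FALSE))
    mutable <- setdiff(block_pos, protected)
    if (!length(mutable)) next
    pos <- if (length(mutable) == 1L) mutable else sample(mutable, 1L)
    seqc[[pos]] <- sample(setdiff(DNA_BASES, seqc[[pos]]), 1L)
    mutated <- TRUE
  }
  if (mutated) seqc else NULL
}

# Placement of each plant in region coordinates (0-based offsets), genome
# frame: block letters/positions and spacer positions.
plant_placements <- function(plan, patterns) {
  L <- plan$window_len
  lapply(seq_len(nrow(plan$plants)), function(i) {
    variant <- plan$plants$variant[[i]]
    ori <- plan$plants$orientation[[i]]
    d <- plan$plants$upstream_distance[[i]]
    vp <- variant_pattern(variant, patterns)
    geo <- vp$geometry
    if (ori == "reverse") {
      blocks <- rev(vapply(geo$blocks, reverse_complement, ""))
      spacers <- rev(geo$spacers)
    } else {
      blocks <- geo$blocks
      spacers <- geo$spacers
    }
    offset <- L - d - geo$span
    rel <- 0L
    block_pos <- list(); block_char <- list()
    spacer_pos <- integer()
    for (j in seq_along(blocks)) {
      bc <- strsplit(blocks[[j]], "")[[1]]
      block_pos[[j]] <- offset + rel + seq_along(bc)      # 1-based
      block_char[[j]] <- bc
      rel <- rel + length(bc)
      if (j <= length(spacers)) {
        if (spacers[[j]] > 0)
          spacer_pos <- c(spacer_pos, offset + rel + seq_len(spacers[[j]]))
        rel <- rel + spacers[[j]]
      }
    }
    list(variant = variant, orientation = ori, upstream_distance = d,
         pattern = vp$pattern, nominal_cost = vp$nominal_cost,
         offset = offset, span = geo$span,
         genome_spacers = paste(spacers, collapse = ","),
         block_pos = unlist(block_pos), block_char = unlist(block_char),
         spacer_pos = spacer_pos)
  })
}

plant_keys <- function(placements) {
  vapply(placements, function(p)
    paste(p$pattern, p$offset, p$genome_spacers, sep = "|"), "")
}

hit_keys <- function(hits) {
  paste(hits$pattern_name, hits$region_offset, hits$genome_spacers, sep = "|")
}

#' Build a synthetic promoter with planted motif variants
#'
#' Draws a uniform background, repairs it until the scanner finds zero
#' hits at the pattern set's budgets, writes the planted variants at the
#' positions implied by their upstream distances (reverse plants inserted
#' as the reverse complement; spacer content drawn randomly), and then
#' verifies that the hits found equal the hits planted, mutating stray
#' background or spacer bases until they do. Overlapping plants are
#' merged: block letters take precedence over spacer fill, and among
#' conflicting block letters the later plant in the plan wins; a plant
#' pushed over its edit budget by such a conflict is an error.
#'
#' @param plan A [promoter_plan()].
#' @param patterns Pattern set (default [surr_patterns()]).
#' @param max_repair Bound on scan-repair passes.
#' @return List with `sequence` (the window) and `truth`, a
#'   `synthetic_truth` record of the planted hits (pattern, 0-based
#'   region offset, realized spacers, realized edit cost, annotation,
#'   upstream distance) plus seed and parameters.
#' @export
build_promoter <- function(plan, patterns = surr_patterns(),
                           max_repair = 400L) {
  assert_that(inherits(plan, "promoter_plan"), "plan must be a promoter_plan")
  with_seed(plan$background_seed, {
    placements <- plant_placements(plan, patterns)
    seqc <- draw_hitfree_background(plan$window_len, patterns, max_repair)
    if (length(placements)) {
      all_block_pos <- unique(unlist(lapply(placements, `[[`, "block_pos")))
      # spacer fill first (never over any plant's block), blocks last
      # (later plants override earlier on conflicts)
      for (p in placements) {
        fill <- setdiff(p$spacer_pos, all_block_pos)
        if (length(fill))
          seqc[fill] <- sample(DNA_BASES, length(fill), replace = TRUE)
      }
      for (p in placements) seqc[p$block_pos] <- p$block_char
      expected <- plant_keys(placements)
      assert_that(!anyDuplicated(expected),
                  "plan places two identical hits (same pattern, offset ",
                  "and spacers)")
      for (iter in seq_len(max_repair)) {
        hits <- scan_region(paste(seqc, collapse = ""), patterns,
                            params = list(nesting = TRUE))
        found <- hit_keys(hits)
        extra_idx <- which(!(found %in% expected))
        if (!length(extra_idx)) {
          # stray hits repaired first: an accidental long hit can
          # transiently mask a planted short through nesting suppression
          missing <- setdiff(expected, found)
          if (length(missing))
            stop("unplaceable plan for '", plan$cluster_name, "': planted ",
                 "site(s) ", paste(missing, collapse = "; "), " not ",
                 "recoverable within the edit budget (overlapping plants ",
                 "in conflict, or plan out of window)", call. = FALSE)
          truth <- promoter_truth(plan, placements, hits)
          return(list(sequence = paste(seqc, collapse = ""), truth = truth))
        }
        mutated <- repair_extras(seqc, hits, extra_idx, all_block_pos)
        assert_that(!is.null(mutated), "stray hit(s) lie entirely on ",
                    "planted blocks; cannot repair plan '",
                    plan$cluster_name, "'")
        seqc <- mutated
      }
      stop("verification did not converge after ", max_repair,
           " repair passes for plan '", plan$cluster_name, "'",
           call. = FALSE)
    }
    hits <- scan_region(paste(seqc, collapse = ""), patterns,
                        params = list(nesting = TRUE))
    assert_that(nrow(hits) == 0L, "internal error: hit-free check failed")
    list(sequence = paste(seqc, collapse = ""),
         truth = promoter_truth(plan, placements, hits))
  })
}

promoter_truth <- function(plan, placements, hits) {
  found <- hit_keys(hits)
  planted <- lapply(placements, function(p) {
    i <- match(paste(p$pattern, p$offset, p$genome_spacers, sep = "|"), found)
    list(variant = p$variant, orientation = p$orientation,
         upstream_distance = p$upstream_distance, pattern = p$pattern,
         region_offset = p$offset, genome_spacers = p$genome_spacers,
         nominal_cost = p$nominal_cost,
         edit_cost = if (!is.na(i)) hits$edit_cost[[i]] else NA_integer_,
         strand_label = if (!is.na(i)) hits$strand_label[[i]] else NA_character_,
         annotation = if (!is.na(i)) hits$annotation[[i]] else NA_character_)
  })
  structure(list(kind = "promoter", cluster_name = plan$cluster_name,
                 window_len = plan$window_len,
                 background_seed = plan$background_seed,
                 n_planted = length(planted), planted = planted),
            class = "synthetic_truth")
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth A `synthetic_truth` record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble promoter plans into a synthetic genome with annotation
#'
#' Each plan becomes one gene: its verified promoter is placed immediately
#' 5' of a dummy CDS in the cluster's reading orientation (reverse genes
#' carry the reverse-complemented promoter at higher coordinates), with
#' random intergenic buffer between genes. The assembled contig is then
#' re-verified: a whole-genome scan must find exactly the planted hits,
#' stray hits being repaired by mutating non-planted bases.
#'
#' @param plans List of [promoter_plan()] objects.
#' @param read_directions Character vector (`"forward"`/`"reverse"`), one
#'   per plan.
#' @param patterns Pattern set.
#' @param cds_len Dummy CDS length in bp (default 120; starts with ATG).
#' @param buffer_len Intergenic buffer in bp (default 60).
#' @param contig_id Contig identifier.
#' @param max_repair Bound on repair passes.
#' @return List with `genome` ([genome_record()]), `features`, `clusters`,
#'   and `truth` (planted hits with 1-based genomic coordinates).
#' @export
build_genome <- function(plans, read_directions, patterns = surr_patterns(),
                         cds_len = 120L, buffer_len = 60L,
                         contig_id = "synthetic_contig", max_repair = 400L) {
  assert_that(length(read_directions) == length(plans),
              "need one read_direction per plan")
  assert_that(cds_len >= 3L, "cds_len must hold at least a start codon")
  built <- lapply(plans, build_promoter, patterns = patterns,
                  max_repair = max_repair)
  with_seed(plans[[1]]$background_seed * 1000L + 7L, {
    segments <- character(0)
    features <- list()
    clusters <- list()
    expected <- character(0)
    block_mask <- integer(0)   # 1-based genomic positions of planted blocks
    cursor <- 0L
    planted_genomic <- list()
    for (k in seq_along(plans)) {
      plan <- plans[[k]]
      dir <- read_directions[[k]]
      prom <- built[[k]]$sequence
      plen <- nchar(prom)
      body <- paste(c("ATG", sample(DNA_BASES, cds_len - 3L, replace = TRUE)),
                    collapse = "")
      buffer <- paste(sample(DNA_BASES, buffer_len, replace = TRUE),
                      collapse = "")
      tag <- sprintf("SYN_%05d", k * 10L)
      placements <- plant_placements(plan, patterns)
      if (dir == "forward") {
        seg <- paste0(buffer, prom, body)
        prom_g0 <- cursor + buffer_len            # 0-based genome offset
        cds_start <- cursor + buffer_len + plen + 1L
        cds_end <- cds_start + cds_len - 1L
        for (p in placements) {
          g0 <- prom_g0 + p$offset
          expected <- c(expected, paste(p$pattern, g0, p$genome_spacers,
                                        sep = "|"))
          block_mask <- c(block_mask, prom_g0 + p$block_pos)
          planted_genomic[[length(planted_genomic) + 1L]] <- list(
            cluster = plan$cluster_name, pattern = p$pattern,
            genome_start = g0 + 1L, genome_end = g0 + p$span,
            upstream_distance = p$upstream_distance,
            variant = p$variant)
        }
      } else {
        seg <- paste0(buffer, reverse_complement(paste0(prom, body)))
        cds_start <- cursor + buffer_len + 1L
        cds_end <- cds_start + cds_len - 1L
        prom_g0 <- cursor + buffer_len + cds_len   # 0-based, revcomp promoter
        for (p in placements) {
          g0 <- prom_g0 + (plen - p$offset - p$span)
          rsp <- rev(as.integer(strsplit(p$genome_spacers, ",")[[1]]))
          expected <- c(expected, paste(p$pattern, g0,
                                        paste(rsp, collapse = ","), sep = "|"))
          block_mask <- c(block_mask,
                          prom_g0 + (plen - p$block_pos) + 1L)
          planted_genomic[[length(planted_genomic) + 1L]] <- list(
            cluster = plan$cluster_name, pattern = p$pattern,
            genome_start = g0 + 1L, genome_end = g0 + p$span,
            upstream_distance = p$upstream_distance,
            variant = p$variant)
        }
      }
      segments <- c(segments, seg)
      features[[k]] <- data.frame(
        locus_tag = tag, contig_id = contig_id, start = cds_start,
        end = cds_end, strand = dir, feature_kind = "CDS",
        stringsAsFactors = FALSE)
      clusters[[k]] <- data.frame(name = plan$cluster_name,
                                  first_cds_locus = tag,
                                  read_direction = dir,
                                  stringsAsFactors = FALSE)
      cursor <- cursor + nchar(seg)
    }
    tail_buffer <- paste(sample(DNA_BASES, buffer_len, replace = TRUE),
                         collapse = "")
    seqc <- strsplit(paste0(paste(segments, collapse = ""), tail_buffer),
                     "")[[1]]
    block_mask <- unique(block_mask)
    for (iter in seq_len(max_repair)) {
      hits <- scan_region(paste(seqc, collapse = ""), patterns,
                          params = list(nesting = TRUE))
      found <- hit_keys(hits)
      extra_idx <- which(!(found %in% expected))
      if (!length(extra_idx)) {
        missing <- setdiff(expected, found)
        assert_that(length(missing) == 0L,
                    "assembly broke planted site(s): ",
                    paste(missing, collapse = "; "))
        break
      }
      mutated <- repair_extras(seqc, hits, extra_idx, block_mask)
      assert_that(!is.null(mutated),
                  "stray genomic hit lies entirely on planted blocks")
      seqc <- mutated
      if (iter == max_repair)
        stop("genome verification did not converge", call. = FALSE)
    }
    genome <- genome_record(contig_id, paste(seqc, collapse = ""))
    features <- do.call(rbind, features)
    clusters <- do.call(rbind, clusters)
    truth <- structure(list(kind = "genome", contig_id = contig_id,
                            n_planted = length(planted_genomic),
                            planted = planted_genomic,
                            per_cluster = lapply(built, function(b)
                              unclass(b$truth))),
                       class = "synthetic_truth")
    list(genome = genome, features = features, clusters = clusters,
         truth = truth)
  })
}

#' Write a synthetic genome bundle to disk
#'
#' Emits `genome.fasta`, `features.gff3`, `clusters.tsv` and `truth.json`
#' into a directory, in the formats the ingest functions read back.
#'
#' @param bundle A [build_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "features.gff3")
  cltsv <- file.path(dir, "clusters.tsv")
  truth <- file.path(dir, "truth.json")
  write_genome_fasta(bundle$genome, fasta)
  f <- bundle$features
  lines <- c("##gff-version 3",
             sprintf("%s\tsurrtools\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
                     f$contig_id, f$start, f$end,
                     ifelse(f$strand == "forward", "+", "-"),
                     f$locus_tag, f$locus_tag))
  writeLines(lines, gff)
  utils::write.table(bundle$clusters, cltsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_truth(bundle$truth, truth)
  invisible(c(fasta = fasta, gff = gff, clusters = cltsv, truth = truth))
}

#' Simulate an exponential growth curve
#'
#' Counts follow `min(capacity, n0 * exp(mu * max(0, t - lag_h)))`
#' perturbed by multiplicative lognormal noise of coefficient of variation
#' `noise_cv` (mean-one correction applied), deterministic under `seed`.
#'
#' @param mu True specific growth rate (h^-1), >= 0.
#' @param n0 Initial density in cells/mL (default 2e6, a typical
#'   inoculation density for these cultures).
#' @param lag_h Lag phase duration in hours.
#' @param capacity Carrying capacity in cells/mL (default `Inf`).
#' @param times Sampling times in hours.
#' @param noise_cv Lognormal noise CV (default 0.1, chamber-counting
#'   scale).
#' @param seed RNG seed.
#' @param strain,condition,replicate_id Curve labels.
#' @return A [growth_curve()] carrying the generating parameters as
#'   attribute `truth`.
#' @export
simulate_growth <- function(mu, n0 = 2e6, lag_h = 0, capacity = Inf,
                            times = 0:8, noise_cv = 0.1, seed = 1L,
                            strain = "sim", condition = NULL,
                            replicate_id = "r1") {
  assert_that(is.numeric(mu) && mu >= 0, "mu must be >= 0")
  assert_that(n0 > 0, "n0 must be positive")
  assert_that(capacity > n0, "capacity must exceed n0")
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  with_seed(seed, {
    mean_counts <- pmin(capacity, n0 * exp(mu * pmax(0, times - lag_h)))
    counts <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mean_counts * exp(stats::rnorm(length(times), 0, sdlog) - sdlog^2 / 2)
    } else mean_counts
    curve <- growth_curve(times, counts, strain = strain,
                          condition = condition, replicate_id = replicate_id)
    attr(curve, "truth") <- structure(
      list(kind = "growth", mu = mu, n0 = n0, lag_h = lag_h,
           capacity = capacity, noise_cv = noise_cv, seed = seed),
      class = "synthetic_truth")
    curve
  })
}

#' Simulate a replicated cell-count table from a truth grid
#'
#' One curve per strain x condition x replicate, long format, ready for
#' [rate_grid()].
#'
#' @param truth_grid Data frame with `strain`, `pressure_MPa`, `sulfur`,
#'   `sulfur_conc_g_per_L`, `mu`.
#' @param n_replicates Biological replicates per cell (default 3).
#' @inheritParams simulate_growth
#' @return Long data frame in the [read_growth_tsv()] layout, truth grid
#'   attached as attribute `truth`.
#' @export
simulate_growth_table <- function(truth_grid, n_replicates = 3L, n0 = 2e6,
                                  times = 0:8, noise_cv = 0.1, seed = 1L) {
  rows <- list()
  for (i in seq_len(nrow(truth_grid))) {
    for (r in seq_len(n_replicates)) {
      curve <- simulate_growth(truth_grid$mu[[i]], n0 = n0, times = times,
                               noise_cv = noise_cv,
                               seed = seed + 1000L * i + r)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = truth_grid$strain[[i]],
        pressure_MPa = truth_grid$pressure_MPa[[i]],
        sulfur = truth_grid$sulfur[[i]],
        sulfur_conc_g_per_L = truth_grid$sulfur_conc_g_per_L[[i]],
        replicate = paste0("rep", r), time_h = curve$times,
        cells_per_mL = curve$counts, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth_grid
  out
}

#' Simulate a qPCR Ct table with planted expression ratios
#'
#' Per group and biological replicate, a reference baseline Ct is drawn
#' `Normal(ref_ct, sd_bio)`; each target gene's baseline is the reference
#' baseline minus `log2(true ratio)` plus its own `Normal(0, sd_bio)`
#' biological noise; technical replicates add `Normal(0, sd_tech)`.
#' Deterministic under `seed`.
#'
#' @param design List: `n_bio` (default 3), `n_tech` (default 3),
#'   `reference` (reference gene name, default `"pcna"`).
#' @param true_ratios Data frame with the group columns (`strain`,
#'   `pressure_MPa`, `sulfur`, `sulfur_conc_g_per_L`), `gene` and `ratio`
#'   (expression relative to the reference; > 0).
#' @param ref_ct Reference-gene mean Ct (default 20).
#' @param sd_bio Biological SD in cycles (default 0.3).
#' @param sd_tech Technical SD in cycles (default 0.15).
#' @param seed RNG seed.
#' @return Ct table in the [read_ct_tsv()] layout, with `true_ratios`
#'   attached as attribute `truth`.
#' @export
simulate_ct <- function(design = list(), true_ratios, ref_ct = 20,
                        sd_bio = 0.3, sd_tech = 0.15, seed = 1L) {
  n_bio <- design$n_bio %||% 3L
  n_tech <- design$n_tech %||% 3L
  reference <- design$reference %||% "pcna"
  assert_that(all(true_ratios$ratio > 0), "true ratios must be positive")
  assert_that(n_bio >= 1L && n_tech >= 1L, "need >= 1 replicate")
  with_seed(seed, {
    groups <- unique(true_ratios[ct_group_cols])
    rows <- list()
    for (gi in seq_len(nrow(groups))) {
      grp <- groups[gi, , drop = FALSE]
      sel <- filter_group(true_ratios, as.list(grp))
      for (b in seq_len(n_bio)) {
        bio <- paste0("bio", b)
        ref_base <- stats::rnorm(1, ref_ct, sd_bio)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = reference, grp, bio_replicate = bio,
          tech_replicate = paste0("tech", seq_len(n_tech)),
          ct = ref_base + stats::rnorm(n_tech, 0, sd_tech),
          row.names = NULL, stringsAsFactors = FALSE)
        for (k in seq_len(nrow(sel))) {
          gene_base <- ref_base - log2(sel$ratio[[k]]) +
            stats::rnorm(1, 0, sd_bio)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = sel$gene[[k]], grp, bio_replicate = bio,
            tech_replicate = paste0("tech", seq_len(n_tech)),
            ct = gene_base + stats::rnorm(n_tech, 0, sd_tech),
            row.names = NULL, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- true_ratios
    out
  })
}
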