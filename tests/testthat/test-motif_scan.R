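pats <- surr_patterns()

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(20240601)
  lens <- c(rep(60, 40), rep(150, 40), rep(300, 15), rep(1000, 5))
  for (i in seq_along(lens)) {
    s <- random_dna(lens[[i]])
    got <- scan_region(s, pats, params = list(nesting = FALSE))
    want <- oracle_scan(s, pats)
    expect_identical(scan_key_set(got), oracle_key_set(want),
                     info = paste("seed case", i))
  }
})

test_that("a planted canonical long is found exactly where planted", {
  plan <- promoter_plan("shii-like",
                        data.frame(variant = "GTTn3AACn5GTT",
                                   upstream_distance = 67,
                                   orientation = "forward"),
                        window_len = 200, background_seed = 31)
  bp <- build_promoter(plan, pats)
  hits <- scan_region(bp$sequence, pats)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$pattern_name, "long")
  expect_true(hits$exact)
  expect_identical(hits$upstream_distance, 67L)
  expect_identical(hits$annotation, "Long")
})

test_that("a verified hit-free background has zero hits", {
  plan <- promoter_plan("empty", data.frame(variant = character(),
                                            upstream_distance = integer(),
                                            orientation = character()),
                        window_len = 200, background_seed = 5)
  bp <- build_promoter(plan, pats)
  expect_identical(nrow(scan_region(bp$sequence, pats)), 0L)
})

test_that("nesting suppression removes only embedded aligned shorts", {
  # one exact long: its 9 bp prefix is itself an exact short and must
  # not be double counted
  plan <- promoter_plan("one-long",
                        data.frame(variant = "GTTn3AACn5GTT",
                                   upstream_distance = 30,
                                   orientation = "forward"),
                        window_len = 120, background_seed = 8)
  bp <- build_promoter(plan, pats)
  raw <- scan_region(bp$sequence, pats, params = list(nesting = FALSE))
  res <- scan_region(bp$sequence, pats)
  expect_identical(sort(unique(raw$pattern_name)), c("long", "short"))
  expect_identical(res$pattern_name, "long")

  # a short 30+ bp away from a long: both retained
  plan2 <- promoter_plan("apart",
                         data.frame(variant = c("GTTn3AACn5GTT", "GTTn3AAC"),
                                    upstream_distance = c(60, 10),
                                    orientation = "forward"),
                         window_len = 160, background_seed = 21)
  bp2 <- build_promoter(plan2, pats)
  res2 <- scan_region(bp2$sequence, pats)
  expect_identical(sort(res2$pattern_name), c("long", "short"))

  # fuzzed: suppression never removes a hit not contained in a long hit
  set.seed(77)
  for (i in 1:40) {
    s <- random_dna(200)
    raw <- scan_region(s, pats, params = list(nesting = FALSE))
    res <- scan_region(s, pats)
    removed <- setdiff(scan_key_set(raw), scan_key_set(res))
    if (!length(removed)) next
    longs <- raw[raw$n_blocks >= 3, , drop = FALSE]
    for (key in removed) {
      off <- as.integer(strsplit(key, " ")[[1]][[2]])
      row <- raw[raw$region_offset == off & raw$n_blocks == 2L, , drop = FALSE]
      expect_true(nrow(row) > 0)
      contained <- any(longs$region_offset <= row$region_offset[[1]] &
                       longs$region_offset + longs$span >=
                         row$region_offset[[1]] + row$span[[1]])
      expect_true(contained, info = key)
    }
  }
})

test_that("strand labels follow cost and palindromy conventions", {
  # exact short: matches both orientations position-by-position
  plan <- promoter_plan("pal", data.frame(variant = "GTTn3AAC",
                                          upstream_distance = 31,
                                          orientation = "forward"),
                        window_len = 120, background_seed = 12)
  hits <- scan_region(build_promoter(plan, pats)$sequence, pats)
  expect_identical(hits$strand_label, "forward_and_reverse")

  # 1-mismatch short: equal cost both ways, tie-break forward
  plan <- promoter_plan("tie", data.frame(variant = "ATTn3AAC",
                                          upstream_distance = 21,
                                          orientation = "forward"),
                        window_len = 120, background_seed = 14)
  hits <- scan_region(build_promoter(plan, pats)$sequence, pats)
  expect_identical(hits$strand_label, "forward")

  # canonical long planted in reverse orientation
  plan <- promoter_plan("rev", data.frame(variant = "GTTn3AACn5GTT",
                                          upstream_distance = 11,
                                          orientation = "reverse"),
                        window_len = 120, background_seed = 18)
  hits <- scan_region(build_promoter(plan, pats)$sequence, pats)
  expect_identical(hits$strand_label, "reverse")
})

test_that("scanning is symmetric under reverse complementation", {
  set.seed(303)
  for (i in 1:25) {
    s <- random_dna(180)
    fwd <- scan_region(s, pats, params = list(nesting = FALSE))
    rev <- scan_region(reverse_complement(s), pats,
                       params = list(nesting = FALSE))
    L <- nchar(s)
    swap <- c(forward = "reverse", reverse = "forward",
              forward_and_reverse = "forward_and_reverse")
    key_fwd <- sort(paste(fwd$pattern_name, fwd$region_offset,
                          fwd$region_offset + fwd$span, fwd$edit_cost))
    key_rev <- sort(paste(rev$pattern_name, L - rev$region_offset - rev$span,
                          L - rev$region_offset, rev$edit_cost))
    expect_identical(key_fwd, key_rev, info = paste("case", i))
    # labels swap on exact hits; forward_and_reverse is a fixed point
    ex_f <- fwd[fwd$exact, , drop = FALSE]
    ex_r <- rev[rev$exact, , drop = FALSE]
    lab_f <- sort(paste(ex_f$pattern_name, ex_f$region_offset,
                        ex_f$strand_label))
    lab_r <- sort(paste(ex_r$pattern_name,
                        L - ex_r$region_offset - ex_r$span,
                        unname(swap[ex_r$strand_label])))
    expect_identical(lab_f, lab_r)
  }
})

test_that("raising budgets or flexibility never removes hits", {
  set.seed(404)
  for (i in 1:15) {
    s <- random_dna(150)
    base <- scan_region(s, pats, params = list(nesting = FALSE))
    wide <- surr_patterns(budgets = c(short = 2L, long = 3L))
    more <- scan_region(s, wide, params = list(nesting = FALSE))
    flex2 <- surr_patterns(spacer_flex = 2L)
    more_flex <- scan_region(s, flex2, params = list(nesting = FALSE))
    # every base-level occurrence is still present at the wider settings
    # (possibly re-collapsed onto a cheaper overlapping alignment)
    covered <- function(h, set)
      any(set$pattern_name == h$pattern_name &
          pmax(set$region_offset, h$region_offset) <
            pmin(set$region_offset + set$span, h$region_offset + h$span))
    for (k in seq_len(nrow(base))) {
      expect_true(covered(base[k, ], more))
      expect_true(covered(base[k, ], more_flex))
    }
    # and narrowing to budget zero only keeps exact hits
    none <- surr_patterns(budgets = c(short = 0L, long = 0L))
    strict <- scan_region(s, none, params = list(nesting = FALSE))
    expect_true(all(strict$edit_cost == 0L))
    expect_true(all(scan_key_set(strict) %in% scan_key_set(base)))
  }
})

test_that("report annotations render matched blocks and realized spacers", {
  plan <- promoter_plan("ann",
                        data.frame(variant = c("GTTn3AATn5GTT",
                                               "GTTn2AACn6GTT",
                                               "GTTn3AACn5GTT"),
                                   upstream_distance = c(10, 40, 70),
                                   orientation = "forward"),
                        window_len = 200, background_seed = 23)
  hits <- scan_region(build_promoter(plan, pats)$sequence, pats)
  expect_identical(hits$annotation[hits$upstream_distance == 70], "Long")
  expect_identical(hits$annotation[hits$upstream_distance == 10],
                   "Long with mutation: GTTn3AATn5GTT")
  expect_identical(hits$annotation[hits$upstream_distance == 40],
                   "Long with mutation: GTTn2AACn6GTT")
  expect_identical(render_annotation(hits[1, ]), hits$annotation[[1]])
})

test_that("genome-wide scan emits BED6 with converted coordinates", {
  # exact short at 1-based 11..19 of a synthetic contig
  plan <- promoter_plan("bed", data.frame(variant = "GTTn3AAC",
                                          upstream_distance = 71,
                                          orientation = "forward"),
                        window_len = 90, background_seed = 2)
  bp <- build_promoter(plan, pats)
  g <- genome_record("ctg", bp$sequence)
  bed <- genome_scan(g, pats)
  expect_identical(nrow(bed), 1L)
  expect_identical(bed$chromStart, 10L)
  expect_identical(bed$chromEnd, 19L)
  expect_identical(bed$strand, ".")

  empty_plan <- promoter_plan("none", data.frame(variant = character(),
                                                 upstream_distance = integer(),
                                                 orientation = character()),
                              window_len = 100, background_seed = 3)
  g0 <- genome_record("ctg0", build_promoter(empty_plan, pats)$sequence)
  expect_identical(nrow(genome_scan(g0, pats)), 0L)

  # BED line count equals the oracle hit count on a random contig
  set.seed(606)
  s <- random_dna(2000)
  bed <- genome_scan(genome_record("ctg2", s), pats)
  expect_identical(nrow(bed), nrow(oracle_scan(s, pats)))
})

test_that("promoter reports aggregate counts per cluster and flag noise", {
  plans <- reported_promoter_plans(base_seed = 3)[c("Mrp-Mbh 2", "SHII")]
  bundle <- build_genome(plans, c("reverse", "forward"), pats)
  report <- promoter_report(bundle$genome, bundle$features, bundle$clusters,
                            pats)
  counts <- tapply(report$occurrence_count, report$cluster, unique)
  expect_identical(counts[["Mrp-Mbh 2"]], 2L)
  expect_identical(counts[["SHII"]], 1L)
  expect_identical(sum(report$cluster == "Mrp-Mbh 2"), 2L)
  expect_identical(
    sort(report$upstream_distance[report$cluster == "Mrp-Mbh 2"]),
    c(11L, 96L))
  expect_error(
    promoter_report(bundle$genome, bundle$features,
                    data.frame(name = "ghost", first_cds_locus = "NOPE",
                               read_direction = "forward"), pats),
    "unresolvable")
})
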