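# Block-and-spacer consensus patterns for SurR recognition sites.
#
# The SurR consensus is a set of fixed-sequence triplet blocks separated by
# spacers of unconstrained sequence: short GTTn3AAC (9 bp, structurally its
# own reverse complement) and long GTTn3AACn5GTT (17 bp). Variant
# occurrences are admitted under an edit budget, where one edit is either a
# block-position mismatch or one unit of spacer-length deviation.

#' Compile a block-and-spacer motif pattern
#'
#' Parses a specification such as `"GTTn3AAC"` or `"GTTn3AACn5GTT"`:
#' fixed blocks over A/C/G/T separated by `nK` spacers of canonical length
#' `K`. The pattern name is inferred from the block count (2 blocks =
#' `"short"`, 3 = `"long"`) unless overridden; default edit budgets are 1
#' for short and 2 for long, matching the most degenerate variants observed
#' upstream of thermococcal energy-metabolism clusters.
#'
#' @param spec_string Pattern specification, e.g. `"GTTn3AACn5GTT"`.
#' @param name Optional name override.
#' @param spacer_flex Maximum deviation of each realized spacer from its
#'   canonical length (default 1); each unit of deviation is charged one
#'   edit.
#' @param edit_budget Maximum total edits (block mismatches plus absolute
#'   spacer deviations) for a reported hit.
#' @return A `motif_pattern` with fields `name`, `blocks`, `spacer_lens`,
#'   `spacer_flex`, `edit_budget`, `span` (canonical bp) and `spec`.
#' @export
compile_pattern <- function(spec_string, name = NULL, spacer_flex = 1L,
                            edit_budget = NULL) {
  assert_that(is.character(spec_string) && length(spec_string) == 1L,
              "pattern spec must be a single string")
  s <- toupper(spec_string)
  assert_that(grepl("^[ACGT]+(N[0-9]+[ACGT]+)+$", s),
              "malformed pattern spec '", spec_string,
              "': expected BLOCK(nK BLOCK)+ with >= 2 blocks")
  blocks <- strsplit(s, "N[0-9]+")[[1]]
  spacer_lens <- as.integer(
    gsub("N", "", regmatches(s, gregexpr("N[0-9]+", s))[[1]]))
  assert_that(all(nzchar(blocks)), "zero-length block in pattern spec")
  assert_that(all(spacer_lens >= 1L), "spacer length must be positive")
  if (is.null(name))
    name <- switch(as.character(length(blocks)), "2" = "short", "3" = "long",
                   paste0("blocks", length(blocks)))
  if (is.null(edit_budget))
    edit_budget <- if (identical(name, "short")) 1L else 2L
  assert_that(is_count(edit_budget), "edit_budget must be a nonnegative integer")
  assert_that(is_count(spacer_flex), "spacer_flex must be a nonnegative integer")
  structure(list(name = name, blocks = blocks, spacer_lens = spacer_lens,
                 spacer_flex = as.integer(spacer_flex),
                 edit_budget = as.integer(edit_budget),
                 span = sum(nchar(blocks)) + sum(spacer_lens),
                 spec = s),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (span %d bp, flex +/-%d, budget %d)\n",
              x$name, render_pattern_string(x$blocks, x$spacer_lens),
              x$span, x$spacer_flex, x$edit_budget))
  invisible(x)
}

#' Default SurR pattern set
#'
#' The short (`GTTn3AAC`) and long (`GTTn3AACn5GTT`) SurR consensus
#' patterns with their default budgets. `include_alt_short = TRUE` adds the
#' alternative short consensus `GTTn3ATC` reported for some Thermococcales
#' under the name `"short_alt"` (off by default; it is not part of the
#' canonical definitions used for the promoter reports).
#'
#' @param spacer_flex Spacer flexibility per spacer (default 1).
#' @param budgets Named numeric: edit budgets for `short` and `long`.
#' @param include_alt_short Also compile `GTTn3ATC` as `"short_alt"`.
#' @return Named list of [compile_pattern()] results.
#' @export
surr_patterns <- function(spacer_flex = 1L, budgets = c(short = 1L, long = 2L),
                          include_alt_short = FALSE) {
  pats <- list(
    short = compile_pattern("GTTn3AAC", spacer_flex = spacer_flex,
                            edit_budget = budgets[["short"]]),
    long = compile_pattern("GTTn3AACn5GTT", spacer_flex = spacer_flex,
                           edit_budget = budgets[["long"]]))
  if (include_alt_short)
    pats$short_alt <- compile_pattern("GTTn3ATC", name = "short_alt",
                                      spacer_flex = spacer_flex,
                                      edit_budget = budgets[["short"]])
  pats
}

# Pattern as seen on the opposite strand: blocks reverse-complemented and
# reversed, spacers reversed. Matching this against the forward genome is
# equivalent to matching the original pattern on the reverse strand.
revcomp_pattern <- function(pattern) {
  p <- pattern
  p$blocks <- unname(rev(vapply(pattern$blocks, reverse_complement, "")))
  p$spacer_lens <- rev(pattern$spacer_lens)
  p
}

is_self_rc <- function(pattern) {
  rc <- revcomp_pattern(pattern)
  identical(rc$blocks, pattern$blocks) &&
    identical(rc$spacer_lens, pattern$spacer_lens)
}

render_pattern_string <- function(blocks, spacer_lens) {
  out <- blocks[[1]]
  for (j in seq_along(spacer_lens))
    out <- paste0(out, "n", spacer_lens[[j]], blocks[[j + 1L]])
  out
}

# All realized spacer-length vectors within spacer_flex of the canonical
# lengths (each component independently), as a matrix with one row per
# realization. Realized spacers of length < 1 are dropped.
spacer_realizations <- function(canonical, flex) {
  choices <- lapply(canonical, function(k) seq(k - flex, k + flex))
  grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  grid <- grid[apply(grid, 1L, function(r) all(r >= 1L)), , drop = FALSE]
  storage.mode(grid) <- "integer"
  grid
}

#' Score a candidate motif placement
#'
#' Tests whether `pattern` matches `seq` at a given offset with the stated
#' realized spacer lengths. The mismatch count is the Hamming distance
#' summed over block positions only (spacer content is unconstrained); the
#' edit cost adds one per unit of spacer-length deviation. A placement
#' whose cost exceeds the pattern's edit budget is a no-match.
#'
#' @param seq DNA string (forward orientation as written).
#' @param offset 0-based offset of the candidate's first base within `seq`.
#' @param pattern A [compile_pattern()] result.
#' @param realized_spacers Integer vector of realized spacer lengths, one
#'   per spacer.
#' @return `NULL` on no-match, else a list with `mismatch_count`,
#'   `spacer_devs` (signed, per spacer), `edit_cost`, `span` and
#'   `matched_blocks` (the block substrings actually observed).
#' @export
match_at <- function(seq, offset, pattern, realized_spacers) {
  assert_that(inherits(pattern, "motif_pattern"), "pattern must be compiled")
  realized_spacers <- as.integer(realized_spacers)
  assert_that(length(realized_spacers) == length(pattern$spacer_lens),
              "need one realized spacer per pattern spacer")
  devs <- realized_spacers - pattern$spacer_lens
  assert_that(all(abs(devs) <= pattern$spacer_flex),
              "realized spacer outside the pattern's flexibility")
  seq <- toupper(seq)
  span <- sum(nchar(pattern$blocks)) + sum(realized_spacers)
  assert_that(offset >= 0 && offset + span <= nchar(seq),
              "candidate window does not fit inside seq")
  pos <- offset + 1L
  mm <- 0L
  matched <- character(length(pattern$blocks))
  for (j in seq_along(pattern$blocks)) {
    b <- pattern$blocks[[j]]
    obs <- substr(seq, pos, pos + nchar(b) - 1L)
    mm <- mm + sum(strsplit(obs, "")[[1]] != strsplit(b, "")[[1]])
    matched[[j]] <- obs
    pos <- pos + nchar(b) +
      if (j <= length(realized_spacers)) realized_spacers[[j]] else 0L
  }
  cost <- mm + sum(abs(devs))
  if (cost > pattern$edit_budget) return(NULL)
  list(mismatch_count = as.integer(mm), spacer_devs = as.integer(devs),
       edit_cost = as.integer(cost), span = as.integer(span),
       matched_blocks = matched)
}
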