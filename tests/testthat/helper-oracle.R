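# Independent brute-force oracle for the motif scanner: plain loops over
# every offset, spacer realization and orientation, explicit character
# comparison, then the hit-definition semantics (orientation merge,
# endpoint-component collapse) re-derived with different code.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Enumerate all candidates of one pattern over seq, genome frame.
oracle_candidates <- function(seq, pattern) {
  seq <- toupper(seq)
  L <- nchar(seq)
  res <- list()
  frames <- list(forward = list(blocks = pattern$blocks,
                                canon = pattern$spacer_lens))
  rc_blocks <- rev(vapply(pattern$blocks, oracle_revcomp, ""))
  rc_canon <- rev(pattern$spacer_lens)
  self_rc <- identical(rc_blocks, pattern$blocks) &&
    identical(rc_canon, pattern$spacer_lens)
  if (!self_rc)
    frames$reverse <- list(blocks = rc_blocks, canon = rc_canon)
  for (ori in names(frames)) {
    fr <- frames[[ori]]
    spacer_opts <- lapply(fr$canon, function(k)
      Filter(function(v) v >= 1, (k - pattern$spacer_flex):(k + pattern$spacer_flex)))
    combos <- expand.grid(spacer_opts)
    for (ci in seq_len(nrow(combos))) {
      r <- as.integer(combos[ci, ])
      span <- sum(nchar(fr$blocks)) + sum(r)
      if (span > L) next
      for (off in 0:(L - span)) {
        pos <- off + 1
        mm <- 0
        for (b in seq_along(fr$blocks)) {
          blk <- fr$blocks[[b]]
          for (k in seq_len(nchar(blk)))
            if (substr(seq, pos + k - 1, pos + k - 1) !=
                substr(blk, k, k)) mm <- mm + 1
          pos <- pos + nchar(blk)
          if (b <= length(r)) pos <- pos + r[[b]]
        }
        cost <- mm + sum(abs(r - fr$canon))
        if (cost <= pattern$edit_budget)
          res[[length(res) + 1]] <- data.frame(
            pattern_name = pattern$name, orientation = ori, offset = off,
            span = span, spacers = paste(r, collapse = ","),
            mm = mm, cost = cost, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(NULL)
  cand <- do.call(rbind, res)
  attr(cand, "self_rc") <- self_rc
  cand
}

# Full oracle scan: merge orientations per placement, then collapse
# endpoint-sharing alignments per pattern keeping min (cost, mm, spacers).
oracle_scan <- function(seq, patterns) {
  all_hits <- list()
  for (pattern in patterns) {
    cand <- oracle_candidates(seq, pattern)
    if (is.null(cand)) next
    self_rc <- attr(cand, "self_rc")
    merged <- list()
    for (key in unique(paste(cand$offset, cand$spacers))) {
      sub <- cand[paste(cand$offset, cand$spacers) == key, , drop = FALSE]
      if (self_rc) {
        h <- sub[1, ]
        h$label <- if (h$cost == 0) "forward_and_reverse" else "forward"
      } else if (nrow(sub) == 2) {
        cf <- sub$cost[sub$orientation == "forward"]
        cr <- sub$cost[sub$orientation == "reverse"]
        if (cf == 0 && cr == 0) {
          h <- sub[sub$orientation == "forward", ]
          h$label <- "forward_and_reverse"
        } else if (cf <= cr) {
          h <- sub[sub$orientation == "forward", ]
          h$label <- "forward"
        } else {
          h <- sub[sub$orientation == "reverse", ]
          h$label <- "reverse"
        }
      } else {
        h <- sub
        h$label <- h$orientation
      }
      merged[[length(merged) + 1]] <- h
    }
    m <- do.call(rbind, merged)
    # endpoint components by fixpoint relabelling
    comp <- seq_len(nrow(m))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
        if (comp[i] < comp[j] &&
            (m$offset[i] == m$offset[j] ||
             m$offset[i] + m$span[i] == m$offset[j] + m$span[j])) {
          comp[j] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cid in unique(comp)) {
      grp <- m[comp == cid, , drop = FALSE]
      grp <- grp[order(grp$cost, grp$mm, grp$spacers), , drop = FALSE]
      all_hits[[length(all_hits) + 1]] <- grp[1, , drop = FALSE]
    }
  }
  if (!length(all_hits))
    return(data.frame(pattern_name = character(), offset = integer(),
                      span = integer(), spacers = character(),
                      mm = integer(), cost = integer(),
                      label = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, all_hits)
  out[order(out$pattern_name, out$offset, out$spacers),
      c("pattern_name", "offset", "span", "spacers", "mm", "cost", "label")]
}

# Canonical comparable key set from a scan_region() hit table (raw, i.e.
# nesting disabled).
scan_key_set <- function(hits) {
  if (!nrow(hits)) return(character(0))
  sort(paste(hits$pattern_name, hits$region_offset, hits$genome_spacers,
             hits$edit_cost, hits$strand_label))
}

oracle_key_set <- function(oracle_hits) {
  if (!nrow(oracle_hits)) return(character(0))
  sort(paste(oracle_hits$pattern_name, oracle_hits$offset,
             oracle_hits$spacers, oracle_hits$cost, oracle_hits$label))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
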