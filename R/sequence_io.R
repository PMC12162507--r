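# Genome/annotation ingest, coordinate arithmetic and promoter extraction.
#
# Coordinates are 1-based inclusive throughout (GFF3 convention); BED output
# elsewhere converts to 0-based half-open.

#' Construct a genome record
#'
#' A genome record holds one contig: an accession-like identifier and its
#' uppercase DNA sequence over the alphabet A, C, G, T, N.
#'
#' @param id Accession-like identifier (non-empty string).
#' @param sequence DNA string; lower case is folded to upper case.
#' @return An object of class `genome_record` with fields `id`, `sequence`
#'   and `length` (bp).
#' @export
genome_record <- function(id, sequence) {
  assert_that(is.character(id) && length(id) == 1L && nzchar(id),
              "genome record id must be a non-empty string")
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "sequence must be a single string")
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  assert_that(!nzchar(bad),
              "illegal character(s) in sequence for '", id, "': ",
              paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp\n", x$id,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' Sequences are uppercased and multi-line entries concatenated. Duplicate
#' identifiers, empty files and non-ACGTN characters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [genome_record()] objects, one per header.
#' @export
read_genome_fasta <- function(path) {
  assert_that(file.exists(path), "no such FASTA file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA ingest error for '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  assert_that(length(set) > 0L, "empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  assert_that(length(dup) == 0L,
              "duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  recs <- lapply(seq_along(set), function(i)
    genome_record(ids[[i]], as.character(set[[i]])))
  stats::setNames(recs, ids)
}

#' Write genome records to FASTA
#'
#' @param genomes A `genome_record` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param seq DNA string over A, C, G, T, N (case folded).
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  assert_that(is.character(seq) && length(seq) == 1L,
              "seq must be a single string")
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Read CDS features from a GFF3-like annotation file
#'
#' Reads the minimal GFF3 dialect used throughout the package: tab-separated
#' lines with seqid, source, type, start, end, score, strand, phase and an
#' attribute column carrying `locus_tag=` or `ID=`. Only `CDS` rows are
#' returned. With `dialect = "alias_table"` a two-column tab-separated file
#' mapping alternative locus tags (for instance old-style `TERMP_#####` to
#' RefSeq `TERMP_RS#####`) is applied so that either name resolves to the
#' same feature via [feature_by_locus()].
#'
#' @param path Annotation file path.
#' @param dialect `"gff3"` or `"alias_table"`.
#' @param alias_path Two-column TSV (alias, locus_tag); required for the
#'   `alias_table` dialect.
#' @return A data frame with columns `locus_tag`, `contig_id`, `start`,
#'   `end`, `strand` (`"forward"`/`"reverse"`) and `feature_kind`, carrying
#'   the alias map as attribute `alias_map`.
#' @export
read_features <- function(path, dialect = c("gff3", "alias_table"),
                          alias_path = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "no such annotation file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("annotation parse error at line ", i, ": expected 9 tab-separated ",
           "columns, got ", length(f), call. = FALSE)
    start <- suppressWarnings(as.integer(f[[4]]))
    end <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(start) || is.na(end))
      stop("annotation parse error at line ", i, ": non-integer coordinates",
           call. = FALSE)
    if (start > end)
      stop("annotation parse error at line ", i, ": start (", start,
           ") > end (", end, ")", call. = FALSE)
    if (start < 1L)
      stop("annotation parse error at line ", i, ": start < 1", call. = FALSE)
    if (!f[[7]] %in% c("+", "-"))
      stop("annotation parse error at line ", i, ": unknown strand symbol '",
           f[[7]], "'", call. = FALSE)
    attrs <- f[[9]]
    tag <- attr_field(attrs, "locus_tag") %||% attr_field(attrs, "ID")
    if (is.null(tag) || !nzchar(tag))
      stop("annotation parse error at line ", i,
           ": no locus_tag or ID attribute", call. = FALSE)
    data.frame(locus_tag = tag, contig_id = f[[1]], start = start, end = end,
               strand = if (f[[7]] == "+") "forward" else "reverse",
               feature_kind = if (f[[3]] == "CDS") "CDS" else "other",
               stringsAsFactors = FALSE)
  })
  feats <- do.call(rbind, rows)
  if (is.null(feats))
    feats <- data.frame(locus_tag = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), feature_kind = character())
  feats <- feats[feats$feature_kind == "CDS", , drop = FALSE]
  rownames(feats) <- NULL
  alias_map <- NULL
  if (dialect == "alias_table") {
    assert_that(!is.null(alias_path),
                "dialect 'alias_table' requires alias_path")
    al <- utils::read.delim(alias_path, header = FALSE,
                            stringsAsFactors = FALSE)
    assert_that(ncol(al) >= 2L, "alias table must have two columns")
    bad <- which(!(al[[2]] %in% feats$locus_tag))
    if (length(bad))
      stop("annotation parse error: alias table line ", bad[[1]],
           " maps to unknown locus '", al[[2]][bad[[1]]], "'", call. = FALSE)
    alias_map <- stats::setNames(al[[2]], al[[1]])
  }
  attr(feats, "alias_map") <- alias_map
  feats
}

attr_field <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"),
                                 attrs))[[1]]
  if (length(m) == 2L) m[[2]] else NULL
}

#' Look up a feature by locus tag, honouring the alias map
#'
#' @param features Feature table from [read_features()].
#' @param locus_tag Locus tag or registered alias.
#' @return The matching one-row data frame.
#' @export
feature_by_locus <- function(features, locus_tag) {
  alias <- attr(features, "alias_map")
  if (!is.null(alias) && locus_tag %in% names(alias))
    locus_tag <- alias[[locus_tag]]
  hit <- features[features$locus_tag == locus_tag, , drop = FALSE]
  assert_that(nrow(hit) == 1L,
              "locus '", locus_tag, "' resolves to ", nrow(hit),
              " features (expected exactly 1)")
  hit
}

#' Read a cluster definition table
#'
#' Tab-separated with columns `name`, `first_cds_locus`, `read_direction`
#' (`forward` or `reverse`). Each cluster names the first CDS of a gene
#' cluster in its reading direction; the promoter is extracted upstream of
#' that CDS.
#'
#' @param path TSV path.
#' @return Data frame of cluster definitions.
#' @export
read_clusters <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "first_cds_locus", "read_direction")
  missing_cols <- setdiff(need, names(cl))
  assert_that(length(missing_cols) == 0L, "cluster table lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  assert_that(all(cl$read_direction %in% c("forward", "reverse")),
              "read_direction must be 'forward' or 'reverse'")
  cl
}

#' Extract the strand-aware upstream (promoter) region of a cluster
#'
#' Returns the region immediately 5' of the first CDS, oriented 5' to 3' on
#' the gene's coding strand so that its last base abuts the start codon
#' (gene-relative position -1). Forward genes take
#' `genome[start - window_len .. start - 1]` as-is; reverse genes take the
#' reverse complement of `genome[end + 1 .. end + window_len]`. The region
#' is truncated (never padded) at contig edges; extraction does not stop at
#' neighbouring genes.
#'
#' @param genome A [genome_record()] (or named list of them; the cluster's
#'   contig is selected by the feature's `contig_id`).
#' @param features Feature table from [read_features()].
#' @param cluster One-row cluster definition (or list with `name`,
#'   `first_cds_locus`, `read_direction`).
#' @param window_len Requested length in bp (default 300, which covers the
#'   most distal SurR site reported upstream of the scanned clusters).
#' @return A `promoter_region`: list with `cluster_name`, `sequence`,
#'   `window_len`, `truncated`, `strand`, `contig_id` and the genomic
#'   coordinates `genome_start`/`genome_end` of the extracted span.
#' @export
extract_upstream <- function(genome, features, cluster, window_len = 300L) {
  assert_that(is_count(window_len) && window_len >= 1, "window_len must be >= 1")
  cds <- feature_by_locus(features, cluster$first_cds_locus)
  if (inherits(genome, "genome_record")) genome <- list(genome)
  names(genome) <- vapply(genome, `[[`, "", "id")
  assert_that(cds$contig_id %in% names(genome),
              "contig '", cds$contig_id, "' not found in genome")
  g <- genome[[cds$contig_id]]
  assert_that(cds$end <= g$length, "feature '", cds$locus_tag,
              "' extends beyond contig end")
  if (!is.null(cluster$read_direction))
    assert_that(identical(cluster$read_direction, cds$strand),
                "cluster '", cluster$name, "' read_direction (",
                cluster$read_direction, ") disagrees with the strand of ",
                cds$locus_tag, " (", cds$strand, ")")
  if (cds$strand == "forward") {
    avail <- cds$start - 1L
    len <- min(window_len, avail)
    gstart <- cds$start - len
    gend <- cds$start - 1L
    seq <- if (len > 0) substr(g$sequence, gstart, gend) else ""
  } else {
    avail <- g$length - cds$end
    len <- min(window_len, avail)
    gstart <- cds$end + 1L
    gend <- cds$end + len
    seq <- if (len > 0) reverse_complement(substr(g$sequence, gstart, gend)) else ""
  }
  structure(list(cluster_name = cluster$name %||% cds$locus_tag,
                 first_cds_locus = cds$locus_tag,
                 sequence = seq, window_len = as.integer(window_len),
                 truncated = len < window_len, strand = cds$strand,
                 contig_id = cds$contig_id,
                 genome_start = if (len > 0) gstart else NA_integer_,
                 genome_end = if (len > 0) gend else NA_integer_),
            class = "promoter_region")
}

#' @export
print.promoter_region <- function(x, ...) {
  cat(sprintf("<promoter_region> %s (%s strand, %d bp%s)\n", x$cluster_name,
              x$strand, nchar(x$sequence),
              if (x$truncated) ", truncated at contig edge" else ""))
  invisible(x)
}

# Map region offsets (0-based, reading orientation) back to 1-based genomic
# coordinates. Returns c(genome_start, genome_end) of the span.
region_span_to_genome <- function(region, offset, span) {
  len <- nchar(region$sequence)
  if (region$strand == "forward") {
    c(region$genome_start + offset, region$genome_start + offset + span - 1L)
  } else {
    c(region$genome_end - offset - span + 1L, region$genome_end - offset)
  }
}

#' Assembly size after deleting a feature
#'
#' Bookkeeping helper: the genome assembly size remaining after an in-frame
#' scarless deletion of `deleted_feature_len` bp (for instance the 648 bp
#' phosphoribosyltransferase ORF removed from the parental genetic strain).
#'
#' @param genome A [genome_record()] or a length in bp.
#' @param deleted_feature_len Deleted length in bp (>= 0).
#' @return Integer bp.
#' @export
deleted_assembly_size <- function(genome, deleted_feature_len) {
  len <- if (inherits(genome, "genome_record")) genome$length else genome
  assert_that(is_count(deleted_feature_len), "deleted_feature_len must be a ",
              "nonnegative integer")
  assert_that(deleted_feature_len <= len,
              "deleted_feature_len exceeds genome length")
  as.integer(len - deleted_feature_len)
}
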