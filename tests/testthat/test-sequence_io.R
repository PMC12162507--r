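test_that("FASTA ingest uppercases, joins lines and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT"), f)
  g <- read_genome_fasta(f)
  expect_length(g, 1L)
  expect_identical(g$c1$id, "c1")
  expect_identical(g$c1$sequence, "ACGT")
  expect_identical(g$c1$length, 4L)

  writeLines(c(">c1", "acg", "tac"), f)
  g <- read_genome_fasta(f)
  expect_identical(g$c1$sequence, "ACGTAC")
  expect_identical(g$c1$length, 6L)

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), f)
  expect_error(read_genome_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_genome_fasta(f), "empty|ingest")
  expect_error(genome_record("x", "ACGQ"), "illegal")
})

test_that("synthetic multi-contig FASTA round-trips byte-identically", {
  set.seed(11)
  contigs <- list(genome_record("ctgA", random_dna(120)),
                  genome_record("ctgB", random_dna(75)))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(contigs, f1)
  back <- read_genome_fasta(f1)
  expect_identical(lapply(back, `[[`, "sequence"),
                   setNames(lapply(contigs, `[[`, "sequence"),
                            c("ctgA", "ctgB")))
  write_genome_fasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("GFF3 ingest returns CDS features with validation diagnostics", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("c1", ".", "CDS", "59761", "60765", ".", "+", ".",
                     "ID=TERMP_RS00325", sep = "\t"),
               paste("c1", ".", "CDS", "100", "300", ".", "-", ".",
                     "locus_tag=TERMP_RS99999", sep = "\t"),
               paste("c1", ".", "gene", "1", "10", ".", "+", ".",
                     "ID=skipme", sep = "\t")), f)
  feats <- read_features(f)
  expect_identical(nrow(feats), 2L)
  expect_identical(feats$locus_tag[[1]], "TERMP_RS00325")
  expect_identical(feats$start[[1]], 59761L)
  expect_identical(feats$end[[1]], 60765L)
  expect_identical(feats$strand[[1]], "forward")
  # reverse strand does not swap coordinates
  expect_identical(feats[2, c("start", "end", "strand")],
                   data.frame(start = 100L, end = 300L, strand = "reverse",
                              row.names = 2L))

  writeLines(paste("c1", ".", "CDS", "300", "100", ".", "+", ".", "ID=x",
                   sep = "\t"), f)
  expect_error(read_features(f), "line 1.*start")
  writeLines(paste("c1", ".", "CDS", "1", "9", ".", "?", ".", "ID=x",
                   sep = "\t"), f)
  expect_error(read_features(f), "strand symbol")
})

test_that("locus-tag aliases resolve to the same feature", {
  f <- withr::local_tempfile(fileext = ".gff3")
  al <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("c1", ".", "CDS", "10", "657", ".", "+", ".",
                   "locus_tag=TERMP_RS02660", sep = "\t"), f)
  writeLines("TERMP_00517\tTERMP_RS02660", al)
  feats <- read_features(f, dialect = "alias_table", alias_path = al)
  expect_identical(feature_by_locus(feats, "TERMP_00517"),
                   feature_by_locus(feats, "TERMP_RS02660"))
  writeLines("TERMP_00001\tTERMP_RS_NOPE", al)
  expect_error(read_features(f, dialect = "alias_table", alias_path = al),
               "unknown locus")
})

test_that("reverse complement is a length-preserving involution", {
  expect_identical(reverse_complement("GTT"), "AAC")
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  expect_error(reverse_complement("ACGU"), ".")
  set.seed(42)
  for (i in 1:200) {
    s <- random_dna(sample(1:80, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(nchar(reverse_complement(s)), nchar(s))
  }
})

make_feats <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$feature_kind <- "CDS"
  df
}

test_that("upstream extraction honours strand, window and contig edges", {
  set.seed(7)
  seq <- random_dna(260)
  g <- genome_record("c1", seq)
  feats <- make_feats(locus_tag = c("fwd1", "rev1"), contig_id = "c1",
                      start = c(101L, 50L), end = c(160L, 200L),
                      strand = c("forward", "reverse"))
  # forward, exact fit
  r <- extract_upstream(g, feats, list(name = "A", first_cds_locus = "fwd1",
                                       read_direction = "forward"), 100)
  expect_identical(r$sequence, substr(seq, 1, 100))
  expect_false(r$truncated)
  # reverse, truncated at the contig edge (260 - 200 = 60 available)
  r <- extract_upstream(g, feats, list(name = "B", first_cds_locus = "rev1",
                                       read_direction = "reverse"), 100)
  expect_identical(nchar(r$sequence), 60L)
  expect_true(r$truncated)
  expect_identical(r$sequence, reverse_complement(substr(seq, 201, 260)))
  expect_error(
    extract_upstream(g, feats, list(name = "C", first_cds_locus = "nope",
                                    read_direction = "forward"), 100),
    "resolves to 0")
})

test_that("a reverse-strand marker lands at the end of the extracted region", {
  # plant a marker immediately 5' of a reverse CDS; position -1 of the
  # region must abut the start codon, verified against direct indexing
  set.seed(13)
  marker <- "GTACGTAC"
  seq <- random_dna(300)
  substr(seq, 201, 208) <- reverse_complement(marker)  # genome end+1..end+8
  g <- genome_record("c1", seq)
  feats <- make_feats(locus_tag = "rev1", contig_id = "c1", start = 120L,
                      end = 200L, strand = "reverse")
  r <- extract_upstream(g, feats, list(name = "R", first_cds_locus = "rev1",
                                       read_direction = "reverse"), 80)
  expect_identical(substr(r$sequence, 73, 80), marker)
})

test_that("region-to-genome mapping is the identity under a brute-force oracle", {
  set.seed(99)
  for (case in 1:100) {
    glen <- sample(150:400, 1)
    seq <- random_dna(glen)
    g <- genome_record("c1", seq)
    strand <- sample(c("forward", "reverse"), 1)
    start <- sample(60:(glen - 60), 1)
    end <- min(glen, start + sample(10:40, 1))
    feats <- make_feats(locus_tag = "x", contig_id = "c1", start = start,
                        end = end, strand = strand)
    win <- sample(20:70, 1)
    r <- extract_upstream(g, feats, list(name = "x", first_cds_locus = "x",
                                         read_direction = strand), win)
    len <- nchar(r$sequence)
    if (len == 0) next
    # every region position re-maps to the genomic base it came from
    offs <- sample(0:(len - 1), min(5L, len))
    for (o in offs) {
      gs <- surrtools:::region_span_to_genome(r, o, 1L)
      base <- substr(seq, gs[[1]], gs[[2]])
      region_base <- substr(r$sequence, o + 1, o + 1)
      if (strand == "forward") expect_identical(region_base, base)
      else expect_identical(region_base, reverse_complement(base))
    }
  }
})

test_that("symmetric CDS pair on a palindromic contig yields identical promoters", {
  set.seed(5)
  half <- random_dna(150)
  seq <- paste0(half, reverse_complement(half))
  g <- genome_record("c1", seq)
  feats <- make_feats(locus_tag = c("f", "r"), contig_id = "c1",
                      start = c(61L, 211L), end = c(90L, 240L),
                      strand = c("forward", "reverse"))
  pf <- extract_upstream(g, feats, list(name = "f", first_cds_locus = "f",
                                        read_direction = "forward"), 40)
  pr <- extract_upstream(g, feats, list(name = "r", first_cds_locus = "r",
                                        read_direction = "reverse"), 40)
  expect_identical(pf$sequence, pr$sequence)
})

test_that("assembly size bookkeeping subtracts the deleted ORF", {
  expect_identical(deleted_assembly_size(1000L, 0L), 1000L)
  expect_identical(deleted_assembly_size(1000L, 648L), 352L)
  expect_identical(deleted_assembly_size(genome_record("c", "ACGTACGT"), 3L), 5L)
  expect_error(deleted_assembly_size(10L, 11L), "exceeds")
})
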