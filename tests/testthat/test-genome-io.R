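test_that("a hand-written GenBank record parses with correct topology, coordinates and strands", {
  gb <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(gb)
  rec <- read_genbank(gb)
  expect_s3_class(rec, "genome_record")
  expect_identical(genome_length(rec), 60L)
  expect_true(rec$circular)
  expect_identical(nrow(rec$features), 3L)
  f <- rec$features
  expect_identical(f$start[f$name == "fwd"], 10L)
  expect_identical(f$end[f$name == "fwd"], 18L)
  expect_identical(f$strand[f$name == "rev"], -1L)
  # origin-spanning join becomes a single wrapping feature with end < start
  w <- f[f$name == "wrap", ]
  expect_identical(c(w$start, w$end), c(55L, 6L))
  expect_true(w$wraps)
  expect_identical(w$length_nt, 12L)
})

test_that("wrapping CDS translates identically to manual translation of the joined spans", {
  gb <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(gb)
  rec <- read_genbank(gb)
  prot <- extract_proteins(rec)
  expect_identical(prot$protein[prot$name == "fwd"], "MK")
  expect_identical(prot$protein[prot$name == "rev"], "MKV")
  # manual: concatenate spans 55..60 and 1..6, translate, drop stop
  manual <- paste0(substr(rec$sequence, 55, 60), substr(rec$sequence, 1, 6))
  manual_aa <- as.character(Biostrings::translate(Biostrings::DNAString(manual)))
  expect_identical(prot$protein[prot$name == "wrap"],
                   sub("\\*$", "", manual_aa))
})

test_that("malformed and multi-record GenBank files raise informative errors", {
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("DEFINITION  no locus here.", "ORIGIN", "//"), bad)
  expect_error(read_genbank(bad), "LOCUS")
  multi <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(multi)
  writeLines(c(readLines(multi), readLines(multi)), multi)
  expect_error(read_genbank(multi), "multi-record")
  trunc <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 100 bp DNA circular", "ORIGIN",
               "        1 acgtacgt", "//"), trunc)
  expect_error(read_genbank(trunc), "declares")
})

test_that("GenBank write/read round trip is lossless for sequence, topology and features", {
  sim <- shared_sim()
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$record, gb)
  rec2 <- read_genbank(gb)
  expect_identical(rec2$sequence, sim$record$sequence)
  expect_identical(rec2$circular, sim$record$circular)
  expect_identical(as.data.frame(rec2$features), as.data.frame(sim$record$features))
})

test_that("FASTA and GFF3 round trips preserve names, sequences and coordinates", {
  sim <- shared_sim()
  prot <- extract_proteins(sim$record)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prot, fa)
  back <- read_fasta(fa)
  expect_identical(back$name, prot$name)
  expect_identical(back$sequence, prot$protein)
  # 60-column wrap
  expect_true(all(nchar(readLines(fa)) <= 61))

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$record, sim$record$features, gff)
  f2 <- read_gff3(gff, genome_length(sim$record))
  f2 <- f2[match(sim$record$features$name, f2$name), ]
  expect_identical(as.data.frame(f2), as.data.frame(sim$record$features))
})

test_that("a wrapping ORF is written as a two-part GFF3 feature sharing an ID", {
  seq <- random_seq(100, seed = 5)
  rec <- genome_record(seq, circular = TRUE,
                       features = tibble::tibble(name = "w", start = 91L,
                                                 end = 12L, strand = 1L))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(rec, rec$features, gff)
  body <- grep("^[^#]", readLines(gff), value = TRUE)
  expect_length(body, 2L)
  expect_true(all(grepl("ID=w", body)))
  f2 <- read_gff3(gff, 100L)
  expect_identical(c(f2$start, f2$end), c(91L, 12L))
  expect_true(f2$wraps)
})

test_that("an empty ORF set still yields a valid header-only GFF3", {
  rec <- genome_record(random_seq(200, 1), circular = TRUE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(rec, rec$features, gff)
  lines <- readLines(gff)
  expect_true(grepl("^##gff-version 3", lines[1]))
  expect_false(any(grepl("^[^#]", lines)))
  expect_identical(nrow(read_gff3(gff, 200L)), 0L)
})

test_that("rotation and flip preserve length, A+T content and per-ORF lengths", {
  sim <- shared_sim()
  rec <- sim$record
  rot <- rotate_genome(rec, 4321L)
  fl <- flip_genome(rec)
  for (x in list(rot, fl)) {
    expect_identical(genome_length(x), genome_length(rec))
    expect_identical(sort(strsplit(x$sequence, NULL)[[1]] %in% c("A", "T")),
                     sort(strsplit(rec$sequence, NULL)[[1]] %in% c("A", "T")))
    expect_identical(sort(x$features$length_nt), sort(rec$features$length_nt))
  }
  # features still translate to the same proteins
  p0 <- extract_proteins(rec)
  for (x in list(rot, fl)) {
    p <- extract_proteins(x)
    expect_identical(p$protein[order(p$name)], p0$protein[order(p0$name)])
  }
})

test_that("anchoring puts the gene's start codon at position 1, is idempotent and invertible", {
  sim <- shared_sim()
  rec <- sim$record
  # scramble: rotate and flip first
  scr <- flip_genome(rotate_genome(rec, 7777L))
  for (gene in c("orf3", "orf9")) {
    anc <- anchor_to_gene(scr, gene)
    i <- which(anc$features$name == gene)
    expect_identical(anc$features$start[i], 1L)
    expect_identical(anc$features$strand[i], 1L)
    expect_identical(substr(anc$sequence, 1, 3), "ATG")
    # idempotent
    anc2 <- anchor_to_gene(anc, gene)
    expect_identical(anc2$sequence, anc$sequence)
    expect_identical(as.data.frame(anc2$features), as.data.frame(anc$features))
  }
  # anchoring on orf1 recovers the original record (it was laid out anchored)
  back <- anchor_to_gene(scr, "orf1")
  expect_identical(back$sequence, rec$sequence)
  expect_error(anchor_to_gene(rec, "nonexistent"), "not found")
})

test_that("translation handles N codons, reverse strands and internal stops", {
  rec <- genome_record("ATGAAATAA", circular = FALSE,
                       features = tibble::tibble(name = "a", start = 1L,
                                                 end = 9L, strand = 1L))
  expect_identical(extract_proteins(rec)$protein, "MK")
  # N in a codon translates to X
  recn <- genome_record("ATGAANTAA", circular = FALSE,
                        features = tibble::tibble(name = "a", start = 1L,
                                                  end = 9L, strand = 1L))
  expect_identical(extract_proteins(recn)$protein, "MX")
  # internal stop: warning + truncation
  reci <- genome_record("ATGTAAAAATAA", circular = FALSE,
                        features = tibble::tibble(name = "a", start = 1L,
                                                  end = 12L, strand = 1L))
  expect_warning(p <- extract_proteins(reci), "internal stop")
  expect_identical(p$protein, "M")
})
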