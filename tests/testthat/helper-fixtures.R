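# Fixtures built in code: random sequences and a minimal hand-written
# GenBank flat file.

random_seq <- function(len, seed, at = 0.6) {
  set.seed(seed)
  p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# hand-written GenBank record: 60 bp circle with a forward CDS (4..12),
# a reverse-complement CDS (20..34) and a CDS joined across the origin
# (55..60 + 1..6). The sequences behind each CDS are planted explicitly.
write_toy_genbank <- function(path) {
  b <- strsplit(strrep("C", 60), NULL)[[1]]
  b[10:18] <- strsplit("ATGAAATAA", NULL)[[1]]
  # reverse CDS: revcomp("ATGAAAGTTTAA") planted at 25..36 -> protein "MKV"
  b[25:36] <- strsplit(paste(rev(strsplit(chartr("ACGT", "TGCA", "ATGAAAGTTTAA"), NULL)[[1]]), collapse = ""), NULL)[[1]]
  b[55:60] <- strsplit("ATGCAT", NULL)[[1]]   # wrap CDS part 1
  b[1:6] <- strsplit("GGATAA", NULL)[[1]]     # wrap CDS part 2 -> MHG
  seq <- paste(b, collapse = "")
  lines <- c(
    "LOCUS       TOY001 60 bp    DNA     circular VRL 01-JAN-2000",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             10..18",
    "                     /gene=\"fwd\"",
    "     CDS             complement(25..36)",
    "                     /gene=\"rev\"",
    "     CDS             join(55..60,1..6)",
    "                     /gene=\"wrap\"",
    "ORIGIN",
    paste0("        1 ", paste(substring(tolower(seq), seq(1, 60, 10), seq(10, 60, 10)), collapse = " ")),
    "//"
  )
  writeLines(lines, path)
  invisible(seq)
}

# small simulated genome shared by several tests (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(
        sim_genome_config(genome_length = 15000L, n_orfs = 15L,
                          orf_length_range = c(150L, 900L)),
        seed = 42L, id = "shared")
    }
    cache
  }
})
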