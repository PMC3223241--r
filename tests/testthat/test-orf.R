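test_that("a minimal linear ORF is found with the stop codon counted in its length", {
  rec <- genome_record("ATGAAATAA", circular = FALSE)
  cand <- enumerate_orfs(rec, min_codons = 2L)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$start, 1L)
  expect_identical(cand$end, 9L)
  expect_identical(cand$length_nt, 9L)
  expect_identical(cand$strand, 1L)
})

test_that("enumeration matches the brute-force per-position oracle on random circular sequences", {
  for (seed in 1:6) {
    len <- sample(c(900L, 1500L, 2400L), 1L)
    seq <- random_seq(len, seed = seed, at = 0.55 + 0.1 * (seed %% 2))
    rec <- genome_record(seq, circular = TRUE)
    got <- enumerate_orfs(rec, min_codons = 20L)
    want <- oracle_orfs(seq, circular = TRUE, min_codons = 20L)
    expect_identical(orf_key(got), orf_key(want))
  }
  # linear case too
  seq <- random_seq(1200L, seed = 99)
  expect_identical(orf_key(enumerate_orfs(genome_record(seq, circular = FALSE), 15L)),
                   orf_key(oracle_orfs(seq, circular = FALSE, min_codons = 15L)))
})

test_that("the candidate set is invariant under rotation of the circular genome", {
  seq <- random_seq(2000L, seed = 17)
  rec <- genome_record(seq, circular = TRUE)
  cand <- enumerate_orfs(rec, 15L)
  for (shift in c(1L, 700L, 1999L)) {
    rot <- rotate_genome(rec, shift)
    cand_r <- enumerate_orfs(rot, 15L)
    # map rotated coordinates back
    back_start <- ((cand_r$start + shift - 2L) %% 2000L) + 1L
    back_end <- ((cand_r$end + shift - 2L) %% 2000L) + 1L
    expect_identical(sort(paste(back_start, back_end, cand_r$strand)),
                     sort(paste(cand$start, cand$end, cand$strand)))
  }
})

test_that("greedy selection drops the shorter of two heavily overlapping ORFs unless rescued", {
  cand <- tibble::tibble(start = c(100L, 250L), end = c(700L, 449L),
                         strand = c(1L, 1L), frame = c(0L, 0L),
                         length_nt = c(601L, 200L), wraps = c(FALSE, FALSE))
  sel <- select_orfs(cand, genome_length = 1000L, max_overlap_bp = 47L)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$length_nt, 601L)
  # homology rescue keeps both
  sel2 <- select_orfs(cand, genome_length = 1000L, max_overlap_bp = 47L,
                      rescued = c(FALSE, TRUE))
  expect_identical(nrow(sel2), 2L)
  # overlap below the threshold also keeps both
  cand$start[2] <- 660L
  cand$end[2] <- 859L
  sel3 <- select_orfs(cand, genome_length = 1000L, max_overlap_bp = 47L)
  expect_identical(nrow(sel3), 2L)
})

test_that("selection recovers exactly the planted ORFs of a synthetic genome", {
  sim <- shared_sim()
  cand <- enumerate_orfs(sim$record, min_codons = 50L)
  sel <- select_orfs(cand, genome_length(sim$record))
  tr <- sim$truth$orfs
  expect_setequal(paste(sel$start, sel$end, sel$strand),
                  paste(tr$start, tr$end, tr$strand))
  # names follow genome order
  expect_identical(sel$name, paste0("orf", seq_len(nrow(sel))))
})

test_that("adjacent-overlap table equals brute-force per-base intersection on random intervals", {
  set.seed(31)
  L <- 500L
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    start <- sort(sample.int(L, n))
    len <- sample(20:120, n, replace = TRUE)
    o <- tibble::tibble(name = paste0("x", seq_len(n)), start = start,
                        end = ((start + len - 2L) %% L) + 1L,
                        strand = 1L)
    got <- overlap_table(o, L, circular = TRUE)
    pos <- function(s, e) if (e >= s) s:e else c(s:L, 1:e)
    o2 <- o[order(o$start), ]
    for (k in seq_len(n)) {
      j <- if (k < n) k + 1L else 1L
      want <- length(intersect(pos(o2$start[k], o2$end[k]),
                               pos(o2$start[j], o2$end[j])))
      expect_identical(got$overlap_bp[k], as.integer(want))
    }
  }
})

test_that("adjacent disjoint ORFs have zero overlap and circular adjacency closes the circle", {
  o <- tibble::tibble(name = c("a", "b", "c"),
                      start = c(10L, 200L, 400L), end = c(100L, 300L, 480L),
                      strand = 1L)
  tab <- overlap_table(o, 500L, circular = TRUE)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$overlap_bp == 0L))
  expect_identical(tab$name_a[3], "c")
  expect_identical(tab$name_b[3], "a")
  # linear adjacency omits the closing pair
  expect_identical(nrow(overlap_table(o, 500L, circular = FALSE)), 2L)
})

test_that("genome statistics match planted truth and satisfy the coding-percent inequality", {
  sim <- shared_sim()
  tr <- sim$truth$orfs
  st <- genome_stats(sim$record, tr)
  expect_identical(st$length_bp, 15000L)
  expect_identical(st$n_orfs, nrow(tr))
  expect_identical(st$n_fwd, sum(tr$strand > 0))
  expect_identical(st$n_rev, sum(tr$strand < 0))
  expect_identical(st$n_fwd + st$n_rev, st$n_orfs)
  # planted ORFs are non-overlapping: union equals sum
  expect_equal(st$coding_pct_union, st$coding_pct_sum)
  expect_equal(st$coding_pct_sum,
               round(100 * sum(tr$length_nt) / 15000, 1), tolerance = 0.051)
  # A+T close to the configured 61% target
  expect_lt(abs(st$at_pct - 61), 1.5)

  # overlapping set: union strictly below sum
  o <- tibble::tibble(name = c("a", "b"), start = c(1L, 50L),
                      end = c(100L, 150L), strand = 1L)
  rec <- genome_record(random_seq(300, 2), circular = TRUE)
  o$wraps <- FALSE; o$length_nt <- c(100L, 101L)
  st2 <- genome_stats(rec, o)
  expect_lt(st2$coding_pct_union, st2$coding_pct_sum)
  expect_identical(st2$n_minimal_overlaps, 0L)   # 51 bp > 47
  st3 <- genome_stats(rec, o, max_minimal_overlap = 60L)
  expect_identical(st3$n_minimal_overlaps, 1L)
})

test_that("an empty ORF set gives zero coverage and zero counts", {
  rec <- genome_record(random_seq(400, 3), circular = TRUE)
  st <- genome_stats(rec, rec$features)
  expect_identical(st$n_orfs, 0L)
  expect_identical(st$coding_pct_sum, 0)
  expect_identical(st$coding_pct_union, 0)
  expect_identical(st$n_minimal_overlaps, 0L)
})

test_that("percentages are rounded half-up to one decimal", {
  expect_identical(baculoannot:::round_half_up(61.25, 1), 61.3)
  expect_identical(baculoannot:::round_half_up(61.24, 1), 61.2)
  expect_identical(baculoannot:::round_half_up(86.35, 1), 86.4)
})
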