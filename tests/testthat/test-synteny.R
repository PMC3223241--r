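test_that("self comparison yields the full main diagonal and every match verifies by substring", {
  seq <- random_seq(400, seed = 12)
  dp <- dotplot(seq, seq, word_size = 8L)
  diag <- dp$matches[dp$matches$strand == "+" & dp$matches$pos_a == dp$matches$pos_b, ]
  expect_identical(nrow(diag), 400L - 8L + 1L)
  # spot-verify reported matches by direct substring comparison
  m <- dp$matches[sample.int(nrow(dp$matches), min(50, nrow(dp$matches))), ]
  for (k in seq_len(nrow(m))) {
    wa <- substr(seq, m$pos_a[k], m$pos_a[k] + 7L)
    wb <- substr(seq, m$pos_b[k], m$pos_b[k] + 7L)
    if (m$strand[k] == "+") expect_identical(wa, wb)
    else expect_identical(wa, baculoannot:::revcomp(wb))
  }
})

test_that("a planted inverted segment shows up as an anti-diagonal run at the planted coordinates", {
  a <- random_seq(600, seed = 21)
  # b = a with segment 201..320 reverse-complemented
  seg <- baculoannot:::revcomp(substr(a, 201, 320))
  b <- paste0(substr(a, 1, 200), seg, substr(a, 321, 600))
  dp <- dotplot(a, b, word_size = 10L)
  runs <- dotplot_runs(dp, min_len = 40L)
  rev_runs <- runs[runs$strand == "-", ]
  expect_gte(nrow(rev_runs), 1L)
  main <- rev_runs[which.max(rev_runs$length), ]
  expect_identical(c(main$start_a, main$end_a), c(201L, 320L))
  expect_identical(c(main$start_b, main$end_b), c(201L, 320L))
  # the flanks remain forward-collinear
  fwd <- runs[runs$strand == "+", ]
  expect_true(any(fwd$start_a == 1L & fwd$end_a >= 190L))
})

test_that("dotplot(A,B) is the coordinate transpose of dotplot(B,A)", {
  a <- random_seq(300, seed = 33)
  b <- paste0(substr(a, 101, 300), random_seq(80, 34))
  d1 <- dotplot(a, b, word_size = 8L)$matches
  d2 <- dotplot(b, a, word_size = 8L)$matches
  expect_setequal(paste(d1$pos_a, d1$pos_b, d1$strand),
                  paste(d2$pos_b, d2$pos_a, d2$strand))
})

test_that("gene-order vectors are signed by strand and ordered along the genome", {
  ortho <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g1", "g2", "g3"),
    genome = c(rep("F", 3), rep("X", 3)),
    ortholog = c("g1", "g2", "g3", "x1", "x2", "x3"),
    order_index = c(1L, 2L, 3L, 2L, 1L, 3L),
    strand = c(1L, 1L, 1L, -1L, 1L, 1L)
  )
  vF <- gene_order_vector(ortho, "F", c("g1", "g2", "g3"))
  expect_identical(unname(vF), 1:3)
  vX <- gene_order_vector(ortho, "X", c("g1", "g2", "g3"))
  expect_identical(unname(vX), c(2L, -1L, 3L))
  expect_identical(names(vX), c("g2", "g1", "g3"))
})

test_that("an inverted block flips signs and reverses order in the gene-order vector", {
  v <- c(a = 1L, b = 2L, c = 3L, d = 4L, e = 5L, f = 6L)
  w <- v
  w[3:5] <- -rev(v[3:5])      # invert genes 3..5
  names(w)[3:5] <- rev(names(v)[3:5])
  expect_identical(unname(w), c(1L, 2L, -5L, -4L, -3L, 6L))
  runs <- conserved_runs(list(v, w))
  # two breakpoints around the inverted block: runs split at its edges,
  # but the block itself stays one conserved run
  blocks <- split(runs$gene, runs$run)
  expect_true(any(vapply(blocks, function(b) identical(b, c("c", "d", "e")), logical(1))))
  expect_identical(length(blocks), 3L)
})

test_that("identical vectors give one run covering the whole gene set", {
  v <- c(a = 1L, b = -2L, c = 3L, d = 4L)
  runs <- conserved_runs(list(v, v, v))
  expect_identical(max(runs$run), 1L)
  expect_identical(runs$gene, names(v))
})

test_that("a single planted breakpoint splits the order into exactly two runs, verified brute-force", {
  v <- stats::setNames(1:8, letters[1:8])
  # transpose the tail block after position 4 to the front (one internal breakpoint)
  w <- c(v[5:8], v[1:4])
  runs <- conserved_runs(list(v, w))
  expect_identical(max(runs$run), 2L)
  expect_identical(unname(split(runs$gene, runs$run)[[1]]), letters[1:4])
  # brute force: every reported run must occur contiguously (fwd or rev) in w
  for (b in split(runs$index, runs$run)) {
    ok <- FALSE
    for (s in seq_len(length(w) - length(b) + 1L)) {
      seg <- unname(w[s:(s + length(b) - 1L)])
      if (identical(seg, b) || identical(seg, -rev(b))) ok <- TRUE
    }
    expect_true(ok)
  }
})

test_that("run finding is independent of the order in which the non-focal genomes are given", {
  set.seed(55)
  v <- stats::setNames(sample(c(-1L, 1L), 10, TRUE) * 1:10, paste0("g", 1:10))
  w1 <- c(v[3:10], v[1:2])
  w2 <- v; w2[4:6] <- -rev(w2[4:6]); names(w2)[4:6] <- rev(names(w2)[4:6])
  r12 <- conserved_runs(list(v, w1, w2))
  r21 <- conserved_runs(list(v, w2, w1))
  expect_identical(r12, r21)
})

test_that("breakpoint distance satisfies identity, symmetry and reversal-invariance on random vectors", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    v1 <- sample(c(-1L, 1L), n, TRUE) * sample.int(n)
    v2 <- sample(c(-1L, 1L), n, TRUE) * sample.int(n)
    expect_identical(breakpoint_distance(v1, v1), 0L)
    expect_identical(breakpoint_distance(v1, v2), breakpoint_distance(v2, v1))
    expect_identical(breakpoint_distance(v1, -rev(v1)), 0L)
    expect_gte(breakpoint_distance(v1, v2), 0L)
  }
  expect_error(breakpoint_distance(c(a = 1L), c(b = 2L)), "no genes")
})

test_that("breakpoint distance of a transposed block equals exhaustive adjacency counting", {
  v <- 1:9
  w <- c(1:3, 7:8, 4:6, 9L)     # block 7..8 moved
  adj <- function(x) {
    a <- x[-length(x)]; b <- x[-1]
    k1 <- paste(a, b); k2 <- paste(-b, -a)
    ifelse(k1 <= k2, k1, k2)
  }
  want <- sum(!(adj(v) %in% adj(w)))
  expect_identical(breakpoint_distance(v, w), as.integer(want))
  expect_identical(breakpoint_distance(v, w), 3L)
})

test_that("rearrangements recorded by the panel simulator are recovered as breakpoints", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  sp <- simulate_panel(tr, sim_panel_config(n_genes = 10, subst_rate = 0,
                                            inversion_rate = 1), seed = 19)
  vA <- gene_order_vector(sp$ortholog_table, "A", sp$focal_genes)
  vB <- gene_order_vector(sp$ortholog_table, "B", sp$focal_genes)
  # distance consistent with an independent per-adjacency comparison
  adj <- function(x) {
    a <- x[-length(x)]; b <- x[-1]
    k1 <- paste(a, b); k2 <- paste(-b, -a)
    ifelse(k1 <= k2, k1, k2)
  }
  expect_identical(breakpoint_distance(vA, vB),
                   as.integer(sum(!(adj(unname(vA)) %in% adj(unname(vB))))))
  # zero divergence, zero rearrangement: identity everywhere
  sp0 <- simulate_panel(tr, sim_panel_config(n_genes = 6, subst_rate = 0), seed = 3)
  v0A <- gene_order_vector(sp0$ortholog_table, "A", sp0$focal_genes)
  v0B <- gene_order_vector(sp0$ortholog_table, "B", sp0$focal_genes)
  expect_identical(breakpoint_distance(v0A, v0B), 0L)
  runs <- conserved_runs(list(v0A, v0B))
  expect_identical(max(runs$run), 1L)
})
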