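# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimised code paths.

# ---- brute-force ORF scanner: tests every position independently ----
# Walks codon by codon from every ATG until the first stop, on both strands,
# then keeps the longest ORF per stop codon. Returns start/end/strand rows in
# the package's coordinate convention.
oracle_orfs <- function(seq, circular, min_codons) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand > 0L) seq else {
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), NULL)[[1]]), collapse = "")
    }
    base <- strsplit(s, NULL)[[1]]
    codon_of <- function(p) {
      idx <- (p - 1L + 0:2) %% L + 1L
      if (!circular && any((p + 0:2) > L)) return(NA_character_)
      paste(base[idx], collapse = "")
    }
    hits <- list()
    for (p in seq_len(L)) {
      if (is.na(codon_of(p)) || codon_of(p) != "ATG") next
      q <- p
      steps <- 0L
      found <- NA_integer_
      while (steps <= L %/% 3L) {
        cq <- codon_of(q)
        if (is.na(cq)) break
        if (cq %in% stops) { found <- q; break }
        q <- if (circular) (q - 1L + 3L) %% L + 1L else q + 3L
        steps <- steps + 1L
      }
      if (is.na(found)) next
      len <- if (circular) ((found - p) %% L) + 3L else found - p + 3L
      if (len > L) next
      hits[[length(hits) + 1L]] <- c(p = p, stop = found, len = len)
    }
    if (length(hits) == 0L) next
    h <- do.call(rbind, hits)
    # longest ORF per stop codon
    h <- h[order(h[, "stop"], -h[, "len"]), , drop = FALSE]
    h <- h[!duplicated(h[, "stop"]), , drop = FALSE]
    h <- h[h[, "len"] >= 3L * min_codons, , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      p <- h[r, "p"]; len <- h[r, "len"]
      if (strand > 0L) {
        st <- p
        en <- ((p + len - 2L) %% L) + 1L
        en <- ((p - 1L + len - 1L) %% L) + 1L
      } else {
        last <- ((p - 1L + len - 1L) %% L) + 1L   # strand coords
        st <- L - last + 1L
        en <- L - p + 1L
      }
      out[[length(out) + 1L]] <- data.frame(start = st, end = en,
                                            strand = strand, length_nt = len)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = integer(), length_nt = integer()))
  }
  do.call(rbind, out)
}

orf_key <- function(d) sort(paste(d$start, d$end, d$strand, d$length_nt))

# ---- naive affine-gap Smith-Waterman, score only ----
# A gap of length k costs open + k * ext (BLAST convention).
oracle_sw_score <- function(a, b, open = 11, ext = 1) {
  B <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  av <- strsplit(a, NULL)[[1]]
  bv <- strsplit(b, NULL)[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)
  Iy <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- B[av[i], bv[j]]
      M[i + 1L, j + 1L] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) + sub
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext, Ix[i, j + 1L] - ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext, Iy[i + 1L, j] - ext)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# ---- naive global Needleman-Wunsch with linear gaps, score only ----
oracle_nw_score <- function(a, b, gap = -8) {
  B <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  av <- strsplit(a, NULL)[[1]]
  bv <- strsplit(b, NULL)[[1]]
  n <- length(av); m <- length(bv)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- max(D[i, j] + B[av[i], bv[j]],
                               D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
    }
  }
  D[n + 1L, m + 1L]
}

# sum-of-pairs score of a pairwise alignment under the same scoring
aln_pair_score <- function(x, y, gap = -8) {
  B <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  xv <- strsplit(x, NULL)[[1]]
  yv <- strsplit(y, NULL)[[1]]
  s <- 0
  for (k in seq_along(xv)) {
    s <- s + if (xv[k] == "-" && yv[k] == "-") 0
             else if (xv[k] == "-" || yv[k] == "-") gap
             else B[xv[k], yv[k]]
  }
  s
}

# ---- exhaustive parsimony via phangorn over all topologies ----
sm_to_phydat <- function(sm) {
  mat <- do.call(rbind, strsplit(unname(sm$seqs), NULL))
  rownames(mat) <- names(sm$seqs)
  phangorn::phyDat(mat, type = "AA")
}

exhaustive_parsimony <- function(sm) {
  pd <- sm_to_phydat(sm)
  trees <- phangorn::allTrees(length(sm$taxa), rooted = FALSE,
                              tip.label = sm$taxa)
  scores <- vapply(trees, function(t) phangorn::fitch(t, pd), numeric(1))
  list(min = min(scores), trees = trees, scores = scores)
}

# random amino-acid supermatrix over AA letters + gaps
random_supermatrix <- function(ntaxa, ncols, seed, p_gap = 0.1) {
  set.seed(seed)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","K","L")
  taxa <- paste0("t", seq_len(ntaxa))
  seqs <- vapply(taxa, function(t) {
    chars <- sample(aa, ncols, replace = TRUE)
    chars[runif(ncols) < p_gap] <- "-"
    paste(chars, collapse = "")
  }, "")
  concatenate(list(g1 = seqs))
}

# unrooted-topology equality
same_topology <- function(t1, t2) {
  canonical_newick(ape::unroot(t1)) == canonical_newick(ape::unroot(t2))
}
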