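# Progressive multiple alignment of protein families and supermatrix
# concatenation. The aligner is deliberately simple and fully deterministic:
# pairwise k-mer distances -> UPGMA guide tree -> profile-profile
# Needleman-Wunsch with sum-of-pairs substitution scores and a linear gap
# penalty. With two sequences it reduces exactly to pairwise global alignment.

MSA_ALPHA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
               "S","T","W","Y","V","B","J","Z","X","*","-")

# substitution lookup over MSA_ALPHA: BLOSUM62 extended with a gap character
msa_score_matrix <- function(matrix = "BLOSUM62", gap = -8) {
  B <- aa_matrix(matrix)
  n <- length(MSA_ALPHA)
  M <- matrix(0, n, n, dimnames = list(MSA_ALPHA, MSA_ALPHA))
  res <- setdiff(MSA_ALPHA, "-")
  M[res, res] <- B[res, res]
  M["-", res] <- gap
  M[res, "-"] <- gap
  M["-", "-"] <- 0
  M
}

# alignment block (character matrix rows=seqs) -> residue frequency profile
block_profile <- function(block) {
  n <- length(MSA_ALPHA)
  f <- matrix(0, n, ncol(block), dimnames = list(MSA_ALPHA, NULL))
  for (i in seq_len(nrow(block))) {
    idx <- match(block[i, ], MSA_ALPHA)
    idx[is.na(idx)] <- match("X", MSA_ALPHA)
    f[cbind(idx, seq_len(ncol(block)))] <- f[cbind(idx, seq_len(ncol(block)))] + 1
  }
  f / nrow(block)
}

# align two alignment blocks; returns merged character matrix (rows stacked)
align_profiles <- function(A, B, M) {
  fa <- block_profile(A)
  fb <- block_profile(B)
  S <- t(fa) %*% M %*% fb                 # column-pair scores
  gapA <- as.numeric(t(fa) %*% M[, "-"])  # cost of A-column vs all-gap
  gapB <- as.numeric(t(fb) %*% M[, "-"])
  n <- ncol(A); m <- ncol(B)
  D <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)         # 1 diag, 2 up (gap in B), 3 left
  D[, 1] <- cumsum(c(0, gapA))
  D[1, ] <- cumsum(c(0, gapB))
  P[-1, 1] <- 2L
  P[1, -1] <- 3L
  for (i in seq_len(n)) {
    di <- D[i, ]
    row <- numeric(m + 1L)
    prow <- integer(m + 1L)
    row[1] <- D[i + 1L, 1]
    prow[1] <- 2L
    for (j in seq_len(m)) {
      d <- di[j] + S[i, j]
      u <- di[j + 1L] + gapA[i]
      l <- row[j] + gapB[j]
      # tie-break: diagonal > up > left
      if (d >= u && d >= l) { row[j + 1L] <- d; prow[j + 1L] <- 1L }
      else if (u >= l)      { row[j + 1L] <- u; prow[j + 1L] <- 2L }
      else                  { row[j + 1L] <- l; prow[j + 1L] <- 3L }
    }
    D[i + 1L, ] <- row
    P[i + 1L, ] <- prow
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  colsA <- integer(0); colsB <- integer(0)   # 0 = gap column
  while (i > 1L || j > 1L) {
    mv <- P[i, j]
    if (mv == 1L) { colsA <- c(i - 1L, colsA); colsB <- c(j - 1L, colsB); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) { colsA <- c(i - 1L, colsA); colsB <- c(0L, colsB); i <- i - 1L }
    else { colsA <- c(0L, colsA); colsB <- c(j - 1L, colsB); j <- j - 1L }
  }
  take <- function(block, cols) {
    out <- matrix("-", nrow(block), length(cols))
    nz <- cols > 0L
    out[, nz] <- block[, cols[nz], drop = FALSE]
    out
  }
  merged <- rbind(take(A, colsA), take(B, colsB))
  attr(merged, "score") <- D[n + 1L, m + 1L]
  merged
}

# fraction of shared k-mers -> distance in [0,1]
kmer_distance <- function(a, b, k = 3L) {
  ka <- substring(a, 1:max(1L, nchar(a) - k + 1L), k:max(k, nchar(a)))
  kb <- substring(b, 1:max(1L, nchar(b) - k + 1L), k:max(k, nchar(b)))
  1 - 2 * length(intersect(ka, kb)) / (length(unique(ka)) + length(unique(kb)))
}

#' Progressive multiple sequence alignment of a protein family
#'
#' Builds a UPGMA guide tree from pairwise k-mer distances and merges profiles
#' along it with global profile-profile dynamic programming (sum-of-pairs
#' substitution score, linear gap penalty). Entirely deterministic: ties in the
#' dynamic program prefer substitution over gap-in-second over gap-in-first.
#' For exactly two sequences the result is the optimal pairwise global
#' alignment under the same scoring.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap Linear gap penalty per residue-vs-gap column (default -8).
#' @param k k-mer size for the guide-tree distances.
#' @return Named character vector of aligned sequences (equal lengths, input
#'   order preserved).
#' @export
progressive_msa <- function(seqs, matrix = "BLOSUM62", gap = -8, k = 3L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  M <- msa_score_matrix(matrix, gap)
  n <- length(seqs)
  blocks <- lapply(seqs, function(s) matrix(strsplit(s, NULL)[[1]], nrow = 1))
  if (n == 2L) {
    merged <- align_profiles(blocks[[1]], blocks[[2]], M)
    rows <- c(1L, 2L)
  } else {
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) dm[i, j] <- dm[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k)
    }
    hc <- stats::hclust(stats::as.dist(dm), method = "average")  # UPGMA
    node_block <- vector("list", n - 1L)
    node_rows <- vector("list", n - 1L)
    for (s in seq_len(n - 1L)) {
      pick <- function(x) {
        if (x < 0L) list(block = blocks[[-x]], rows = -x)
        else list(block = node_block[[x]], rows = node_rows[[x]])
      }
      a <- pick(hc$merge[s, 1])
      b <- pick(hc$merge[s, 2])
      node_block[[s]] <- align_profiles(a$block, b$block, M)
      node_rows[[s]] <- c(a$rows, b$rows)
    }
    merged <- node_block[[n - 1L]]
    rows <- node_rows[[n - 1L]]
  }
  aligned <- apply(merged, 1, paste, collapse = "")
  stats::setNames(aligned[order(rows)], names(seqs)[rows][order(rows)])
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are placed in canonical (alphabetical) order so the result does not
#' depend on input order. A taxon missing from a gene is padded with gaps for
#' that partition and recorded; a taxon present in no gene is dropped with a
#' warning.
#'
#' @param alignments Named list: gene -> named character vector of aligned
#'   sequences (equal length within a gene).
#' @param trim_gap_frac If set (e.g. 0.5), alignment columns whose gap
#'   fraction exceeds this value are dropped per gene before concatenation;
#'   `NULL` (default) keeps every column.
#' @return A `supermatrix` object: list with `taxa`, `seqs` (named character
#'   vector), `partitions` (tibble `gene`, `start`, `end`) and `padded`
#'   (tibble `gene`, `taxon` of gap-padded cells).
#' @export
concatenate <- function(alignments, trim_gap_frac = NULL) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  alignments <- alignments[order(names(alignments))]
  if (!is.null(trim_gap_frac)) {
    alignments <- lapply(alignments, function(a) {
      m <- do.call(rbind, strsplit(unname(a), NULL))
      keep <- colMeans(m == "-") <= trim_gap_frac
      stats::setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                      names(a))
    })
  }
  taxa <- sort(unique(unlist(lapply(alignments, names))))
  widths <- vapply(alignments, function(a) nchar(a[[1]]), integer(1))
  for (g in names(alignments)) {
    if (!all(nchar(alignments[[g]]) == widths[[g]])) {
      rlang::abort(paste0("alignment '", g, "' has unequal sequence lengths"))
    }
  }
  padded <- list()
  rowstr <- stats::setNames(rep("", length(taxa)), taxa)
  for (g in names(alignments)) {
    a <- alignments[[g]]
    for (t in taxa) {
      if (t %in% names(a)) {
        rowstr[t] <- paste0(rowstr[t], a[[t]])
      } else {
        rowstr[t] <- paste0(rowstr[t], strrep("-", widths[[g]]))
        padded[[length(padded) + 1L]] <- tibble::tibble(gene = g, taxon = t)
      }
    }
  }
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  all_gap <- vapply(rowstr, function(s) s == strrep("-", nchar(s)), logical(1))
  if (any(all_gap)) {
    rlang::warn(paste0("taxa present in no gene excluded: ",
                       paste(taxa[all_gap], collapse = ", ")))
    rowstr <- rowstr[!all_gap]
    taxa <- taxa[!all_gap]
  }
  structure(
    list(taxa = taxa, seqs = rowstr,
         partitions = tibble::tibble(gene = names(alignments),
                                     start = as.integer(starts),
                                     end = as.integer(ends)),
         padded = dplyr::bind_rows(padded)),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partition(s)\n",
              length(x$taxa), nchar(x$seqs[[1]]), nrow(x$partitions)))
  invisible(x)
}
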