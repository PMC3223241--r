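# Protein similarity engine: exact local alignment, reciprocal best hits and
# gene classification over a genome panel. Alignment itself is delegated to
# Biostrings' Smith-Waterman (affine gaps); a length-k gap costs
# gap_open + k * gap_extend, matching the BLASTP convention for 11/1.

.aa_matrix_cache <- new.env(parent = emptyenv())

aa_matrix <- function(name = "BLOSUM62") {
  if (is.null(.aa_matrix_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .aa_matrix_cache[[name]] <- get(name, envir = e)
  }
  .aa_matrix_cache[[name]]
}

check_protein <- function(x, arg) {
  if (length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    rlang::abort(paste0("'", arg, "' must be a non-empty protein sequence"))
  }
  invisible(TRUE)
}

#' Optimal local protein alignment
#'
#' Exact Smith-Waterman with affine gap penalties. Percent identity is
#' computed over aligned columns in which neither sequence has a gap (the
#' convention behind statements like "43% identity over 140 aa"); the reported
#' `aligned_len` is the number of alignment columns including gaps.
#'
#' @param a,b Protein sequences (single strings over the 20 amino acids + X).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1).
#' @return One-row tibble: `score`, `identity_pct`, `aligned_len`,
#'   `start_a`, `end_a`, `start_b`, `end_b`.
#' @export
align_local <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  check_protein(a, "a")
  check_protein(b, "b")
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = aa_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pstr <- strsplit(as.character(Biostrings::alignedPattern(pa)), NULL)[[1]]
  sstr <- strsplit(as.character(Biostrings::alignedSubject(pa)), NULL)[[1]]
  cols <- pstr != "-" & sstr != "-"
  ident <- if (any(cols)) 100 * sum(pstr[cols] == sstr[cols]) / sum(cols) else 0
  tibble::tibble(
    score = Biostrings::score(pa),
    identity_pct = ident,
    aligned_len = length(pstr),
    start_a = IRanges::start(Biostrings::pattern(pa)),
    end_a = IRanges::end(Biostrings::pattern(pa)),
    start_b = IRanges::start(Biostrings::subject(pa)),
    end_b = IRanges::end(Biostrings::subject(pa))
  )
}

# all-vs-all local alignment score matrix (rows = proteome A, cols = B);
# scoreOnly avoids the per-pair traceback cost
proteome_score_matrix <- function(pa, pb, matrix, gap_open, gap_extend) {
  paset <- Biostrings::AAStringSet(pa)
  M <- aa_matrix(matrix)
  sc <- vapply(pb, function(b) {
    Biostrings::pairwiseAlignment(paset, b, type = "local",
                                  substitutionMatrix = M,
                                  gapOpening = gap_open,
                                  gapExtension = gap_extend, scoreOnly = TRUE)
  }, numeric(length(pa)))
  matrix(sc, nrow = length(pa), dimnames = list(names(pa), names(pb)))
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is reported iff b is a's unique highest-scoring hit, a is b's
#' unique highest-scoring hit, and the score reaches `min_score` with at least
#' `min_aln_len` aligned columns. Ties for best hit disqualify a protein (the
#' uniqueness clause), so decoy paralogs drop the pair rather than misassign
#' it. The result is symmetric in the order of the two proteomes and
#' independent of the ordering of proteins within each.
#'
#' @param proteome_a,proteome_b Named character vectors (or tibbles with
#'   `name`/`protein` columns) of protein sequences.
#' @param min_score Minimum alignment score (default 50).
#' @param min_aln_len Minimum alignment length in columns (default 30).
#' @inheritParams align_local
#' @return Tibble `protein_a`, `protein_b`, `score`, `identity_pct`,
#'   `aligned_len`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, min_score = 50,
                                 min_aln_len = 30L, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1) {
  as_named <- function(p) {
    if (is.data.frame(p)) stats::setNames(p$protein, p$name) else p
  }
  pa <- as_named(proteome_a)
  pb <- as_named(proteome_b)
  if (length(pa) == 0L || length(pb) == 0L) rlang::abort("proteomes must be non-empty")
  sc <- proteome_score_matrix(pa, pb, matrix, gap_open, gap_extend)

  # unique (untied) best hit of each row / column
  row_best <- apply(sc, 1, function(x) {
    i <- which(x == max(x))
    if (length(i) == 1L) i else NA_integer_
  })
  col_best <- apply(sc, 2, function(x) {
    i <- which(x == max(x))
    if (length(i) == 1L) i else NA_integer_
  })
  ia <- which(!is.na(row_best) & col_best[row_best] == seq_along(pa))
  pairs <- purrr::map_dfr(ia, function(i) {
    j <- row_best[i]
    if (sc[i, j] < min_score) return(NULL)
    det <- align_local(pa[[i]], pb[[j]], matrix, gap_open, gap_extend)
    tibble::tibble(protein_a = names(pa)[i], protein_b = names(pb)[j],
                   score = det$score, identity_pct = det$identity_pct,
                   aligned_len = det$aligned_len)
  })
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          score = numeric(), identity_pct = numeric(),
                          aligned_len = integer()))
  }
  pairs <- dplyr::filter(pairs, .data$aligned_len >= min_aln_len)
  dplyr::arrange(pairs, .data$protein_a)
}

#' Build an ortholog table for a genome panel
#'
#' Runs [reciprocal_best_hits()] between the focal proteome and every other
#' genome's proteome and records, per focal gene and genome, the ortholog
#' name, its order index along that genome and its strand sign. The focal
#' genome maps to itself with identity.
#'
#' @param panel Named list of genome gene tables, each a tibble with columns
#'   `name`, `protein`, `order_index`, `strand`. The first element (or the one
#'   named by `focal`) is the reference.
#' @param focal Name of the focal genome (default: first in `panel`).
#' @inheritParams reciprocal_best_hits
#' @return Tibble `gene`, `genome`, `ortholog`, `order_index`, `strand`,
#'   `score`, `identity_pct` (one row per present ortholog).
#' @export
ortholog_table <- function(panel, focal = names(panel)[1], min_score = 50,
                           min_aln_len = 30L, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  stopifnot(focal %in% names(panel))
  ref <- panel[[focal]]
  purrr::map_dfr(names(panel), function(g) {
    tab <- panel[[g]]
    if (g == focal) {
      return(tibble::tibble(gene = ref$name, genome = g, ortholog = ref$name,
                            order_index = ref$order_index, strand = ref$strand,
                            score = NA_real_, identity_pct = 100))
    }
    rbh <- reciprocal_best_hits(ref, tab, min_score, min_aln_len,
                                matrix, gap_open, gap_extend)
    idx <- match(rbh$protein_b, tab$name)
    tibble::tibble(gene = rbh$protein_a, genome = g, ortholog = rbh$protein_b,
                   order_index = tab$order_index[idx], strand = tab$strand[idx],
                   score = rbh$score, identity_pct = rbh$identity_pct)
  })
}

#' Classify genes by their presence pattern across a genome panel
#'
#' Given ortholog assignments and a group label per genome (e.g. NPV-I,
#' NPV-II, GV), each focal gene is labelled: `core` if present in every panel
#' genome; `group-specific` if present in all genomes of exactly one group and
#' absent from all others; `unique` if present only in the focal genome;
#' otherwise `shared-subset`.
#'
#' @param ortho Ortholog table (`gene`, `genome`, ... rows mark presence).
#' @param groups Tibble with columns `genome` and `group` covering every panel
#'   genome (including the focal one).
#' @param focal Focal genome id.
#' @return Tibble `gene`, `class`.
#' @export
classify_genes <- function(ortho, groups, focal) {
  stopifnot(all(c("genome", "group") %in% names(groups)))
  all_genomes <- unique(groups$genome)
  grp_of <- stats::setNames(groups$group, groups$genome)
  purrr::map_dfr(unique(ortho$gene), function(g) {
    present <- unique(ortho$genome[ortho$gene == g])
    cls <- if (setequal(present, all_genomes)) {
      "core"
    } else if (setequal(present, focal)) {
      "unique"
    } else {
      grps <- unique(grp_of[present])
      full_groups <- vapply(grps, function(gr) {
        all(all_genomes[grp_of[all_genomes] == gr] %in% present)
      }, logical(1))
      if (length(grps) == 1L && full_groups[1]) "group-specific" else "shared-subset"
    }
    tibble::tibble(gene = g, class = cls)
  })
}
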