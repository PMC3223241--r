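# Maximum-parsimony inference on amino-acid supermatrices: Fitch scoring,
# stepwise-addition + NNI hill-climbing search, and nonparametric bootstrap.
# Gaps (and X/ambiguity codes) are treated as missing data, i.e. compatible
# with every state, as in PAUP's default handling.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")
FULL_MASK <- bitwShiftL(1L, 20L) - 1L

# supermatrix -> integer bitmask matrix (rows = taxa, cols = sites)
sm_states <- function(sm) {
  chars <- lapply(sm$seqs, function(s) strsplit(s, NULL)[[1]])
  codes <- stats::setNames(bitwShiftL(1L, seq_along(AA20) - 1L), AA20)
  res <- vapply(chars, function(v) {
    x <- unname(codes[v])
    x[is.na(x)] <- FULL_MASK     # gap, X, B, Z, ... = any state
    x
  }, integer(nchar(sm$seqs[[1]])))
  if (is.matrix(res)) t(res) else matrix(res, ncol = 1L,
                                         dimnames = list(names(res), NULL))
}

# collapse identical site patterns, summing weights
compress_patterns <- function(states, weights = rep(1, ncol(states))) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- tapply(weights, key, sum)
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(w[key[first]]))
}

# weighted Fitch length of a tree; tree may be the usual unrooted phylo with a
# trifurcating representation root (sequential combination at that node is a
# rooted resolution of the same unrooted tree, so the count is exact)
fitch_score <- function(tree, states, weights = rep(1, ncol(states))) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  S <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) S[[i]] <- states[tree$tip.label[i], ]
  changes <- 0
  E <- tree$edge
  for (e in seq_len(nrow(E))) {
    par <- E[e, 1L]
    cs <- S[[E[e, 2L]]]
    ps <- S[[par]]
    if (is.null(ps)) {
      S[[par]] <- cs
    } else {
      inter <- bitwAnd(ps, cs)
      z <- inter == 0L
      if (any(z)) {
        changes <- changes + sum(weights[z])
        inter[z] <- bitwOr(ps[z], cs[z])
      }
      S[[par]] <- inter
    }
  }
  changes
}

#' Parsimony score of a tree on a supermatrix
#'
#' Fitch length: the minimum number of state changes over the tree, summed
#' across columns, with gaps and ambiguity codes treated as missing data.
#' The score is invariant under re-rooting and leaf-order permutation.
#'
#' @param tree An unrooted binary `phylo` over exactly the supermatrix taxa.
#' @param supermatrix A [concatenate()] supermatrix.
#' @return Integer score.
#' @export
parsimony_score <- function(tree, supermatrix) {
  if (!setequal(tree$tip.label, supermatrix$taxa)) {
    rlang::abort("tree tips and supermatrix taxa do not match")
  }
  cp <- compress_patterns(sm_states(supermatrix))
  as.integer(fitch_score(tree, cp$states, cp$weights))
}

# attach a new tip in the middle of edge `edge_idx`
insert_tip <- function(tree, edge_idx, label) {
  n <- length(tree$tip.label)
  E <- tree$edge
  E[E > n] <- E[E > n] + 1L
  newtip <- n + 1L
  newnode <- n + 1L + tree$Nnode + 1L
  v <- E[edge_idx, 2L]
  E[edge_idx, 2L] <- newnode
  E <- rbind(E, c(newnode, v), c(newnode, newtip))
  structure(list(edge = E, tip.label = c(tree$tip.label, label),
                 Nnode = tree$Nnode + 1L),
            class = "phylo", order = NULL)
}

#' Canonical newick string of an unrooted tree topology
#'
#' Two `phylo` objects describe the same unrooted topology iff their canonical
#' strings are equal: the tree is rooted on the alphabetically smallest tip
#' and children are ordered by their canonical substrings.
#'
#' @param tree A `phylo` object.
#' @return A single newick string (no branch lengths).
#' @export
canonical_newick <- function(tree) {
  ntip <- length(tree$tip.label)
  E <- tree$edge
  nbr <- vector("list", max(E))
  for (e in seq_len(nrow(E))) {
    nbr[[E[e, 1]]] <- c(nbr[[E[e, 1]]], E[e, 2])
    nbr[[E[e, 2]]] <- c(nbr[[E[e, 2]]], E[e, 1])
  }
  lab <- tree$tip.label
  canon <- function(node, parent) {
    if (node <= ntip) return(lab[node])
    kids <- setdiff(nbr[[node]], parent)
    paste0("(", paste(sort(vapply(kids, canon, "", node)), collapse = ","), ")")
  }
  t0 <- which(lab == min(lab))[1]
  paste0("(", lab[t0], ",", canon(nbr[[t0]][1], t0), ");")
}

#' Maximum-parsimony tree search
#'
#' Heuristic search: seeded random-order stepwise addition followed by
#' nearest-neighbour-interchange hill climbing, repeated over independent
#' restarts; the best tree found is returned. All ties (equal-score insertion
#' points, NNI neighbours, restarts) are broken by canonical newick order, so
#' the result is fully reproducible under a fixed seed. With fewer than four
#' taxa the single (trivial) topology is returned.
#'
#' @param supermatrix A [concatenate()] supermatrix.
#' @param seed Integer seed for the addition orders.
#' @param n_restarts Number of random-addition restarts (default 10).
#' @return An `mp_tree` object: list with `tree` (unrooted `phylo`), `score`,
#'   `seed`, `n_restarts`, `n_taxa`, `n_cols`, and `bootstrap` (`NULL` until
#'   [bootstrap_mp()] fills it).
#' @export
search_mp <- function(supermatrix, seed = 1L, n_restarts = 10L) {
  taxa <- supermatrix$taxa
  states <- sm_states(supermatrix)
  cp <- compress_patterns(states)
  res <- local_seed(seed, {
    mp_search_engine(taxa, cp$states, cp$weights, n_restarts)
  })
  structure(list(tree = res$tree, score = as.integer(res$score), seed = seed,
                 n_restarts = n_restarts, n_taxa = length(taxa),
                 n_cols = ncol(states), bootstrap = NULL),
            class = "mp_tree")
}

# run code with a temporary RNG state
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

mp_search_engine <- function(taxa, states, weights, n_restarts) {
  n <- length(taxa)
  if (n < 4L) {
    tr <- if (n == 1L) {
      structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = taxa, Nnode = 1L),
                class = "phylo")
    } else {
      ape::read.tree(text = paste0("(", paste(taxa, collapse = ","), ");"))
    }
    return(list(tree = tr, score = fitch_score(tr, states, weights)))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ord <- sample(taxa)
    tr <- ape::read.tree(text = paste0("(", paste(ord[1:3], collapse = ","), ");"))
    for (t in ord[-(1:3)]) {
      cands <- lapply(seq_len(nrow(tr$edge)), insert_tip, tree = tr, label = t)
      tr <- pick_best(cands, states, weights)$tree
    }
    cur <- list(tree = tr, score = fitch_score(tr, states, weights),
                key = canonical_newick(tr))
    repeat {
      nb <- phangorn::nni(cur$tree)
      cand <- pick_best(nb, states, weights)
      if (cand$score < cur$score ||
          (cand$score == cur$score && cand$key < cur$key)) {
        if (cand$score == cur$score) break  # equal-score plateau: stop, stay deterministic
        cur <- cand
      } else break
    }
    if (is.null(best) || cur$score < best$score ||
        (cur$score == best$score && cur$key < best$key)) {
      best <- cur
    }
  }
  best
}

# lowest-score tree in a list; ties by canonical newick
pick_best <- function(trees, states, weights) {
  scores <- vapply(trees, fitch_score, numeric(1), states = states, weights = weights)
  imin <- which(scores == min(scores))
  if (length(imin) > 1L) {
    keys <- vapply(trees[imin], canonical_newick, "")
    imin <- imin[order(keys)[1]]
  }
  list(tree = trees[[imin]], score = scores[imin],
       key = canonical_newick(trees[[imin]]))
}

# bipartition keys of all internal edges (tip-label sets, smallest-label side)
bipartition_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  E <- tree$edge
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(E))) {
    below[[E[e, 1]]] <- c(below[[E[e, 1]]], below[[E[e, 2]]])
  }
  all_tips <- sort(tree$tip.label)
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(E))) {
    v <- E[e, 2]
    if (v <= ntip) next
    side <- sort(below[[v]])
    other <- setdiff(all_tips, side)
    if (length(side) < 2L || length(other) < 2L) next  # trivial split
    key <- if (all_tips[1] %in% side) paste(side, collapse = "|")
           else paste(other, collapse = "|")
    keys <- c(keys, key)
    nodes <- c(nodes, v)
  }
  tibble::tibble(node = nodes, key = keys)
}

#' Bootstrap support for a maximum-parsimony tree
#'
#' Columns of the supermatrix are resampled with replacement; each replicate
#' is analysed with [search_mp()]'s engine and the support of each internal
#' edge of the focal tree is the percentage of replicate trees containing the
#' same bipartition. Reproducible under a fixed seed; replicate seeds are
#' derived from `seed`.
#'
#' @param supermatrix A [concatenate()] supermatrix.
#' @param fit An `mp_tree` from [search_mp()]; if `NULL`, one is inferred.
#' @param replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param n_restarts Restarts per replicate search (default 2).
#' @return The `mp_tree` with its `bootstrap` field set to a tibble
#'   (`node`, `clade`, `support`) and the tree's `node.label` carrying the
#'   supports for newick export.
#' @export
bootstrap_mp <- function(supermatrix, fit = NULL, replicates = 100L,
                         seed = 1L, n_restarts = 2L) {
  stopifnot(replicates >= 1L)
  if (is.null(fit)) fit <- search_mp(supermatrix, seed = seed)
  taxa <- supermatrix$taxa
  states <- sm_states(supermatrix)
  ncols <- ncol(states)
  if (nrow(unique(states)) == 1L) {
    rlang::warn("zero-variation supermatrix: bootstrap supports are degenerate")
  }
  focal <- bipartition_keys(fit$tree)
  counts <- stats::setNames(rep(0L, nrow(focal)), focal$key)
  for (i in seq_len(replicates)) {
    wts <- local_seed(seed + i, tabulate(sample.int(ncols, ncols, replace = TRUE), ncols))
    cp <- compress_patterns(states, wts)
    keep <- cp$weights > 0
    rep_tree <- local_seed(seed + i, {
      mp_search_engine(taxa, cp$states[, keep, drop = FALSE],
                       cp$weights[keep], n_restarts)$tree
    })
    hit <- focal$key %in% bipartition_keys(rep_tree)$key
    counts[hit] <- counts[hit] + 1L
  }
  bs <- tibble::tibble(
    node = focal$node,
    clade = strsplit(focal$key, "|", fixed = TRUE),
    support = 100 * as.numeric(counts) / replicates
  )
  fit$bootstrap <- bs
  fit$replicates <- replicates
  ntip <- fit$n_taxa
  labs <- rep("", fit$tree$Nnode)
  labs[bs$node - ntip] <- format(round_half_up(bs$support, 0), trim = TRUE)
  fit$tree$node.label <- labs
  fit
}

#' @export
print.mp_tree <- function(x, ...) {
  cat(sprintf("<mp_tree> %d taxa, %d columns; parsimony score %d (seed %d, %d restarts)\n",
              x$n_taxa, x$n_cols, x$score, x$seed, x$n_restarts))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap: %d replicates, mean support %.1f%%\n",
                x$replicates, mean(x$bootstrap$support)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the internal splits of a parsimony tree
#'
#' @param x An `mp_tree`.
#' @param ... Unused.
#' @return Tibble with one row per internal bipartition: `node`, the clade's
#'   taxa (as `clade` list-column and comma-separated `taxa`), and bootstrap
#'   `support` (NA before [bootstrap_mp()]).
#' @export
tidy.mp_tree <- function(x, ...) {
  bp <- bipartition_keys(x$tree)
  out <- tibble::tibble(
    node = bp$node,
    clade = strsplit(bp$key, "|", fixed = TRUE),
    taxa = gsub("\\|", ",", bp$key),
    support = NA_real_
  )
  if (!is.null(x$bootstrap)) {
    out$support <- x$bootstrap$support[match(bp$key,
      vapply(x$bootstrap$clade, paste, "", collapse = "|"))]
  }
  out
}

#' One-row summary of a parsimony fit
#'
#' @param x An `mp_tree`.
#' @param ... Unused.
#' @return One-row tibble: `score`, `n_taxa`, `n_cols`, `n_restarts`, `seed`,
#'   `replicates`, `mean_support`.
#' @export
glance.mp_tree <- function(x, ...) {
  tibble::tibble(
    score = x$score, n_taxa = x$n_taxa, n_cols = x$n_cols,
    n_restarts = x$n_restarts, seed = x$seed,
    replicates = if (is.null(x$replicates)) NA_integer_ else x$replicates,
    mean_support = if (is.null(x$bootstrap)) NA_real_ else mean(x$bootstrap$support)
  )
}

#' Write an inferred tree as newick
#'
#' Bootstrap supports (if present) are written as internal node labels.
#'
#' @param fit An `mp_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mp_newick <- function(fit, path) {
  ape::write.tree(fit$tree, file = path)
  invisible(path)
}
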