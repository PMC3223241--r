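# Seeded synthetic genomes and genome panels with planted ground truth.
#
# simulate_genome() lays non-overlapping ORFs around a circle with spacers,
# plants promoter motifs upstream of a configurable fraction of ORFs, and
# guarantees the planted annotation is exactly what enumerate_orfs() +
# select_orfs() recover: an in-frame stop "guard" immediately 5' of every
# planted ATG pins the maximal-ORF start, and a cleanup pass converts one
# codon of every chance background ORF into a stop. Chance ORFs confined to a
# planted ORF's footprint are left alone — they are shorter than their host,
# so the minimal-overlap selection rejects them.

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"), c("T","C","A","G")),
        1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

#' Configuration for a synthetic genome
#'
#' Defaults emulate a granulovirus-sized genome: 120 kb circle, 130 planted
#' ORFs on both strands, 61% A+T. All sampling is controlled by the seed given
#' to [simulate_genome()].
#'
#' @param genome_length Circle size in bp.
#' @param at_target A+T percentage the background is drawn to hit.
#' @param n_orfs Number of planted ORFs.
#' @param orf_length_range Min/max planted ORF length in nt (stop included;
#'   rounded to multiples of 3, minimum 150).
#' @param fraction_reverse Fraction of ORFs on the reverse strand.
#' @param promoter_late_rate,promoter_early_rate Per-ORF probability of
#'   planting a late ((A/T/G)TAAG) / early (TATA + CAGT) promoter upstream.
#' @param min_codons ORF threshold (codons, stop included) the cleanup pass
#'   suppresses chance background ORFs against; should match the threshold
#'   used at annotation time.
#' @param min_spacer Minimum intergenic spacer (bp); must leave room for the
#'   3 bp stop guard and the planted motifs of both flanking ORFs.
#' @param suppress_chance_orfs If `TRUE` (default) chance background ORFs are
#'   disrupted so the planted set is exactly recoverable; set `FALSE` to keep
#'   the raw background.
#' @return A `sim_genome_config` list.
#' @export
sim_genome_config <- function(genome_length = 120000L, at_target = 61,
                              n_orfs = 130L, orf_length_range = c(150L, 1290L),
                              fraction_reverse = 0.42,
                              promoter_late_rate = 0.6,
                              promoter_early_rate = 0.3,
                              min_codons = 50L, min_spacer = 160L,
                              suppress_chance_orfs = TRUE) {
  cfg <- list(genome_length = as.integer(genome_length), at_target = at_target,
              n_orfs = as.integer(n_orfs),
              orf_length_range = as.integer(orf_length_range),
              fraction_reverse = fraction_reverse,
              promoter_late_rate = promoter_late_rate,
              promoter_early_rate = promoter_early_rate,
              min_codons = as.integer(min_codons),
              min_spacer = as.integer(min_spacer),
              suppress_chance_orfs = isTRUE(suppress_chance_orfs))
  rates <- c(cfg$fraction_reverse, cfg$promoter_late_rate, cfg$promoter_early_rate)
  if (any(rates < 0 | rates > 1)) rlang::abort("rates must lie in [0, 1]")
  if (cfg$genome_length <= 0L || any(cfg$orf_length_range < 150L)) {
    rlang::abort("genome_length must be positive and ORF lengths >= 150 nt")
  }
  structure(cfg, class = "sim_genome_config")
}

# sample codons with per-base probabilities matching the A+T target
codon_weights <- function(at_target) {
  p <- c(A = at_target / 200, C = (100 - at_target) / 200,
         G = (100 - at_target) / 200, T = at_target / 200)
  vapply(strsplit(NONSTOP_CODONS, NULL), function(cc) prod(p[cc]), numeric(1))
}

# write txt at circular positions start..start+nchar-1 of base vector b
place_str <- function(b, start, txt, L) {
  pos <- wrap_pos(seq.int(start, start + nchar(txt) - 1L), L)
  b[pos] <- strsplit(txt, NULL)[[1]]
  b
}

#' Simulate a circular genome with planted ORF and promoter truth
#'
#' See the package vignette for the construction; briefly: ORF lengths,
#' strands and spacers are drawn under the config, background bases are a
#' shuffled multiset hitting the A+T target exactly, every planted start codon
#' is preceded by an in-frame stop guard, promoter motifs are written at fixed
#' upstream offsets (late motif start 30 nt, TATA 70 nt, initiator 40 nt
#' before the ATG), and chance ORFs outside planted footprints are disrupted.
#' Identical seeds give byte-identical genomes.
#'
#' @param config A [sim_genome_config()].
#' @param seed Integer seed (mandatory).
#' @param id Identifier for the genome record.
#' @return A list of class `sim_genome`: `record` (a [genome_record()] whose
#'   features are the planted ORFs), `truth` (list with `orfs` and `promoters`
#'   tibbles), `config`, `seed`.
#' @export
simulate_genome <- function(config = sim_genome_config(), seed, id = "simulated") {
  stopifnot(inherits(config, "sim_genome_config"), !missing(seed))
  L <- config$genome_length
  n <- config$n_orfs
  local_seed(as.integer(seed), {
    # ---- layout ----
    if (n > 0L) {
      lo <- ceiling(config$orf_length_range[1] / 3)
      hi <- floor(config$orf_length_range[2] / 3)
      lens <- 3L * sample(lo:hi, n, replace = TRUE)
      spare <- L - sum(lens) - n * config$min_spacer
      if (spare < 0L) {
        rlang::abort(sprintf(
          "infeasible config: %d bp of ORFs + %d bp minimum spacing exceed genome length %d",
          sum(lens), n * config$min_spacer, L))
      }
      extra <- if (spare > 0L) as.integer(stats::rmultinom(1, spare, rep(1, n))) else integer(n)
      spacers <- config$min_spacer + extra
      strand <- rep(1L, n)
      n_rev <- round(config$fraction_reverse * n)
      if (n_rev > 0L && n > 1L) strand[sample(2:n, min(n_rev, n - 1L))] <- -1L
      starts <- cumsum(c(1L, utils::head(lens + spacers, -1L)))
      ends <- starts + lens - 1L
    } else {
      if (L < 1L) rlang::abort("infeasible config: empty genome")
      lens <- starts <- ends <- integer(0)
      strand <- integer(0)
    }

    b <- character(L)
    protected <- logical(L)

    # ---- planted coding sequence ----
    cw <- codon_weights(config$at_target)
    stop_w <- c(TAA = 1, TAG = 0.5, TGA = 0.5)
    for (i in seq_len(n)) {
      n_int <- lens[i] / 3L - 2L
      interior <- sample(NONSTOP_CODONS, n_int, replace = TRUE, prob = cw)
      cds <- paste0("ATG", paste(interior, collapse = ""),
                    sample(names(stop_w), 1L, prob = stop_w))
      if (strand[i] < 0L) cds <- revcomp(cds)
      b <- place_str(b, starts[i], cds, L)
      protected[circ_positions(starts[i], ends[i], L)] <- TRUE
    }

    # ---- stop guards 5' of every planted ATG ----
    for (i in seq_len(n)) {
      gpos <- if (strand[i] > 0L) starts[i] - 3L else ends[i] + 1L
      guard <- if (strand[i] > 0L) "TAA" else "TTA"
      b <- place_str(b, gpos, guard, L)
      protected[wrap_pos(seq.int(gpos, gpos + 2L), L)] <- TRUE
    }

    # ---- promoters ----
    prom <- list()
    plant_motif <- function(b, i, motif, offset_far) {
      # motif occupies offsets (offset_far .. offset_far - nchar + 1) before the ATG
      if (strand[i] > 0L) {
        p0 <- starts[i] - offset_far
        b <- place_str(b, p0, motif, L)
      } else {
        p0 <- ends[i] + offset_far - nchar(motif) + 1L
        b <- place_str(b, p0, revcomp(motif), L)
      }
      protected[wrap_pos(seq.int(p0, p0 + nchar(motif) - 1L), L)] <<- TRUE
      b
    }
    for (i in seq_len(n)) {
      late <- stats::runif(1) < config$promoter_late_rate
      early <- stats::runif(1) < config$promoter_early_rate
      if (late) {
        b <- plant_motif(b, i, "ATAAG", 30L)
        prom[[length(prom) + 1L]] <- tibble::tibble(
          orf = i, motif_id = "late", motif = "ATAAG", offset_upstream = 30L)
      }
      if (early) {
        b <- plant_motif(b, i, "TATAA", 70L)
        b <- plant_motif(b, i, "CAGT", 40L)
        prom[[length(prom) + 1L]] <- tibble::tibble(
          orf = i, motif_id = "early", motif = "TATAA", offset_upstream = 70L)
      }
    }

    # ---- exact-composition background ----
    n_bg <- sum(b == "")
    n_at <- round(n_bg * config$at_target / 100)
    n_a <- floor(n_at / 2); n_t <- n_at - n_a
    n_c <- floor((n_bg - n_at) / 2); n_g <- n_bg - n_at - n_c
    pool <- sample(c(rep("A", n_a), rep("T", n_t), rep("C", n_c), rep("G", n_g)))
    b[b == ""] <- pool

    # ---- cleanup: suppress chance ORFs outside planted footprints ----
    planted_key <- paste(starts, ends, strand)
    for (iter in if (config$suppress_chance_orfs) seq_len(30L) else integer(0)) {
      rec <- genome_record(paste(b, collapse = ""), id = id, circular = TRUE)
      cand <- enumerate_orfs(rec, min_codons = config$min_codons)
      off <- cand[!(paste(cand$start, cand$end, cand$strand) %in% planted_key), ]
      if (nrow(off) > 0L) {
        inside <- vapply(seq_len(nrow(off)), function(k) {
          sp <- circ_span(off$start[k], off$end[k], L)
          any(vapply(seq_len(n), function(i) {
            circ_overlap(off$start[k], off$end[k], starts[i], ends[i], L) == sp &&
              sp < lens[i]
          }, logical(1)))
        }, logical(1))
        off <- off[!inside, ]
      }
      if (nrow(off) == 0L) break
      fixed_any <- FALSE
      for (k in seq_len(nrow(off))) {
        b2 <- disrupt_orf(b, off$start[k], off$end[k], off$strand[k], protected, L)
        if (!is.null(b2)) {
          b <- b2
          fixed_any <- TRUE
        }
      }
      if (!fixed_any) break
    }

    seq <- paste(b, collapse = "")
    orfs <- tibble::tibble(
      name = paste0("orf", seq_len(n)),
      start = starts, end = ends, strand = strand,
      wraps = ends < starts, length_nt = lens
    )
    promoters <- if (length(prom) > 0L) {
      d <- dplyr::bind_rows(prom)
      d$orf_name <- orfs$name[d$orf]
      d[, c("orf_name", "motif_id", "motif", "offset_upstream")]
    } else {
      tibble::tibble(orf_name = character(), motif_id = character(),
                     motif = character(), offset_upstream = integer())
    }
    structure(
      list(record = genome_record(seq, id = id, circular = TRUE, features = orfs),
           truth = list(orfs = orfs, promoters = promoters),
           config = config, seed = as.integer(seed)),
      class = "sim_genome"
    )
  })
}

# overwrite the 5'-most fully-unprotected codon of an ORF with a stop codon
# (on the ORF's own strand); NULL if no codon can be touched
disrupt_orf <- function(b, start, end, strand, protected, L) {
  span <- circ_span(start, end, L)
  n_cod <- span %/% 3L
  firsts <- if (strand > 0L) {
    start + 3L * (seq_len(n_cod) - 1L)
  } else {
    end - 2L - 3L * (seq_len(n_cod) - 1L)
  }
  for (p in firsts) {
    pos <- wrap_pos(seq.int(p, p + 2L), L)
    if (!any(protected[pos])) {
      b[pos] <- strsplit(if (strand > 0L) "TAA" else "TTA", NULL)[[1]]
      return(b)
    }
  }
  NULL
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> seed %d: %d bp, %d planted ORFs, %d planted motifs\n",
              x$seed, genome_length(x$record), nrow(x$truth$orfs),
              nrow(x$truth$promoters)))
  invisible(x)
}

#' Configuration for a synthetic genome panel
#'
#' @param n_genes Number of homologous gene families.
#' @param gene_length_aa Min/max ancestral protein length (aa).
#' @param subst_rate Per-site amino-acid substitution probability per unit
#'   branch length (capped at 0.95 on any one branch).
#' @param inversion_rate,transposition_rate Expected number of gene-order
#'   inversions / transpositions per unit branch length.
#' @return A `sim_panel_config` list.
#' @export
sim_panel_config <- function(n_genes = 24L, gene_length_aa = c(100L, 200L),
                             subst_rate = 0.3, inversion_rate = 0,
                             transposition_rate = 0) {
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_aa = as.integer(gene_length_aa),
                 subst_rate = subst_rate, inversion_rate = inversion_rate,
                 transposition_rate = transposition_rate),
            class = "sim_panel_config")
}

#' Simulate a panel of genomes diverged along a known tree
#'
#' Ancestral proteins for `n_genes` gene families are evolved along the given
#' tree by seeded per-site amino-acid substitution; gene order evolves by
#' seeded inversions (segment reversed, strands flipped) and transpositions
#' (segment moved), drawn per branch at the configured rates and recorded.
#' The first tip (alphabetically) is the focal genome unless `focal` is given.
#'
#' @param tree An `ape` `phylo` (or newick string) with branch lengths;
#'   missing lengths default to 1.
#' @param config A [sim_panel_config()].
#' @param seed Integer seed (mandatory).
#' @param focal Focal genome (tip label).
#' @return A list of class `sim_panel`: `panel` (named list of per-genome gene
#'   tables `name`, `protein`, `order_index`, `strand`), `ortholog_table`
#'   (truth, in [ortholog_table()] layout), `ops` (recorded rearrangements),
#'   `gene_families` (list: gene -> named protein vector across taxa),
#'   `focal`, `focal_genes`, `tree`, `config`, `seed`.
#' @export
simulate_panel <- function(tree, config = sim_panel_config(), seed,
                           focal = NULL) {
  stopifnot(inherits(config, "sim_panel_config"), !missing(seed))
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tips <- tree$tip.label
  if (is.null(focal)) focal <- sort(tips)[1]
  ng <- config$n_genes
  local_seed(as.integer(seed), {
    lens <- sample(config$gene_length_aa[1]:config$gene_length_aa[2], ng,
                   replace = TRUE)
    root_prot <- lapply(lens, function(l) sample(AA20, l, replace = TRUE))
    root_order <- seq_len(ng) * c(1L, sample(c(-1L, 1L), ng - 1L, replace = TRUE))

    ntip <- length(tips)
    root <- ntip + 1L
    states <- vector("list", ntip + tree$Nnode)
    states[[root]] <- list(prot = root_prot, ord = root_order)
    ops <- list()
    E <- tree$edge
    # walk edges so that each child's parent state already exists
    remaining <- seq_len(nrow(E))
    while (length(remaining) > 0L) {
      ready <- remaining[!vapply(remaining, function(e) is.null(states[[E[e, 1]]]), logical(1))]
      for (e in ready) {
        par <- states[[E[e, 1]]]
        bl <- tree$edge.length[e]
        p <- min(0.95, config$subst_rate * bl)
        prot <- lapply(par$prot, function(s) {
          hit <- stats::runif(length(s)) < p
          if (any(hit)) {
            s[hit] <- vapply(s[hit], function(a) sample(setdiff(AA20, a), 1L), "")
          }
          s
        })
        ord <- par$ord
        child_id <- E[e, 2]
        child_lab <- if (child_id <= ntip) tips[child_id] else paste0("node", child_id)
        n_inv <- stats::rpois(1, config$inversion_rate * bl)
        n_tra <- stats::rpois(1, config$transposition_rate * bl)
        for (r in seq_len(n_inv)) {
          ij <- sort(sample(seq_along(ord), 2L))
          ord[ij[1]:ij[2]] <- -rev(ord[ij[1]:ij[2]])
          ops[[length(ops) + 1L]] <- tibble::tibble(
            branch_to = child_lab, op = "inversion", from = ij[1], to = ij[2])
        }
        for (r in seq_len(n_tra)) {
          ij <- sort(sample(seq_along(ord), 2L))
          seg <- ord[ij[1]:ij[2]]
          rest <- ord[-(ij[1]:ij[2])]
          at <- sample(0:length(rest), 1L)
          ord <- append(rest, seg, after = at)
          ops[[length(ops) + 1L]] <- tibble::tibble(
            branch_to = child_lab, op = "transposition", from = ij[1], to = ij[2])
        }
        states[[child_id]] <- list(prot = prot, ord = ord)
        remaining <- setdiff(remaining, e)
      }
    }

    panel <- lapply(stats::setNames(seq_len(ntip), tips), function(i) {
      st <- states[[i]]
      g <- abs(st$ord)
      tibble::tibble(
        name = paste0(tips[i], "_g", g),
        protein = vapply(st$prot[g], paste, "", collapse = ""),
        order_index = seq_len(ng),
        strand = as.integer(sign(st$ord))
      )
    })

    focal_tab <- panel[[focal]]
    focal_gene_of <- stats::setNames(focal_tab$name,
                                     sub(".*_g", "", focal_tab$name))
    truth <- purrr::map_dfr(tips, function(t) {
      tab <- panel[[t]]
      gidx <- sub(".*_g", "", tab$name)
      tibble::tibble(gene = unname(focal_gene_of[gidx]), genome = t,
                     ortholog = tab$name, order_index = tab$order_index,
                     strand = tab$strand,
                     score = NA_real_, identity_pct = NA_real_)
    })
    fams <- lapply(stats::setNames(seq_len(ng), paste0("g", seq_len(ng))),
                   function(g) {
      vapply(tips, function(t) {
        tab <- panel[[t]]
        tab$protein[tab$name == paste0(t, "_g", g)]
      }, "")
    })
    structure(
      list(panel = panel, ortholog_table = truth,
           ops = if (length(ops)) dplyr::bind_rows(ops) else
             tibble::tibble(branch_to = character(), op = character(),
                            from = integer(), to = integer()),
           gene_families = fams, focal = focal,
           focal_genes = focal_tab$name[order(focal_tab$order_index)],
           tree = tree, config = config, seed = as.integer(seed)),
      class = "sim_panel"
    )
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> seed %d: %d genomes x %d genes, %d rearrangement op(s)\n",
              x$seed, length(x$panel), x$config$n_genes, nrow(x$ops)))
  invisible(x)
}
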