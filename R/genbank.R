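# Minimal GenBank flat-file reader/writer for single-record viral genomes.
# No installed R package parses GenBank flat files offline, so this is done by
# hand: LOCUS (length + topology), CDS features (including complement() and
# origin-spanning join()), and ORIGIN sequence. Multi-record files, multi-exon
# joins other than an origin wrap, and protein records are out of scope.

#' Read a single-record GenBank flat file
#'
#' Parses the LOCUS line (sequence length and circular/linear topology), all
#' CDS features — including `complement(...)` and two-part `join(...)`
#' locations that wrap the origin of a circular genome — and the ORIGIN
#' sequence block. Feature names come from `/gene`, falling back to
#' `/locus_tag`, then to `CDS_<n>`.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return A [genome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) {
    rlang::abort(paste0("parse error: no LOCUS line in '", path, "'"))
  }
  if (length(locus_idx) > 1L) {
    rlang::abort("unsupported input: multi-record GenBank files are not supported")
  }
  locus <- lines[locus_idx]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  if (length(toks) < 3L) rlang::abort(paste0("parse error at line ", locus_idx, ": ", locus))
  id <- toks[2]
  len <- suppressWarnings(as.integer(toks[3]))
  if (is.na(len)) rlang::abort(paste0("parse error at line ", locus_idx, ": bad length in LOCUS"))
  circular <- any(grepl("circular", toks, ignore.case = TRUE))

  # ---- ORIGIN block ----
  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1L) rlang::abort("parse error: expected exactly one ORIGIN block")
  endrec <- grep("^//", lines)
  endrec <- endrec[endrec > ori][1]
  if (is.na(endrec)) endrec <- length(lines) + 1L
  seq_lines <- lines[seq.int(ori + 1L, endrec - 1L)]
  seq <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) != len) {
    rlang::abort(sprintf("parse error: LOCUS declares %d bp but ORIGIN has %d", len, nchar(seq)))
  }

  # ---- FEATURES block: collect CDS entries ----
  featstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(featstart) == 1L) {
    block <- lines[seq.int(featstart + 1L, ori - 1L)]
    is_key <- grepl("^ {5}\\S", block)
    key_idx <- which(is_key)
    keys <- sub("^ {5}(\\S+).*", "\\1", block[key_idx])
    rows <- list()
    for (k in seq_along(key_idx)) {
      if (keys[k] != "CDS") next
      from <- key_idx[k]
      to <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
      entry <- block[from:to]
      # location: first line text after key, continued until a /qualifier line
      loc <- sub("^ {5}\\S+\\s*", "", entry[1])
      j <- 2L
      while (j <= length(entry) && !grepl("^\\s*/", entry[j])) {
        loc <- paste0(loc, trimws(entry[j]))
        j <- j + 1L
      }
      quals <- entry[grepl("^\\s*/", entry)]
      getq <- function(q) {
        hit <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
        if (length(hit) == 0L) return(NA_character_)
        gsub('^[^=]*=|"', "", hit[1])
      }
      parsed <- parse_gb_location(loc, len, circular,
                                  line = featstart + from)
      nm <- getq("gene")
      if (is.na(nm)) nm <- getq("locus_tag")
      if (is.na(nm)) nm <- paste0("CDS_", length(rows) + 1L)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(name = nm, start = parsed$start, end = parsed$end,
                       strand = parsed$strand)
    }
    if (length(rows) > 0L) feats <- dplyr::bind_rows(rows)
  }
  genome_record(seq, id = id, circular = circular, features = feats)
}

# parse a GenBank location string into (start, end, strand); supports
# "a..b", "complement(a..b)", and origin-wrapping "join(a..L,1..b)"
parse_gb_location <- function(loc, L, circular, line = NA) {
  loc0 <- loc
  strand <- 1L
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  err <- function(msg) {
    rlang::abort(sprintf("parse error at line %s: %s in location '%s'",
                         as.character(line), msg, loc0))
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2L) err("only two-part origin-wrapping joins supported")
    sp <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
      if (length(m) != 3L) err("bad span")
      as.integer(m[2:3])
    })
    if (!circular || sp[[1]][2] != L || sp[[2]][1] != 1L) {
      err("join does not wrap the origin of a circular sequence")
    }
    return(list(start = sp[[1]][1], end = sp[[2]][2], strand = strand))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3L) err("unsupported location")
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS with topology, CDS features
#' with `/gene` qualifiers, ORIGIN block) that [read_genbank()] round-trips
#' losslessly. Wrapping features are written as `join(start..L,1..end)`.
#'
#' @param record A [genome_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  L <- genome_length(record)
  topo <- if (record$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s VRL 01-JAN-2000",
                   record$id, L, topo),
           sprintf("DEFINITION  %s.", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    span <- if (f$wraps[i]) {
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    } else {
      sprintf("%d..%d", f$start[i], f$end[i])
    }
    if (f$strand[i] < 0L) span <- sprintf("complement(%s)", span)
    out <- c(out,
             sprintf("     CDS             %s", span),
             sprintf("                     /gene=\"%s\"", f$name[i]))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq.int(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
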