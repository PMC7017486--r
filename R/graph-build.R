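#' Variation-graph construction from a reference and an SV catalog
#'
#' Builds a bidirected variation graph from a reference genome and a VCF of
#' structural variants. Reference contigs are split into nodes at every
#' variant breakpoint (and at a configurable maximum node length); each ALT
#' allele is embedded as new nodes and/or edges: a deletion becomes a bypass
#' edge, an insertion becomes one or more inserted-sequence nodes, and an
#' inversion becomes a pair of edges entering and leaving the reference
#' segment in reverse orientation (no sequence is duplicated). Each contig
#' contributes one embedded reference path, and every VCF record is annotated
#' with one walk per allele, anchored on the reference path on both sides.
#'
#' Coordinates: VCF positions are 1-based; all internal intervals are 0-based
#' half-open.
#'
#' @param reference Named character vector of contig sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param variants A VCF path or a record table from [read_vcf()]. Records
#'   must be sorted by contig and position; explicit REF alleles must match
#'   the reference. Symbolic `<DEL>`/`<INV>` alleles are resolved from INFO
#'   END (or SVLEN); symbolic `<INS>` requires an INFO SEQ sequence.
#' @param max_node_len Maximum node length in bp; longer reference segments
#'   are split deterministically left to right (default 1024).
#' @return A `variation_graph` object.
#' @export
build_graph <- function(reference, variants, max_node_len = 1024L) {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference) &&
      is.null(names(reference))) {
    reference <- read_fasta(reference)
  } else if (methods::is(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  reference <- toupper(reference)
  if (is.character(variants)) variants <- read_vcf(variants)
  rec <- variants
  if (nrow(rec) > 0) {
    ## VCF must be coordinate-sorted within contig
    for (ctg in unique(rec$chrom)) {
      p <- rec$pos[rec$chrom == ctg]
      if (is.unsorted(p)) stop_graphsv("VCF records not sorted by position on contig ", ctg)
    }
  }

  ## --- resolve every ALT allele to a core replacement interval -------------
  resolved <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    resolved[[i]] <- resolve_record(rec[i, ], reference)
  }

  ## --- breakpoints and reference nodes -------------------------------------
  ctgs <- names(reference)
  bps <- stats::setNames(lapply(ctgs, function(ctg) {
    c(0L, nchar(reference[[ctg]]))
  }), ctgs)
  for (r in resolved) {
    for (a in r$alts) {
      bps[[r$contig]] <- c(bps[[r$contig]], a$rs, a$re)
    }
  }
  node_seq <- character(0)
  node_contig <- character(0)
  node_offset <- integer(0)
  contigs <- list()
  for (ctg in ctgs) {
    L <- nchar(reference[[ctg]])
    cuts <- sort(unique(bps[[ctg]]))
    cuts <- cuts[cuts >= 0L & cuts <= L]
    ## enforce the node length cap, splitting left to right
    full <- integer(0)
    for (j in seq_len(length(cuts) - 1L)) {
      a <- cuts[j]; b <- cuts[j + 1L]
      full <- c(full, seq(a, b - 1L, by = max_node_len))
    }
    full <- c(full, L)
    starts <- full[-length(full)]
    ends <- full[-1L]
    ids <- length(node_seq) + seq_along(starts)
    node_seq <- c(node_seq, substring(reference[[ctg]], starts + 1L, ends))
    node_contig <- c(node_contig, rep(ctg, length(starts)))
    node_offset <- c(node_offset, starts)
    contigs[[ctg]] <- list(node_id = as.integer(ids), offset = as.integer(starts),
                           len = as.integer(L))
  }

  g <- structure(list(
    node_seq = node_seq,
    node_len = nchar(node_seq),
    node_contig = node_contig,
    node_offset = as.integer(node_offset),
    edges = matrix(integer(0), ncol = 2L),
    paths = list(),
    variants = list(),
    contigs = contigs,
    max_node_len = as.integer(max_node_len)
  ), class = "variation_graph")

  edge_env <- new.env(parent = emptyenv())
  add_edges <- function(sides) {
    if (nrow(sides) == 0L) return(invisible())
    for (j in seq_len(nrow(sides))) {
      k <- edge_key(sides[j, 1L], sides[j, 2L])
      if (is.null(edge_env[[k]])) {
        edge_env[[k]] <- c(min(sides[j, ]), max(sides[j, ]))
      }
    }
  }

  ## reference paths and their edges
  for (ctg in ctgs) {
    ids <- contigs[[ctg]]$node_id
    g$paths[[length(g$paths) + 1L]] <- list(
      name = ctg, node_id = ids, rev = rep(FALSE, length(ids)), is_reference = TRUE)
    add_edges(walk_edge_sides(ids, rep(FALSE, length(ids))))
  }

  ## --- embed alleles --------------------------------------------------------
  rseg <- function(ctg, a, b) {
    if (a >= b) return(integer(0))
    off <- contigs[[ctg]]$offset
    contigs[[ctg]]$node_id[off >= a & off < b]
  }
  node_ending_at <- function(ctg, p) {
    off <- contigs[[ctg]]$offset
    ids <- contigs[[ctg]]$node_id
    i <- which(off + g$node_len[ids] == p)
    if (length(i) != 1L) return(NA_integer_)
    ids[i]
  }
  node_starting_at <- function(ctg, p) {
    i <- which(contigs[[ctg]]$offset == p)
    if (length(i) != 1L) return(NA_integer_)
    contigs[[ctg]]$node_id[i]
  }

  for (r in resolved) {
    ctg <- r$contig
    u1 <- min(vapply(r$alts, `[[`, integer(1), "rs"))
    u2 <- max(vapply(r$alts, `[[`, integer(1), "re"))
    anchorL <- node_ending_at(ctg, u1)
    anchorR <- node_starting_at(ctg, u2)
    if (is.na(anchorL) || is.na(anchorR)) {
      stop_graphsv("variant ", r$id, " cannot be anchored on the reference path ",
                   "(breakpoints at the very start or end of contig ", ctg, ")")
    }
    walks <- list()
    ## reference allele: reference nodes across the union interval
    ref_ids <- c(anchorL, rseg(ctg, u1, u2), anchorR)
    walks[[1L]] <- list(node_id = ref_ids, rev = rep(FALSE, length(ref_ids)))
    for (a in r$alts) {
      pre <- rseg(ctg, u1, a$rs)
      post <- rseg(ctg, a$re, u2)
      if (a$kind == "INV") {
        seg <- rseg(ctg, a$rs, a$re)
        mid_id <- rev(seg)
        mid_rev <- rep(TRUE, length(seg))
      } else if (nchar(a$alt_core) == 0L) { # pure deletion
        mid_id <- integer(0)
        mid_rev <- logical(0)
      } else {                               # insertion / replacement sequence
        pieces <- substring(a$alt_core,
                            seq(1L, nchar(a$alt_core), by = max_node_len),
                            pmin(seq(max_node_len, nchar(a$alt_core) + max_node_len - 1L,
                                     by = max_node_len), nchar(a$alt_core)))
        new_ids <- length(g$node_seq) + seq_along(pieces)
        g$node_seq <- c(g$node_seq, pieces)
        g$node_len <- c(g$node_len, nchar(pieces))
        g$node_contig <- c(g$node_contig, rep(NA_character_, length(pieces)))
        g$node_offset <- c(g$node_offset, rep(NA_integer_, length(pieces)))
        mid_id <- as.integer(new_ids)
        mid_rev <- rep(FALSE, length(new_ids))
      }
      wid <- c(anchorL, pre, mid_id, post, anchorR)
      wrev <- c(FALSE, rep(FALSE, length(pre)), mid_rev, rep(FALSE, length(post)), FALSE)
      add_edges(walk_edge_sides(wid, wrev))
      walks[[length(walks) + 1L]] <- list(node_id = wid, rev = wrev)
    }
    g$variants[[length(g$variants) + 1L]] <- list(
      id = r$id, contig = ctg, pos = r$pos, rs = u1, re = u2,
      n_alleles = length(walks), allele_walks = walks,
      svtypes = vapply(r$alts, `[[`, character(1), "kind"))
  }

  ek <- ls(edge_env)
  em <- matrix(0L, nrow = length(ek), ncol = 2L)
  for (j in seq_along(ek)) em[j, ] <- edge_env[[ek[j]]]
  o <- order(em[, 1L], em[, 2L])
  g$edges <- em[o, , drop = FALSE]
  g
}

## Resolve one VCF record (possibly multi-allelic) to per-ALT core
## replacement intervals on 0-based coordinates.
resolve_record <- function(rec, reference) {
  ctg <- rec$chrom
  if (!ctg %in% names(reference)) {
    stop_graphsv("record ", rec$id, ": contig ", ctg, " not in reference")
  }
  seq <- reference[[ctg]]
  pos <- rec$pos
  alts <- strsplit(rec$alt, ",", fixed = TRUE)[[1]]
  out <- list()
  for (alt in alts) {
    if (grepl("^<", alt)) {
      svtype <- gsub("[<>]", "", alt)
      end <- suppressWarnings(as.integer(info_get(rec$info, "END")))
      if (is.na(end)) {
        svlen <- suppressWarnings(as.integer(info_get(rec$info, "SVLEN")))
        if (!is.na(svlen)) end <- pos + abs(svlen)
      }
      if (svtype %in% c("DEL", "INV")) {
        if (is.na(end) || end <= pos) {
          stop_graphsv("record ", rec$id, ": symbolic ", alt,
                       " needs a valid INFO END or SVLEN")
        }
        out[[length(out) + 1L]] <- list(rs = pos, re = end, kind = svtype,
                                        alt_core = "")
      } else if (svtype == "INS") {
        insseq <- info_get(rec$info, "SEQ")
        if (is.na(insseq)) {
          stop_graphsv("record ", rec$id,
                       ": symbolic <INS> without an INFO SEQ sequence")
        }
        out[[length(out) + 1L]] <- list(rs = pos, re = pos, kind = "INS",
                                        alt_core = toupper(insseq))
      } else {
        stop_graphsv("record ", rec$id, ": unknown symbolic ALT type <", svtype, ">")
      }
    } else {
      refa <- rec$ref
      have <- substring(seq, pos, pos + nchar(refa) - 1L)
      if (have != refa) {
        stop_graphsv("record ", rec$id, " at ", ctg, ":", pos,
                     ": REF allele does not match the reference sequence (",
                     substr(refa, 1, 20), " vs ", substr(have, 1, 20), ")")
      }
      ## inversion check on the padding-stripped alleles (before trimming,
      ## which could shift the interval when segment ends happen to match)
      inv_ref <- substring(refa, 2L)
      inv_alt <- substring(alt, 2L)
      if (nchar(refa) > 2L && nchar(refa) == nchar(alt) &&
          substring(refa, 1L, 1L) == substring(alt, 1L, 1L) &&
          inv_alt != inv_ref && inv_alt == revcomp(inv_ref)) {
        out[[length(out) + 1L]] <- list(rs = pos, re = pos + nchar(inv_ref),
                                        kind = "INV", alt_core = "")
      } else {
        tr <- trim_alleles(refa, alt)
        rs <- pos - 1L + tr$prefix
        re <- pos - 1L + nchar(refa) - tr$suffix
        core_ref <- substring(refa, tr$prefix + 1L, nchar(refa) - tr$suffix)
        core_alt <- substring(alt, tr$prefix + 1L, nchar(alt) - tr$suffix)
        kind <- if (nchar(core_alt) == 0L) "DEL"
        else if (nchar(core_ref) == 0L) "INS"
        else "REPL"
        out[[length(out) + 1L]] <- list(rs = rs, re = re, kind = kind,
                                        alt_core = core_alt)
      }
    }
  }
  list(id = rec$id, contig = ctg, pos = pos, alts = out)
}

## Longest shared suffix, then longest shared prefix of the remainder.
trim_alleles <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  maxtrim <- min(nr, na)
  s <- 0L
  while (s < maxtrim &&
         substring(ref, nr - s, nr - s) == substring(alt, na - s, na - s)) {
    s <- s + 1L
  }
  p <- 0L
  maxp <- maxtrim - s
  while (p < maxp &&
         substring(ref, p + 1L, p + 1L) == substring(alt, p + 1L, p + 1L)) {
    p <- p + 1L
  }
  list(prefix = p, suffix = s)
}

#' Spell the sequence of a walk through the graph
#'
#' Concatenates node sequences along an oriented walk, reverse-complementing
#' nodes traversed in reverse orientation.
#'
#' @param g A `variation_graph`.
#' @param node_id Integer vector of node ids.
#' @param rev Logical vector of orientations (TRUE = reverse).
#' @return The walk sequence as a single string.
#' @export
path_sequence <- function(g, node_id, rev = rep(FALSE, length(node_id))) {
  stopifnot(length(node_id) == length(rev))
  if (length(node_id) == 0L) return("")
  if (any(node_id < 1L | node_id > length(g$node_seq))) {
    stop_graphsv("walk references nodes absent from the graph")
  }
  if (length(node_id) > 1L) {
    sides <- walk_edge_sides(node_id, rev)
    keys <- edge_key(sides[, 1L], sides[, 2L])
    have <- edge_key(g$edges[, 1L], g$edges[, 2L])
    bad <- !(keys %in% have)
    if (any(bad)) {
      stop_graphsv("walk is disconnected: no edge between steps ",
                   which(bad)[1L], " and ", which(bad)[1L] + 1L)
    }
  }
  seqs <- g$node_seq[node_id]
  if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
  paste(seqs, collapse = "")
}

#' Extract the embedded reference path sequence of a contig
#'
#' @param g A `variation_graph`.
#' @param contig Contig name.
#' @return The contig sequence spelled by the reference path.
#' @export
reference_sequence <- function(g, contig) {
  p <- ref_path(g, contig)
  paste(g$node_seq[p$node_id], collapse = "")
}

ref_path <- function(g, contig) {
  for (p in g$paths) if (p$is_reference && p$name == contig) return(p)
  stop_graphsv("no reference path for contig ", contig)
}

#' @export
print.variation_graph <- function(x, ...) {
  cat("variation_graph:", length(x$node_seq), "nodes,", nrow(x$edges), "edges,",
      length(x$paths), "paths,", length(x$variants), "variants\n")
  cat("  contigs:", paste(names(x$contigs), collapse = ", "), "\n")
  invisible(x)
}
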