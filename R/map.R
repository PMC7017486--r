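#' Mapper parameters
#'
#' Seed-and-extend parameters for graph read mapping. Scoring is bwa-like:
#' match +1, mismatch -4, gap open -6, gap extend -1. Mapping quality is
#' `min(cap, scale * (best - second best score))`, 0 on ties or candidate
#' overflow, `cap` for a unique placement.
#'
#' @param k Seed k-mer length (default 16).
#' @param band Alignment band half-width; default `2 + ceiling(0.1 * read
#'   length)`, set per read.
#' @param max_walks Bound on candidate walks enumerated per seed cluster;
#'   overflow renders the read ambiguous (MAPQ 0).
#' @param max_candidates Seed clusters examined per read (best-supported
#'   first).
#' @param min_score_frac Minimum alignment score, as a fraction of read
#'   length, to report a placement.
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param mapq_scale,mapq_cap Mapping-quality model parameters.
#' @return List of parameters.
#' @export
map_params <- function(k = 16L, band = NULL, max_walks = 64L, max_candidates = 8L,
                       min_score_frac = 0.4, match = 1L, mismatch = -4L,
                       gap_open = -6L, gap_extend = -1L,
                       mapq_scale = 10, mapq_cap = 60L) {
  list(k = as.integer(k), band = band, max_walks = as.integer(max_walks),
       max_candidates = as.integer(max_candidates),
       min_score_frac = min_score_frac, match = as.integer(match),
       mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
       gap_extend = as.integer(gap_extend), mapq_scale = mapq_scale,
       mapq_cap = as.integer(mapq_cap))
}

#' Build the k-mer seed index of a variation graph
#'
#' Indexes every within-node k-mer (forward orientation) and every
#' junction-spanning k-mer: walks of length `k` starting near an oriented
#' node end and crossing at least one edge, enumerated over both node
#' orientations so that reverse-strand and inversion-crossing placements
#' are discoverable. Each k-mer maps to the graph position (node,
#' orientation, oriented 1-based offset) of its first base. The index also
#' caches the spelled reference sequence per contig for fast placement of
#' reads that lie on the reference path.
#'
#' @param g A `variation_graph`.
#' @param k Seed length.
#' @return A `graph_index` object.
#' @export
graph_index <- function(g, k = 16L) {
  k <- as.integer(k)
  nn <- length(g$node_seq)
  rc_seq <- cpp_revcomp(g$node_seq)

  succ <- vector("list", n_sides(g))
  for (j in seq_len(nrow(g$edges))) {
    s1 <- g$edges[j, 1L]; s2 <- g$edges[j, 2L]
    for (pair in list(c(s1, s2), c(s2, s1))) {
      s <- pair[1L]; t <- pair[2L]
      entry <- c(side_node(t), as.integer(side_is_right(t)))
      succ[[s]] <- rbind(succ[[s]], entry)
    }
  }

  oriented_seq <- function(node, rev) if (rev) rc_seq[node] else g$node_seq[node]

  kms <- vector("list", nn)
  for (n in seq_len(nn)) {
    len <- g$node_len[n]
    if (len >= k) {
      off <- seq_len(len - k + 1L)
      kms[[n]] <- data.table::data.table(
        kmer = substring(g$node_seq[n], off, off + k - 1L),
        node = n, rev = FALSE, off = off)
    }
  }

  jn <- list()
  extend_seq <- function(node, rev, need, budget) {
    s <- if (rev) side_id(node, "left") else side_id(node, "right")
    nexts <- succ[[s]]
    out <- character(0)
    if (is.null(nexts)) return(out)
    for (r in seq_len(nrow(nexts))) {
      m <- nexts[r, 1L]; mrev <- nexts[r, 2L] == 1L
      oseq <- oriented_seq(m, mrev)
      got <- min(nchar(oseq), need)
      head <- substring(oseq, 1L, got)
      if (got == need) {
        out <- c(out, head)
      } else {
        tails <- extend_seq(m, mrev, need - got, budget)
        out <- c(out, paste0(head, tails))
      }
      if (length(out) > budget) break
    }
    out
  }
  for (n in seq_len(nn)) {
    len <- g$node_len[n]
    for (rv in c(FALSE, TRUE)) {
      oseq <- oriented_seq(n, rv)
      for (off in max(1L, len - k + 2L):len) {
        head <- substring(oseq, off, len)
        tails <- extend_seq(n, rv, k - (len - off + 1L), 32L)
        if (length(tails)) {
          jn[[length(jn) + 1L]] <- data.table::data.table(
            kmer = paste0(head, tails), node = n, rev = rv, off = off)
        }
      }
    }
  }
  dt <- unique(data.table::rbindlist(c(kms, jn)))
  data.table::setkey(dt, kmer)

  ## reference caches for the linear fast path
  ctg_seq <- character(0)
  ctg_tab <- list()
  for (ctg in names(g$contigs)) {
    ctg_seq[[ctg]] <- reference_sequence(g, ctg)
    ids <- g$contigs[[ctg]]$node_id
    ctg_tab[[ctg]] <- list(node_id = ids, offset = g$contigs[[ctg]]$offset,
                           len = g$contigs[[ctg]]$len)
  }
  structure(list(k = k, dt = dt, succ = succ, rc_seq = rc_seq,
                 ctg_seq = ctg_seq, ctg_tab = ctg_tab),
            class = "graph_index")
}

#' @export
print.graph_index <- function(x, ...) {
  cat("graph_index: k =", x$k, "|", nrow(x$dt), "indexed k-mer positions\n")
  invisible(x)
}

## A walk segment: steps (node_id, rev) with the contributed oriented range
## [o_start, o_end] (1-based inclusive, in the step's own orientation) and
## the spelled sequence.  walks_from() enumerates walks starting at oriented
## position (node, rev, off) extending up to `need` bases (shorter at dead
## ends); attribute "overflow" marks a hit of the walk bound.
walks_from <- function(g, idx, node, rev, off, need, max_walks) {
  count <- 0L
  overflow <- FALSE
  oriented_seq <- function(n, rv) if (rv) idx$rc_seq[n] else g$node_seq[n]
  rec <- function(n, rv, o, nd) {
    oseq <- oriented_seq(n, rv)
    len <- nchar(oseq)
    got <- min(len - o + 1L, nd)
    chunk <- substring(oseq, o, o + got - 1L)
    if (got >= nd) {
      count <<- count + 1L
      return(list(list(node_id = n, rev = rv, o_start = o, o_end = o + got - 1L,
                       seq = chunk)))
    }
    s <- if (rv) side_id(n, "left") else side_id(n, "right")
    nexts <- idx$succ[[s]]
    if (is.null(nexts)) {
      count <<- count + 1L
      return(list(list(node_id = n, rev = rv, o_start = o, o_end = o + got - 1L,
                       seq = chunk)))
    }
    out <- list()
    for (r in seq_len(nrow(nexts))) {
      if (count >= max_walks) { overflow <<- TRUE; break }
      subs <- rec(nexts[r, 1L], nexts[r, 2L] == 1L, 1L, nd - got)
      for (w in subs) {
        out[[length(out) + 1L]] <- list(
          node_id = c(n, w$node_id), rev = c(rv, w$rev),
          o_start = c(o, w$o_start), o_end = c(o + got - 1L, w$o_end),
          seq = paste0(chunk, w$seq))
      }
    }
    out
  }
  res <- rec(node, rev, off, need)
  attr(res, "overflow") <- overflow
  res
}

## Flip a walk segment: reverse step order and orientations.
flip_walk <- function(g, w) {
  len <- g$node_len[w$node_id]
  list(node_id = rev(w$node_id), rev = rev(!w$rev),
       o_start = rev(len - w$o_end + 1L), o_end = rev(len - w$o_start + 1L),
       seq = cpp_revcomp(w$seq))
}

## Candidate windows around an anchor base at (node, rev, off): walks
## covering up to `left` bases before the anchor and `right` bases from the
## anchor on, spliced through the anchor.  anchor_pos is the 1-based
## position of the anchor base in the window sequence.
candidate_windows <- function(g, idx, node, rev, off, left, right, max_walks) {
  len <- g$node_len[node]
  flip_off <- len - off + 1L
  lw <- walks_from(g, idx, node, !rev, flip_off, left + 1L, max_walks)
  over <- isTRUE(attr(lw, "overflow"))
  rw <- walks_from(g, idx, node, rev, off, right, max_walks)
  if (isTRUE(attr(rw, "overflow"))) over <- TRUE
  out <- list()
  for (l in lw) {
    fl <- flip_walk(g, l)      # ends on (node, rev) at the anchor base
    nl <- length(fl$node_id)
    fl$o_end[nl] <- fl$o_end[nl] - 1L   # drop the anchor base
    drop_last <- fl$o_end[nl] < fl$o_start[nl]
    lseq <- substring(fl$seq, 1L, nchar(fl$seq) - 1L)
    for (r in rw) {
      if (drop_last) {
        ids <- c(fl$node_id[-nl], r$node_id)
        rvs <- c(fl$rev[-nl], r$rev)
        os <- c(fl$o_start[-nl], r$o_start)
        oe <- c(fl$o_end[-nl], r$o_end)
      } else {
        ids <- c(fl$node_id, r$node_id[-1L])
        rvs <- c(fl$rev, r$rev[-1L])
        os <- c(fl$o_start, r$o_start[-1L])
        oe <- c(fl$o_end[-nl], r$o_end)
      }
      out[[length(out) + 1L]] <- list(
        node_id = ids, rev = rvs, o_start = os, o_end = oe,
        seq = paste0(lseq, r$seq), anchor_pos = nchar(lseq) + 1L)
      if (length(out) >= max_walks) { over <- TRUE; break }
    }
    if (length(out) >= max_walks) break
  }
  attr(out, "overflow") <- over
  out
}

## Reference steps covering contig span [a, b) (0-based half-open).
steps_from_ref_span <- function(idx, ctg, a, b) {
  tab <- idx$ctg_tab[[ctg]]
  i1 <- findInterval(a, tab$offset)
  i2 <- findInterval(b - 1L, tab$offset)
  ids <- tab$node_id[i1:i2]
  offs <- tab$offset[i1:i2]
  n <- length(ids)
  o_start <- rep(1L, n)
  o_end <- c(offs[-1L], b) - offs    # full nodes except the last
  o_start[1L] <- a - offs[1L] + 1L
  o_end[n] <- b - offs[n]
  list(node_id = ids, rev = rep(FALSE, n), o_start = o_start, o_end = o_end)
}

## Per-node covered intervals (node-forward, 1-based inclusive) and
## traversed edge keys of a graph alignment; steps are already trimmed to
## the covered span, del_iv holds 0-based half-open span-relative intervals
## of graph bases deleted in the read.
alignment_footprint <- function(g, aln) {
  if (length(aln$node_id) == 0L) {
    return(list(nodes = matrix(integer(0), ncol = 3L), edges = character(0)))
  }
  clens <- aln$o_end - aln$o_start + 1L
  ends <- cumsum(clens)
  starts <- c(0L, ends[-length(ends)])
  total <- ends[length(ends)]
  cov <- matrix(c(0L, total), ncol = 2L)
  if (!is.null(aln$del_iv) && nrow(aln$del_iv)) {
    pieces <- list()
    cur <- 0L
    for (j in seq_len(nrow(aln$del_iv))) {
      a <- aln$del_iv[j, 1L]; b <- aln$del_iv[j, 2L]
      if (a > cur) pieces[[length(pieces) + 1L]] <- c(cur, a)
      cur <- max(cur, b)
    }
    if (total > cur) pieces[[length(pieces) + 1L]] <- c(cur, total)
    cov <- if (length(pieces)) do.call(rbind, pieces) else matrix(integer(0), ncol = 2L)
  }
  nodes_out <- list()
  for (i in seq_along(aln$node_id)) {
    a <- starts[i]; b <- ends[i]
    if (!nrow(cov)) break
    ia <- pmax(cov[, 1L], a); ib <- pmin(cov[, 2L], b)
    okv <- ia < ib
    if (any(okv)) {
      os <- aln$o_start[i] + (ia[okv] - a)
      oe <- aln$o_start[i] + (ib[okv] - a) - 1L
      if (aln$rev[i]) {
        len <- g$node_len[aln$node_id[i]]
        t1 <- len - oe + 1L; t2 <- len - os + 1L
        os <- t1; oe <- t2
      }
      nodes_out[[length(nodes_out) + 1L]] <- cbind(aln$node_id[i], os, oe)
    }
  }
  ek <- character(0)
  if (length(aln$node_id) > 1L) {
    sides <- walk_edge_sides(aln$node_id, aln$rev)
    ek <- edge_key(sides[, 1L], sides[, 2L])
  }
  list(nodes = if (length(nodes_out)) do.call(rbind, nodes_out)
       else matrix(integer(0), ncol = 3L),
       edges = ek)
}

#' Map reads to the variation graph
#'
#' Seed-and-extend alignment: exact k-mer seeds anchor candidate placements;
#' candidates on the forward reference path are scored directly against the
#' cached contig sequence, all others (and reference candidates whose linear
#' alignment is imperfect, e.g. reads crossing an SV allele) against
#' enumerated graph walks, using banded affine-gap alignment. The
#' best-scoring placement is reported with a mapping quality from the score
#' gap to the second best. Reads shorter than the seed length or without an
#' acceptable placement are reported unmapped (empty steps, MAPQ 0).
#'
#' @param g A `variation_graph`.
#' @param idx A [graph_index()] of `g`.
#' @param reads List with `name` and `seq` character vectors.
#' @param params [map_params()].
#' @return List of graph alignments; each has steps (`node_id`, `rev`,
#'   `o_start`, `o_end`, trimmed to the aligned span), `del_iv` (span-relative
#'   intervals of graph bases skipped by read deletions), `score`,
#'   `identity`, `mapq`, `strand`.
#' @export
map_reads <- function(g, idx, reads, params = map_params()) {
  k <- idx$k
  n_reads <- length(reads$seq)
  if (n_reads == 0L) return(list())
  seqs <- unname(toupper(reads$seq))
  lens <- nchar(seqs)
  rc <- cpp_revcomp(seqs)

  ok <- which(lens >= k)
  sr_read <- integer(0); sr_q <- integer(0)
  for (len in unique(lens[ok])) {
    ids <- ok[lens[ok] == len]
    offs <- unique(c(seq(1L, len - k + 1L, by = k), len - k + 1L))
    sr_read <- c(sr_read, rep(ids, each = length(offs)))
    sr_q <- c(sr_q, rep(offs, times = length(ids)))
  }
  seeds <- data.table::data.table(
    read = c(sr_read, sr_read),
    strand = rep(c("+", "-"), each = length(sr_read)),
    q = c(sr_q, sr_q),
    kmer = c(substring(seqs[sr_read], sr_q, sr_q + k - 1L),
             substring(rc[sr_read], sr_q, sr_q + k - 1L)))
  hits <- idx$dt[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  data.table::setkey(hits, read)
  ## plain vectors + per-read ranges (avoids per-read data.table overhead)
  h_read <- hits$read; h_strand <- hits$strand; h_q <- hits$q
  h_node <- hits$node; h_rev <- hits$rev; h_off <- hits$off
  grp_lo <- findInterval(seq_len(n_reads) - 1L, h_read) + 1L
  grp_hi <- findInterval(seq_len(n_reads), h_read)

  node_is_ref <- !is.na(g$node_contig)

  out <- vector("list", n_reads)
  empty_aln <- function(name) {
    list(name = name, node_id = integer(0), rev = logical(0),
         o_start = integer(0), o_end = integer(0),
         del_iv = matrix(integer(0), ncol = 2L),
         score = NA_integer_, identity = 0, mapq = 0L, strand = "+")
  }

  for (i in seq_len(n_reads)) {
    len <- lens[i]
    if (len < k) {
      warning("read ", reads$name[i], " shorter than seed length; unmapped")
      out[[i]] <- empty_aln(reads$name[i])
      next
    }
    rng <- if (grp_hi[i] >= grp_lo[i]) grp_lo[i]:grp_hi[i] else integer(0)
    if (!length(rng)) {
      out[[i]] <- empty_aln(reads$name[i])
      next
    }
    band <- params$band %||% (2L + as.integer(ceiling(0.1 * len)))
    ckey <- paste(h_strand[rng], h_node[rng], h_rev[rng], h_off[rng] - h_q[rng])
    uk <- unique(ckey)
    cntv <- tabulate(match(ckey, uk), nbins = length(uk))
    cand_keys <- uk[order(-cntv)][seq_len(min(length(uk), params$max_candidates))]
    placements <- list()
    overflow <- FALSE
    perfect <- len * params$match

    finish_alignment <- function(aln, steps, strand) {
      ## aln: score/nmatch/ops/lens + covered span already mapped onto steps
      del_iv <- matrix(integer(0), ncol = 2L)
      if (length(aln$ops) > 1L) {
        cur <- 0L
        divs <- list()
        for (j in seq_along(aln$ops)) {
          if (aln$ops[j] == 0L) cur <- cur + aln$lens[j]
          else if (aln$ops[j] == 2L) {
            divs[[length(divs) + 1L]] <- c(cur, cur + aln$lens[j])
            cur <- cur + aln$lens[j]
          }
        }
        if (length(divs)) del_iv <- do.call(rbind, divs)
      }
      ## canonical key: a walk and its reverse-complement walk are the same
      ## placement (identical graph footprint)
      n_st <- length(steps$node_id)
      k_fwd <- paste(paste(steps$node_id, collapse = ","),
                     paste(steps$rev + 0L, collapse = ","), steps$o_start[1L])
      flip_os <- g$node_len[steps$node_id[n_st]] - steps$o_end[n_st] + 1L
      k_rev <- paste(paste(rev(steps$node_id), collapse = ","),
                     paste(rev(!steps$rev) + 0L, collapse = ","), flip_os)
      pkey <- min(k_fwd, k_rev)
      prev <- placements[[pkey]]
      if (is.null(prev) || prev$score < aln$score) {
        placements[[pkey]] <<- list(
          score = aln$score, nmatch = aln$nmatch,
          node_id = steps$node_id, rev = steps$rev,
          o_start = steps$o_start, o_end = steps$o_end,
          del_iv = del_iv, strand = strand)
      }
      aln$score
    }

    eval_ref_candidate <- function(node, off, q, strand) {
      ## linear placement on the forward reference path
      ctg <- g$node_contig[node]
      cseq <- idx$ctg_seq[[ctg]]
      L <- nchar(cseq)
      S <- if (strand == "+") seqs[i] else rc[i]
      astart <- g$node_offset[node] + off - 1L - (q - 1L)  # 0-based read start
      if (astart >= 0L && astart + len <= L &&
          substring(cseq, astart + 1L, astart + len) == S) {
        aln <- list(score = perfect, nmatch = len, ops = 0L, lens = len)
        steps <- steps_from_ref_span(idx, ctg, astart, astart + len)
        return(finish_alignment(aln, steps, strand))
      }
      w0 <- max(0L, astart - band)
      w1 <- min(L, astart + len + band)
      if (w1 - w0 < len - band) return(NA_integer_)
      res <- cpp_band_align(S, substring(cseq, w0 + 1L, w1), band,
                            params$match, params$mismatch,
                            params$gap_open, params$gap_extend)
      if (is.na(res$score)) return(NA_integer_)
      a <- w0 + res$ref_start; b <- w0 + res$ref_end
      if (b <= a) return(NA_integer_)
      steps <- steps_from_ref_span(idx, ctg, a, b)
      finish_alignment(list(score = res$score, nmatch = res$nmatch,
                            ops = res$ops, lens = res$lens), steps, strand)
    }

    eval_walk_candidate <- function(node, rev, off, q, strand) {
      S <- if (strand == "+") seqs[i] else rc[i]
      wins <- candidate_windows(g, idx, node, rev, off,
                                left = q - 1L + band,
                                right = len - q + 1L + band,
                                max_walks = params$max_walks)
      if (isTRUE(attr(wins, "overflow"))) overflow <<- TRUE
      best_local <- NA_integer_
      for (w in wins) {
        exp_start <- w$anchor_pos - (q - 1L)
        wlen <- nchar(w$seq)
        aln <- NULL
        if (exp_start >= 1L && exp_start + len - 1L <= wlen &&
            substring(w$seq, exp_start, exp_start + len - 1L) == S) {
          aln <- list(score = perfect, ref_start = exp_start - 1L,
                      ref_end = exp_start - 1L + len, nmatch = len,
                      ops = 0L, lens = len)
        } else {
          w0 <- max(1L, exp_start - band)
          w1 <- min(wlen, exp_start + len - 1L + band)
          if (w1 - w0 + 1L < len - band) next
          res <- cpp_band_align(S, substring(w$seq, w0, w1), band,
                                params$match, params$mismatch,
                                params$gap_open, params$gap_extend)
          if (is.na(res$score)) next
          res$ref_start <- res$ref_start + w0 - 1L
          res$ref_end <- res$ref_end + w0 - 1L
          aln <- res
        }
        clens <- w$o_end - w$o_start + 1L
        ends_w <- cumsum(clens)
        starts_w <- c(0L, ends_w[-length(ends_w)])
        keep <- which(starts_w < aln$ref_end & ends_w > aln$ref_start)
        k1 <- keep[1L]; k2 <- keep[length(keep)]
        os <- w$o_start[keep]; oe <- w$o_end[keep]
        os[1L] <- w$o_start[k1] + (aln$ref_start - starts_w[k1])
        oe[length(oe)] <- w$o_start[k2] + (aln$ref_end - 1L - starts_w[k2])
        sc <- finish_alignment(
          list(score = aln$score, nmatch = aln$nmatch, ops = aln$ops,
               lens = aln$lens),
          list(node_id = w$node_id[keep], rev = w$rev[keep],
               o_start = os, o_end = oe), strand)
        if (is.na(best_local) || sc > best_local) best_local <- sc
      }
      best_local
    }

    cands <- lapply(cand_keys, function(ck) {
      r <- rng[which(ckey == ck)[1L]]
      list(strand = h_strand[r], node = h_node[r], rev = h_rev[r],
           off = h_off[r], q = h_q[r])
    })
    deferred <- list()
    for (cd in cands) {
      if (!cd$rev && node_is_ref[cd$node]) {
        sc <- eval_ref_candidate(cd$node, cd$off, cd$q, cd$strand)
        ## a sub-perfect linear alignment may straddle an SV allele: retry
        ## this candidate against graph walks in a second phase
        if (is.na(sc) || sc < perfect) deferred[[length(deferred) + 1L]] <- cd
      } else {
        eval_walk_candidate(cd$node, cd$rev, cd$off, cd$q, cd$strand)
      }
    }
    best_now <- if (length(placements)) {
      max(vapply(placements, `[[`, numeric(1), "score"))
    } else -Inf
    if (best_now < perfect) {
      for (cd in deferred) {
        eval_walk_candidate(cd$node, cd$rev, cd$off, cd$q, cd$strand)
      }
    }

    if (!length(placements)) {
      out[[i]] <- empty_aln(reads$name[i])
      next
    }
    scores <- vapply(placements, `[[`, numeric(1), "score")
    ord <- order(scores, decreasing = TRUE)
    best <- placements[[ord[1L]]]
    if (best$score < params$min_score_frac * len * params$match) {
      out[[i]] <- empty_aln(reads$name[i])
      next
    }
    mapq <- if (overflow) {
      0L
    } else if (length(ord) == 1L) {
      params$mapq_cap
    } else {
      gap <- scores[ord[1L]] - scores[ord[2L]]
      as.integer(min(params$mapq_cap, floor(params$mapq_scale * gap)))
    }
    out[[i]] <- list(name = reads$name[i], node_id = best$node_id,
                     rev = best$rev, o_start = best$o_start, o_end = best$o_end,
                     del_iv = best$del_iv, score = best$score,
                     identity = best$nmatch / len, mapq = mapq,
                     strand = best$strand)
  }
  out
}

#' Map one read pair
#'
#' Both mates are mapped independently (pairing is informational only; the
#' coverage index counts each mate as a read).
#'
#' @param g A `variation_graph`.
#' @param idx A [graph_index()].
#' @param read1,read2 Lists with `name`, `seq` (single read each).
#' @param params [map_params()].
#' @return List of two graph alignments.
#' @export
map_read_pair <- function(g, idx, read1, read2, params = map_params()) {
  c(map_reads(g, idx, list(name = read1$name, seq = read1$seq), params),
    map_reads(g, idx, list(name = read2$name, seq = read2$seq), params))
}
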