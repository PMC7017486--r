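#' Genotyper parameters
#'
#' @param min_support Minimum traversal support for a haplotype to be called
#'   (default 1).
#' @param bias Support bias `B`: the site is homozygous for the best
#'   traversal when its support exceeds `B` times the second best
#'   (default 6).
#' @param max_traversals Bound on enumerated haplotypes per snarl
#'   (default 500000); above it, weakly supported alleles are pre-filtered.
#' @param prefilter_support Allele-support threshold used by the pre-filter
#'   (default 1).
#' @return List of parameters.
#' @export
caller_params <- function(min_support = 1, bias = 6, max_traversals = 500000L,
                          prefilter_support = 1) {
  stopifnot(min_support > 0, bias > 0, max_traversals > 0, prefilter_support > 0)
  list(min_support = min_support, bias = bias,
       max_traversals = as.integer(max_traversals),
       prefilter_support = prefilter_support)
}

variant_by_id <- function(g, id) {
  for (v in g$variants) if (v$id == id) return(v)
  stop_graphsv("unknown variant id ", id)
}

## Average support of a walk: mean over the multiset of per-base counts of
## interior nodes (boundary/anchor steps excluded) and counts of all
## traversed edges.
walk_support <- function(g, pack, node_id, rev) {
  n <- length(node_id)
  tot <- 0; cnt <- 0L
  if (n > 2L) {
    for (i in 2L:(n - 1L)) {
      v <- pack$node_base_coverage[[node_id[i]]]
      tot <- tot + sum(v)
      cnt <- cnt + length(v)
    }
  }
  if (n > 1L) {
    sides <- walk_edge_sides(node_id, rev)
    keys <- edge_key(sides[, 1L], sides[, 2L])
    tot <- tot + sum(pack_edge_count(pack, keys))
    cnt <- cnt + length(keys)
  }
  if (cnt == 0L) return(list(average_support = 0, n_bases = 0L, n_edges = 0L))
  list(average_support = tot / cnt,
       n_bases = cnt - (n - 1L), n_edges = n - 1L)
}

#' Average support of a snarl traversal
#'
#' The average over the per-base counts of the traversal's interior nodes
#' and the counts of all traversed edges; boundary nodes are excluded from
#' the base average, and a pure-deletion traversal (no interior node) is
#' averaged over its edges only.
#'
#' @param g A `variation_graph`.
#' @param pack A `pack_index`.
#' @param traversal A traversal (fields `node_id`, `rev`).
#' @return List with `average_support`, `n_bases`, `n_edges`.
#' @export
traversal_support <- function(g, pack, traversal) {
  walk_support(g, pack, traversal$node_id, traversal$rev)
}

## Assemble the walk of one allele combination through a snarl.
## Returns NULL when the combination is edge-inconsistent.
combo_walk <- function(g, snarl, vars, alleles) {
  ctg <- snarl$contig
  tab <- g$contigs[[ctg]]
  rseg_ids <- function(a, b) tab$node_id[tab$offset >= a & tab$offset < b]
  start_node <- side_node(snarl$start)
  end_node <- side_node(snarl$end)
  ids <- start_node
  rvs <- FALSE
  covered_to <- snarl$ref_start
  for (j in seq_along(vars)) {
    v <- vars[[j]]
    a <- alleles[j]
    if (v$rs < covered_to) {
      if (a != 0L) return(NULL)   # allele skipped by an earlier choice
      next
    }
    pre <- rseg_ids(covered_to, v$rs)
    ids <- c(ids, pre)
    rvs <- c(rvs, rep(FALSE, length(pre)))
    w <- v$allele_walks[[a + 1L]]
    nw <- length(w$node_id)
    ids <- c(ids, w$node_id[-1L])
    rvs <- c(rvs, w$rev[-1L])
    anchorR <- w$node_id[nw]
    covered_to <- v$re + g$node_len[anchorR]
  }
  if (ids[length(ids)] != end_node) {
    post <- rseg_ids(covered_to, snarl$ref_end)
    ids <- c(ids, post, end_node)
    rvs <- c(rvs, rep(FALSE, length(post) + 1L))
  }
  list(node_id = ids, rev = rvs)
}

#' Enumerate candidate haplotype traversals of a snarl
#'
#' Renders the Cartesian product of allele choices over the VCF variants
#' contained in the snarl as walks from the snarl start to its end. When
#' the product exceeds `max_traversals`, alleles with average support below
#' `prefilter_support` are dropped per variant (always keeping the
#' reference allele and the best-supported allele) before enumeration;
#' combinations whose alleles cannot be jointly spelled (incompatible
#' overlapping alleles) are dropped.
#'
#' @param g A `variation_graph`.
#' @param snarl A top-level reference snarl.
#' @param pack A `pack_index`.
#' @param params [caller_params()].
#' @return List of traversals (fields `node_id`, `rev`, `alleles` named by
#'   variant id); empty when the site must be skipped.
#' @export
enumerate_traversals <- function(g, snarl, pack, params = caller_params()) {
  vids <- snarl$contained_variant_ids
  if (!length(vids)) return(list())
  vars <- lapply(vids, variant_by_id, g = g)
  ord <- order(vapply(vars, `[[`, integer(1), "rs"))
  vars <- vars[ord]
  allele_sets <- lapply(vars, function(v) seq_len(v$n_alleles) - 1L)
  n_tr <- prod(vapply(allele_sets, length, numeric(1)))
  if (n_tr > params$max_traversals) {
    allele_sets <- lapply(seq_along(vars), function(j) {
      v <- vars[[j]]
      supp <- vapply(seq_len(v$n_alleles), function(ai) {
        w <- v$allele_walks[[ai]]
        walk_support(g, pack, w$node_id, w$rev)$average_support
      }, numeric(1))
      keep <- which(supp >= params$prefilter_support) - 1L
      keep <- sort(unique(c(0L, which.max(supp) - 1L, keep)))
      keep
    })
    n_tr <- prod(vapply(allele_sets, length, numeric(1)))
    if (n_tr > params$max_traversals) {
      warning("snarl ", snarl$contig, ":", snarl$ref_start, "-", snarl$ref_end,
              " still has ", n_tr, " traversals after filtering; site skipped")
      return(list())
    }
  }
  combos <- expand.grid(rev(allele_sets), KEEP.OUT.ATTRS = FALSE)
  combos <- as.matrix(combos[, rev(seq_len(ncol(combos))), drop = FALSE])
  out <- list()
  for (r in seq_len(nrow(combos))) {
    w <- combo_walk(g, snarl, vars, combos[r, ])
    if (is.null(w)) next
    out[[length(out) + 1L]] <- list(
      node_id = w$node_id, rev = w$rev,
      alleles = stats::setNames(as.integer(combos[r, ]),
                                vapply(vars, `[[`, character(1), "id")))
  }
  out
}

## Interior-node ids and edge keys of a traversal.
traversal_elements <- function(g, trav) {
  n <- length(trav$node_id)
  nodes <- if (n > 2L) trav$node_id[2L:(n - 1L)] else integer(0)
  edges <- character(0)
  if (n > 1L) {
    sides <- walk_edge_sides(trav$node_id, trav$rev)
    edges <- edge_key(sides[, 1L], sides[, 2L])
  }
  list(nodes = nodes, edges = edges)
}

## Average support over a traversal's elements, optionally excluding node
## ids / edge keys shared by every candidate traversal of the snarl (shared
## elements carry no information about which haplotype the reads support;
## an inversion's interior nodes are the canonical case).  Falls back to
## all elements when nothing distinguishing remains.
support_excluding <- function(g, pack, elems, excl_nodes, excl_edges) {
  avg_over <- function(nodes, edges) {
    tot <- 0; cnt <- 0L
    for (n in nodes) {
      v <- pack$node_base_coverage[[n]]
      tot <- tot + sum(v); cnt <- cnt + length(v)
    }
    if (length(edges)) {
      tot <- tot + sum(pack_edge_count(pack, edges))
      cnt <- cnt + length(edges)
    }
    if (cnt == 0L) 0 else tot / cnt
  }
  nodes <- setdiff(elems$nodes, excl_nodes)
  edges <- setdiff(elems$edges, excl_edges)
  if (length(nodes) + length(edges) == 0L) {
    return(avg_over(elems$nodes, elems$edges))
  }
  avg_over(nodes, edges)
}

## The published calling rules, applied in order to the supports of the two
## most supported traversals (strict inequalities as printed): homozygous
## when best > min_support and best > B * second; else heterozygous when
## second > min_support; else homozygous for the best when it alone exceeds
## min_support (only supported haplotype); else no call.
apply_genotype_rules <- function(s1, s2, params = caller_params()) {
  B <- params$bias; ms <- params$min_support
  if (s1 > ms && s1 > B * s2) return("hom")
  if (s2 > ms) return("het")
  if (s1 > ms) return("hom")
  "no_call"
}

#' Genotype one snarl from traversal supports
#'
#' The two most supported traversals are selected (ties broken
#' deterministically: reference alleles first, then lexicographically
#' smaller allele vectors). If the best support exceeds `min_support` and is
#' more than `bias` times the second best, the site is homozygous for the
#' best traversal; else if the second best exceeds `min_support` the site is
#' heterozygous for the top two; else if the best exceeds `min_support` the
#' site is homozygous for the best (the only supported haplotype);
#' otherwise no call is made.
#'
#' @param g A `variation_graph`.
#' @param snarl A top-level reference snarl (with `contained_variant_ids`).
#' @param pack A `pack_index`.
#' @param params [caller_params()].
#' @return A genotype call: `genotype` (two allele vectors or NULL),
#'   `best`/`second` traversals, `supports`, `quality`.
#' @export
genotype_snarl <- function(g, snarl, pack, params = caller_params()) {
  travs <- enumerate_traversals(g, snarl, pack, params)
  no_call <- list(snarl = snarl, genotype = NULL, best = NULL, second = NULL,
                  supports = c(0, 0), quality = 0L,
                  variant_ids = snarl$contained_variant_ids)
  if (!length(travs)) return(no_call)
  elems <- lapply(travs, traversal_elements, g = g)
  shared_nodes <- Reduce(intersect, lapply(elems, `[[`, "nodes"))
  shared_edges <- Reduce(intersect, lapply(elems, `[[`, "edges"))
  supp <- vapply(seq_along(travs), function(i) {
    support_excluding(g, pack, elems[[i]], shared_nodes, shared_edges)
  }, numeric(1))
  is_ref <- vapply(travs, function(tr) all(tr$alleles == 0L), logical(1))
  akey <- vapply(travs, function(tr) paste(tr$alleles, collapse = ","), character(1))
  ord <- order(-supp, !is_ref, akey)
  best <- travs[[ord[1L]]]
  s1 <- supp[ord[1L]]
  second <- if (length(ord) > 1L) travs[[ord[2L]]] else NULL
  s2 <- if (length(ord) > 1L) supp[ord[2L]] else 0
  decision <- apply_genotype_rules(s1, s2, params)
  if (decision == "no_call") return(no_call)
  gt <- if (decision == "het") {
    list(best$alleles, second$alleles)
  } else {
    list(best$alleles, best$alleles)
  }
  q <- round(10 * log10((s1 + s2) * min(1, s1 / (params$bias * s2 + 1e-9)) + 1))
  list(snarl = snarl, genotype = gt, best = best, second = second,
       supports = c(s1, s2), quality = as.integer(q),
       variant_ids = snarl$contained_variant_ids)
}

#' Convert genotype calls to VCF records
#'
#' Emits one output record per input VCF record with GT from the two chosen
#' traversals' allele assignments, FORMAT fields DP (site support), AD
#' (support of the chosen traversals per allele), GQ, and the call quality
#' as QUAL. Sites without a call are written as `./.`.
#'
#' @param g A `variation_graph`.
#' @param calls List of genotype calls from [genotype_snarl()].
#' @param input_records Record table the graph was built from.
#' @param sample_name Name of the emitted sample column.
#' @return VCF record table (single sample).
#' @export
calls_to_vcf <- function(g, calls, input_records, sample_name = "SAMPLE") {
  by_var <- list()
  for (cl in calls) {
    for (vid in cl$variant_ids) by_var[[vid]] <- cl
  }
  rec <- data.table::data.table(
    chrom = input_records$chrom, pos = input_records$pos, id = input_records$id,
    ref = input_records$ref, alt = input_records$alt,
    qual = NA_real_, filter = ".", info = input_records$info,
    format = "GT:DP:AD:GQ")
  smp <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    vid <- rec$id[i]
    cl <- by_var[[vid]]
    n_all <- length(strsplit(rec$alt[i], ",", fixed = TRUE)[[1]]) + 1L
    if (is.null(cl) || is.null(cl$genotype)) {
      smp[i] <- paste0("./.:0:", paste(rep(0L, n_all), collapse = ","), ":0")
      next
    }
    a1 <- cl$genotype[[1L]][[vid]]
    a2 <- cl$genotype[[2L]][[vid]]
    gt <- paste(sort(c(a1, a2)), collapse = "/")
    s1 <- cl$supports[1L]; s2 <- cl$supports[2L]
    ad <- rep(0, n_all)
    ad[a1 + 1L] <- ad[a1 + 1L] + round(s1)
    ad[a2 + 1L] <- ad[a2 + 1L] + round(if (a2 == a1) 0 else s2)
    dp <- round(s1 + s2)
    smp[i] <- paste0(gt, ":", dp, ":", paste(round(ad), collapse = ","), ":",
                     cl$quality)
    rec$qual[i] <- cl$quality
  }
  rec[[sample_name]] <- smp
  data.table::setattr(rec, "samples", sample_name)
  rec[]
}

#' Genotype every site of a variation graph
#'
#' Driver: find snarls, keep top-level reference-anchored ones, genotype
#' each snarl containing VCF variants from the pack index, and emit a
#' genotyped single-sample VCF. Deterministic given identical inputs.
#'
#' @param g A `variation_graph`.
#' @param pack A `pack_index`.
#' @param input_records Record table the graph was built from (VCF path also
#'   accepted).
#' @param params [caller_params()].
#' @param sample_name Output sample name.
#' @param snarls Optional precomputed output of [top_level_reference_snarls()].
#' @return VCF record table (single sample) with attribute `calls`.
#' @export
genotype_graph <- function(g, pack, input_records, params = caller_params(),
                           sample_name = "SAMPLE", snarls = NULL) {
  if (is.character(input_records)) input_records <- read_vcf(input_records)
  if (is.null(snarls)) {
    snarls <- top_level_reference_snarls(g, find_snarls(g))
  }
  snarls <- Filter(function(s) length(s$contained_variant_ids) > 0L, snarls)
  calls <- lapply(snarls, function(s) genotype_snarl(g, s, pack, params))
  out <- calls_to_vcf(g, calls, input_records, sample_name)
  data.table::setattr(out, "calls", calls)
  out
}
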