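#' Compute the compressed coverage ("pack") index
#'
#' Single pass over a stream of graph alignments: every alignment with
#' mapping quality at least `min_mapq` increments each node base it covers
#' (graph bases skipped by read deletions are not covered) and each edge it
#' traverses by one. The result is order-independent.
#'
#' @param g A `variation_graph`.
#' @param alignments List of graph alignments from [map_reads()].
#' @param min_mapq Mapping-quality threshold (default 5).
#' @return A `pack_index`: `node_base_coverage` (list of integer vectors,
#'   one per node), `edge_coverage` (named integer vector keyed by edge),
#'   `min_mapq_applied`.
#' @export
compute_pack <- function(g, alignments, min_mapq = 5L) {
  cov <- lapply(g$node_len, function(l) integer(l))
  edge_keys <- character(0)
  n_used <- 0L
  for (aln in alignments) {
    if (is.null(aln$mapq) || aln$mapq < min_mapq) next
    if (length(aln$node_id) == 0L) next
    if (any(aln$node_id < 1L | aln$node_id > length(g$node_seq))) {
      stop_graphsv("alignment ", aln$name %||% "?", " references unknown nodes")
    }
    fp <- alignment_footprint(g, aln)
    if (nrow(fp$nodes)) {
      for (j in seq_len(nrow(fp$nodes))) {
        n <- fp$nodes[j, 1L]
        cov[[n]][fp$nodes[j, 2L]:fp$nodes[j, 3L]] <-
          cov[[n]][fp$nodes[j, 2L]:fp$nodes[j, 3L]] + 1L
      }
    }
    if (length(fp$edges)) edge_keys <- c(edge_keys, fp$edges)
    n_used <- n_used + 1L
  }
  ec <- integer(0)
  if (length(edge_keys)) {
    tab <- table(edge_keys)
    ec <- as.integer(tab)
    names(ec) <- names(tab)
  }
  structure(list(node_base_coverage = cov, edge_coverage = ec,
                 min_mapq_applied = as.integer(min_mapq),
                 n_alignments_used = n_used),
            class = "pack_index")
}

#' @export
print.pack_index <- function(x, ...) {
  tot <- sum(vapply(x$node_base_coverage, sum, numeric(1)))
  cat("pack_index:", length(x$node_base_coverage), "nodes,",
      length(x$edge_coverage), "covered edges; total base coverage", tot,
      "(MAPQ >=", x$min_mapq_applied, ",", x$n_alignments_used,
      "alignments)\n")
  invisible(x)
}

## Edge coverage lookup (0 when unseen).
pack_edge_count <- function(pack, key) {
  v <- pack$edge_coverage[key]
  ifelse(is.na(v), 0L, v)
}

#' Write graph alignments as JSON lines
#'
#' One JSON object per line; streams in constant memory per alignment.
#'
#' @param alignments List of graph alignments.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (aln in alignments) {
    obj <- list(name = aln$name,
                steps = lapply(seq_along(aln$node_id), function(i) {
                  list(id = aln$node_id[i], rev = aln$rev[i],
                       o_start = aln$o_start[i], o_end = aln$o_end[i])
                }),
                del_iv = if (nrow(aln$del_iv)) {
                  lapply(seq_len(nrow(aln$del_iv)),
                         function(j) as.list(aln$del_iv[j, ]))
                } else list(),
                score = aln$score, identity = aln$identity,
                mapq = aln$mapq, strand = aln$strand)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  }
  invisible(path)
}

#' Read graph alignments from JSON lines
#'
#' @param path Path to a JSON-lines alignment file.
#' @return List of graph alignments.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop_graphsv("malformed alignment JSON at line ", i, ": ",
                                   conditionMessage(e))
                    })
    st <- obj$steps
    di <- if (length(obj$del_iv)) {
      do.call(rbind, lapply(obj$del_iv, function(v) as.integer(unlist(v))))
    } else matrix(integer(0), ncol = 2L)
    out[[i]] <- list(
      name = obj$name,
      node_id = vapply(st, function(s) as.integer(s$id), integer(1)),
      rev = vapply(st, function(s) isTRUE(s$rev), logical(1)),
      o_start = vapply(st, function(s) as.integer(s$o_start), integer(1)),
      o_end = vapply(st, function(s) as.integer(s$o_end), integer(1)),
      del_iv = di,
      score = if (is.null(obj$score)) NA_integer_ else as.integer(obj$score),
      identity = as.numeric(obj$identity %||% 0),
      mapq = as.integer(obj$mapq %||% 0L),
      strand = obj$strand %||% "+")
  }
  out
}

#' Serialize a pack index to JSON
#'
#' @param pack A `pack_index`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pack <- function(pack, path) {
  obj <- list(min_mapq = pack$min_mapq_applied,
              n_alignments_used = pack$n_alignments_used,
              node_base_coverage = pack$node_base_coverage,
              edge_coverage = as.list(pack$edge_coverage))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pack index from JSON
#'
#' @param path Path to a pack JSON file.
#' @return A `pack_index`.
#' @export
read_pack <- function(path) {
  obj <- jsonlite::read_json(path)
  ec <- vapply(obj$edge_coverage, function(v) as.integer(v), integer(1))
  structure(list(
    node_base_coverage = lapply(obj$node_base_coverage,
                                function(v) as.integer(unlist(v))),
    edge_coverage = ec,
    min_mapq_applied = as.integer(obj$min_mapq),
    n_alignments_used = as.integer(obj$n_alignments_used %||% NA_integer_)
  ), class = "pack_index")
}
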