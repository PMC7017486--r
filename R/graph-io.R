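#' Serialize a variation graph to JSON
#'
#' Schema: `{"nodes":[{"id","seq"}], "edges":[{"from","from_end","to","to_end"}],
#' "paths":[{"name","steps":[{"id","rev"}],"reference":bool}],
#' "variants":[{"id","contig","pos","rs","re","svtypes","alleles":[[{"id","rev"}]]}]}`.
#' Node ends are `"left"`/`"right"`; `rs`/`re` are the 0-based half-open
#' breakpoint interval of the variant on its contig.
#'
#' @param g A `variation_graph`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_graph <- function(g, path) {
  steps_js <- function(node_id, rev) {
    lapply(seq_along(node_id), function(i) list(id = node_id[i], rev = rev[i]))
  }
  obj <- list(
    nodes = lapply(seq_along(g$node_seq), function(i) {
      nd <- list(id = i, seq = g$node_seq[i])
      if (!is.na(g$node_contig[i])) {
        nd$contig <- g$node_contig[i]; nd$offset <- g$node_offset[i]
      }
      nd
    }),
    edges = lapply(seq_len(nrow(g$edges)), function(j) {
      list(from = side_node(g$edges[j, 1L]), from_end = side_end(g$edges[j, 1L]),
           to = side_node(g$edges[j, 2L]), to_end = side_end(g$edges[j, 2L]))
    }),
    paths = lapply(g$paths, function(p) {
      list(name = p$name, steps = steps_js(p$node_id, p$rev),
           reference = p$is_reference)
    }),
    variants = lapply(g$variants, function(v) {
      list(id = v$id, contig = v$contig, pos = v$pos, rs = v$rs, re = v$re,
           svtypes = as.list(v$svtypes),
           alleles = lapply(v$allele_walks, function(w) steps_js(w$node_id, w$rev)))
    }),
    max_node_len = g$max_node_len
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a variation graph from JSON
#'
#' Validates the schema ([write_graph()]) and referential integrity: every
#' edge and path step must reference an existing node.
#'
#' @param path Path to a graph JSON file.
#' @return A `variation_graph`.
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$nodes) || is.null(obj$edges) || is.null(obj$paths)) {
    stop_graphsv("graph JSON missing nodes/edges/paths: ", path)
  }
  ids <- vapply(obj$nodes, function(n) as.integer(n$id), integer(1))
  if (anyDuplicated(ids)) stop_graphsv("duplicate node ids in ", path)
  n <- length(ids)
  node_seq <- character(n); node_contig <- rep(NA_character_, n)
  node_offset <- rep(NA_integer_, n)
  for (nd in obj$nodes) {
    i <- as.integer(nd$id)
    if (i < 1L || i > n) stop_graphsv("node ids must be 1..n_nodes (got ", i, ")")
    node_seq[i] <- toupper(nd$seq)
    if (!is.null(nd$contig)) {
      node_contig[i] <- nd$contig; node_offset[i] <- as.integer(nd$offset)
    }
  }
  if (any(!grepl("^[ACGTN]+$", node_seq))) {
    stop_graphsv("node sequences must be non-empty over ACGTN")
  }
  chk_node <- function(i, what) {
    if (is.na(i) || i < 1L || i > n) {
      stop_graphsv(what, " references missing node ", i)
    }
    i
  }
  em <- matrix(0L, nrow = length(obj$edges), ncol = 2L)
  for (j in seq_along(obj$edges)) {
    e <- obj$edges[[j]]
    s1 <- side_id(chk_node(as.integer(e$from), paste0("edge ", j)), e$from_end)
    s2 <- side_id(chk_node(as.integer(e$to), paste0("edge ", j)), e$to_end)
    em[j, ] <- c(min(s1, s2), max(s1, s2))
  }
  em <- unique(em)
  em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  parse_steps <- function(steps, what) {
    list(node_id = vapply(steps, function(s) chk_node(as.integer(s$id), what), integer(1)),
         rev = vapply(steps, function(s) isTRUE(s$rev), logical(1)))
  }
  paths <- lapply(obj$paths, function(p) {
    st <- parse_steps(p$steps, paste0("path ", p$name))
    list(name = p$name, node_id = st$node_id, rev = st$rev,
         is_reference = isTRUE(p$reference))
  })
  contigs <- list()
  for (p in paths) {
    if (p$is_reference) {
      off <- node_offset[p$node_id]
      contigs[[p$name]] <- list(node_id = p$node_id, offset = off,
                                len = sum(nchar(node_seq[p$node_id])))
    }
  }
  variants <- lapply(obj$variants %||% list(), function(v) {
    list(id = v$id, contig = v$contig, pos = as.integer(v$pos),
         rs = as.integer(v$rs), re = as.integer(v$re),
         n_alleles = length(v$alleles),
         allele_walks = lapply(v$alleles, parse_steps,
                               what = paste0("variant ", v$id)),
         svtypes = unlist(v$svtypes))
  })
  g <- structure(list(
    node_seq = node_seq, node_len = nchar(node_seq),
    node_contig = node_contig, node_offset = node_offset,
    edges = em, paths = paths, variants = variants, contigs = contigs,
    max_node_len = as.integer(obj$max_node_len %||% 1024L)
  ), class = "variation_graph")
  g
}
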