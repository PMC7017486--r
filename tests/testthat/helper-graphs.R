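## Hand-built variation graphs and random VCF-derived fixtures.

side_of <- function(node_id, end) graphsv::side(node_id, end)

## Build a variation_graph directly from node sequences and side edges.
## seqs: named character; edges: list of c(node_a, end_a, node_b, end_b)
## using names of seqs; ref_path: names of the reference walk (forward).
make_graph <- function(seqs, edges, ref_path = NULL) {
  ids <- stats::setNames(seq_along(seqs), names(seqs))
  em <- matrix(0L, nrow = length(edges), ncol = 2L)
  for (j in seq_along(edges)) {
    e <- edges[[j]]
    s1 <- side_of(ids[[e[1]]], e[2])
    s2 <- side_of(ids[[e[3]]], e[4])
    em[j, ] <- c(min(s1, s2), max(s1, s2))
  }
  em <- unique(em)
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  node_contig <- rep(NA_character_, length(seqs))
  node_offset <- rep(NA_integer_, length(seqs))
  paths <- list()
  contigs <- list()
  if (!is.null(ref_path)) {
    rid <- ids[ref_path]
    off <- c(0L, cumsum(nchar(seqs[ref_path])))[seq_along(rid)]
    node_contig[rid] <- "ref"
    node_offset[rid] <- off
    paths <- list(list(name = "ref", node_id = unname(rid),
                       rev = rep(FALSE, length(rid)), is_reference = TRUE))
    contigs <- list(ref = list(node_id = unname(rid), offset = unname(off),
                               len = sum(nchar(seqs[ref_path]))))
  }
  structure(list(
    node_seq = unname(toupper(seqs)), node_len = unname(nchar(seqs)),
    node_contig = node_contig, node_offset = node_offset,
    edges = em, paths = paths, variants = list(), contigs = contigs,
    max_node_len = 1024L
  ), class = "variation_graph")
}

## The canonical bubble: A -> {B | C} -> D.
bubble_graph <- function() {
  make_graph(
    seqs = c(A = "ACGTA", B = "GGG", C = "TTT", D = "CATGC"),
    edges = list(c("A", "right", "B", "left"), c("A", "right", "C", "left"),
                 c("B", "right", "D", "left"), c("C", "right", "D", "left")),
    ref_path = c("A", "B", "D"))
}

## Two chained bubbles: A -> {B | C} -> D -> {E | F} -> G.
chain_graph <- function() {
  make_graph(
    seqs = c(A = "ACGTA", B = "GGG", C = "TTT", D = "CATGC",
             E = "AAA", F = "CCC", G = "TGACT"),
    edges = list(c("A", "right", "B", "left"), c("A", "right", "C", "left"),
                 c("B", "right", "D", "left"), c("C", "right", "D", "left"),
                 c("D", "right", "E", "left"), c("D", "right", "F", "left"),
                 c("E", "right", "G", "left"), c("F", "right", "G", "left")),
    ref_path = c("A", "B", "D", "E", "G"))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

## A random small VCF-derived graph: contig of `len` bp carrying up to
## `n_var` small variants (deletion / insertion / inversion), node cap
## `max_node_len` to vary the node structure.
random_vcf_graph <- function(seed, n_var = 3, len = 300, max_node_len = 64) {
  set.seed(seed)
  genome <- c(chrT = random_dna(len))
  pos <- 2L
  recs <- list()
  i <- 0L
  while (length(recs) < n_var && pos < len - 60L) {
    gap <- sample(15:40, 1)
    pos <- pos + gap
    sz <- sample(4:25, 1)
    if (pos + sz + 2L >= len) break
    ty <- sample(c("DEL", "INS", "INV"), 1)
    i <- i + 1L
    pad <- substring(genome, pos, pos)
    if (ty == "DEL") {
      recs[[i]] <- data.table::data.table(
        chrom = "chrT", pos = pos, id = paste0("v", i),
        ref = substring(genome, pos, pos + sz), alt = pad,
        qual = NA_real_, filter = ".", info = ".")
      pos <- pos + sz + 1L
    } else if (ty == "INS") {
      recs[[i]] <- data.table::data.table(
        chrom = "chrT", pos = pos, id = paste0("v", i),
        ref = pad, alt = paste0(pad, random_dna(sz)),
        qual = NA_real_, filter = ".", info = ".")
      pos <- pos + 1L
    } else {
      seg <- substring(genome, pos + 1L, pos + sz)
      recs[[i]] <- data.table::data.table(
        chrom = "chrT", pos = pos, id = paste0("v", i),
        ref = paste0(pad, seg), alt = paste0(pad, graphsv::revcomp(seg)),
        qual = NA_real_, filter = ".", info = ".")
      pos <- pos + sz + 1L
    }
  }
  rec <- data.table::rbindlist(recs)
  list(genome = genome, records = rec,
       graph = build_graph(genome, rec, max_node_len = max_node_len))
}

## Synthetic pack index with constant per-node coverage and explicit edge
## counts (named by edge key, or a flat value for all graph edges).
make_pack <- function(g, node_cov = 0, edge_cov = 0) {
  cov <- lapply(seq_along(g$node_len), function(i) {
    v <- if (is.list(node_cov)) node_cov[[i]] %||% 0 else node_cov
    if (length(v) == 1L) rep(as.integer(v), g$node_len[i]) else as.integer(v)
  })
  keys <- graphsv:::edge_key(g$edges[, 1], g$edges[, 2])
  ec <- if (is.numeric(edge_cov) && is.null(names(edge_cov))) {
    stats::setNames(rep(as.integer(edge_cov), length(keys)), keys)
  } else {
    base <- stats::setNames(rep(0L, length(keys)), keys)
    base[names(edge_cov)] <- as.integer(edge_cov)
    base
  }
  structure(list(node_base_coverage = cov, edge_coverage = ec,
                 min_mapq_applied = 5L, n_alignments_used = NA_integer_),
            class = "pack_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
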