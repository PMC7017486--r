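make_ref_graph <- function(seed = 31, len = 2000, records = NULL) {
  set.seed(seed)
  genome <- c(chrM = random_dna(len))
  if (is.null(records)) {
    records <- data.table::data.table(
      chrom = character(0), pos = integer(0), id = character(0),
      ref = character(0), alt = character(0), qual = numeric(0),
      filter = character(0), info = character(0))
  }
  g <- build_graph(genome, records, max_node_len = 512L)
  list(genome = genome, g = g, idx = graph_index(g))
}

## spell the aligned span of a graph alignment from its step ranges
aln_seq <- function(g, aln) {
  paste(vapply(seq_along(aln$node_id), function(i) {
    os <- if (aln$rev[i]) revcomp(g$node_seq[aln$node_id[i]])
          else g$node_seq[aln$node_id[i]]
    substring(os, aln$o_start[i], aln$o_end[i])
  }, character(1)), collapse = "")
}

test_that("an error-free reference read maps uniquely with identity 1", {
  fx <- make_ref_graph(31)
  S <- substring(fx$genome, 501, 650)
  aln <- map_reads(fx$g, fx$idx, list(name = "r1", seq = S))[[1]]
  expect_equal(aln$identity, 1)
  expect_equal(aln$mapq, 60)
  expect_identical(aln_seq(fx$g, aln), unname(S))
})

test_that("a read spanning a deletion follows the bypass edge with identity 1", {
  set.seed(32)
  genome <- c(chrM = random_dna(1500))
  rec <- data.table::data.table(
    chrom = "chrM", pos = 700L, id = "del",
    ref = substring(genome, 700, 700), alt = "<DEL>",
    qual = NA_real_, filter = ".", info = "SVTYPE=DEL;END=900")
  g <- build_graph(genome, rec)
  idx <- graph_index(g)
  ## hom-alt haplotype: deletion applied; read across the junction
  hap <- paste0(substring(genome, 1, 700), substring(genome, 901, 1500))
  S <- substring(hap, 630, 779)     # 70 bp left + 80 bp right of the junction
  aln <- map_reads(g, idx, list(name = "r", seq = S))[[1]]
  expect_equal(aln$identity, 1)
  expect_gt(aln$mapq, 5)
  fp <- graphsv:::alignment_footprint(g, aln)
  bypass <- graphsv:::edge_key(side(1, "right"), side(3, "left"))
  expect_true(bypass %in% fp$edges)
})

test_that("reads from a repeated sequence are ambiguous (MAPQ 0)", {
  set.seed(33)
  block <- random_dna(300)
  genome <- c(chrM = paste0(random_dna(400), block, random_dna(400), block,
                            random_dna(200)))
  fx <- list(genome = genome)
  g <- build_graph(genome, data.table::data.table(
    chrom = character(0), pos = integer(0), id = character(0),
    ref = character(0), alt = character(0), qual = numeric(0),
    filter = character(0), info = character(0)))
  idx <- graph_index(g)
  S <- substring(block, 51, 200)
  aln <- map_reads(g, idx, list(name = "r", seq = S))[[1]]
  expect_equal(aln$mapq, 0)
})

test_that("reads shorter than the seed length are unmapped with a warning", {
  fx <- make_ref_graph(34, len = 500)
  expect_warning(
    aln <- map_reads(fx$g, fx$idx, list(name = "tiny", seq = "ACGTACGT")),
    "shorter than")
  expect_length(aln[[1]]$node_id, 0)
  expect_equal(aln[[1]]$mapq, 0)
})

test_that("reverse-strand reads map to the same footprint as their mates", {
  fx <- make_ref_graph(35)
  S <- substring(fx$genome, 301, 450)
  a1 <- map_reads(fx$g, fx$idx, list(name = "f", seq = S))[[1]]
  a2 <- map_reads(fx$g, fx$idx, list(name = "r", seq = revcomp(S)))[[1]]
  f1 <- graphsv:::alignment_footprint(fx$g, a1)
  f2 <- graphsv:::alignment_footprint(fx$g, a2)
  expect_equal(f1$nodes[order(f1$nodes[, 1]), ], f2$nodes[order(f2$nodes[, 1]), ])
  expect_equal(a2$mapq, 60)
})

test_that("pack counting honours the MAPQ threshold and edge traversal", {
  g <- make_graph(c(A = random_dna(10), B = random_dna(8)),
                  edges = list(c("A", "right", "B", "left")),
                  ref_path = c("A", "B"))
  full_a <- list(name = "x", node_id = 1L, rev = FALSE, o_start = 1L,
                 o_end = 10L, del_iv = matrix(integer(0), ncol = 2),
                 score = 10L, identity = 1, mapq = 60L, strand = "+")
  low <- full_a; low$mapq <- 3L
  span <- list(name = "s", node_id = c(1L, 2L), rev = c(FALSE, FALSE),
               o_start = c(6L, 1L), o_end = c(10L, 4L),
               del_iv = matrix(integer(0), ncol = 2),
               score = 9L, identity = 1, mapq = 30L, strand = "+")
  pack <- compute_pack(g, list(full_a, full_a, full_a, low, span))
  expect_equal(pack$node_base_coverage[[1]],
               c(3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L))
  expect_equal(pack$node_base_coverage[[2]], c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  ek <- graphsv:::edge_key(side(1, "right"), side(2, "left"))
  expect_equal(unname(pack$edge_coverage[ek]), 1L)
  ## empty stream
  p0 <- compute_pack(g, list())
  expect_true(all(unlist(p0$node_base_coverage) == 0))
  expect_length(p0$edge_coverage, 0)
  ## unknown node errors
  badaln <- full_a; badaln$node_id <- 99L
  expect_error(compute_pack(g, list(badaln)), "unknown nodes")
})

test_that("read deletions do not cover the deleted graph bases", {
  g <- make_graph(c(A = random_dna(30)), edges = list(), ref_path = "A")
  aln <- list(name = "d", node_id = 1L, rev = FALSE, o_start = 1L, o_end = 20L,
              del_iv = matrix(c(5L, 9L), ncol = 2),  # walk bases [5,9) deleted
              score = 1L, identity = 1, mapq = 60L, strand = "+")
  pack <- compute_pack(g, list(aln))
  cov <- pack$node_base_coverage[[1]]
  expect_equal(which(cov == 1L), c(1:5, 10:20))
})

test_that("pack is order-independent and conserves covered bases", {
  set.seed(36)
  fx <- make_ref_graph(36, len = 3000)
  n <- 400
  starts <- sample(0:(3000 - 150), n, replace = TRUE)
  reads <- list(name = paste0("r", seq_len(n)),
                seq = substring(fx$genome, starts + 1, starts + 150))
  alns <- map_reads(fx$g, fx$idx, reads)
  pack1 <- compute_pack(fx$g, alns)
  pack2 <- compute_pack(fx$g, rev(alns))
  expect_identical(pack1$node_base_coverage, pack2$node_base_coverage)
  expect_identical(sort(pack1$edge_coverage), sort(pack2$edge_coverage))
  ## conservation: error-free reads cover exactly read_length bases each
  used <- sum(vapply(alns, function(a) a$mapq >= 5, logical(1)))
  expect_equal(sum(unlist(pack1$node_base_coverage)), used * 150)
})

test_that("coverage of an embedded haplotype tracks the simulated depth", {
  cfg <- sim_config(n_per_type = 3, n_samples = 1, error_rate = 0)
  ts <- simulate_truth_set(cfg, seed = 37)
  g <- build_graph(ts$genome, ts$truth)
  idx <- graph_index(g)
  hp <- apply_genotypes(ts$genome, ts$truth, "s1")
  d <- 12
  rd <- simulate_reads(hp$haplotypes, d, cfg, seed = 38)
  alns <- map_reads(g, idx, list(name = c(rd$r1$name, rd$r2$name),
                                 seq = c(rd$r1$seq, rd$r2$seq)))
  pack <- compute_pack(g, alns)
  refn <- which(!is.na(g$node_contig))
  cov <- unlist(pack$node_base_coverage[refn])
  cov <- cov[500:(length(cov) - 500)]          # clip contig ends
  se <- sd(cov) / sqrt(length(cov) / 150)      # reads are 150 bp correlated
  expect_lt(abs(mean(cov) - d), 3 * max(se, 0.5))
})

test_that("alignment JSON-lines round-trip and malformed input errors", {
  fx <- make_ref_graph(39, len = 600)
  reads <- list(name = c("a", "b", "c"),
                seq = c(substring(fx$genome, 11, 160),
                        substring(fx$genome, 201, 350),
                        substring(fx$genome, 401, 550)))
  alns <- map_reads(fx$g, fx$idx, reads)
  f <- tempfile(fileext = ".jsonl")
  write_alignments(alns, f)
  back <- read_alignments(f)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$node_id, alns[[i]]$node_id)
    expect_identical(back[[i]]$o_start, alns[[i]]$o_start)
    expect_identical(back[[i]]$mapq, alns[[i]]$mapq)
  }
  ## empty file -> empty stream
  f0 <- tempfile(); writeLines(character(0), f0)
  expect_length(read_alignments(f0), 0)
  ## truncated JSON errors with the line number
  fbad <- tempfile()
  writeLines(c('{"name":"x","steps":[],"del_iv":[],"mapq":0}',
               '{"name":"y","steps":['), fbad)
  expect_error(read_alignments(fbad), "line 2")
})
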