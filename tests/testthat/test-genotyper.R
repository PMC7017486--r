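## One-deletion fixture with a pack crafted to produce chosen supports.
del_fixture <- function(seed = 41, ref_cov = 10, alt_edge = 0, ref_edge = NULL) {
  set.seed(seed)
  genome <- c(chrG = random_dna(400))
  rec <- data.table::data.table(
    chrom = "chrG", pos = 150L, id = "del",
    ref = substring(genome, 150, 150), alt = "<DEL>",
    qual = NA_real_, filter = ".", info = "SVTYPE=DEL;END=250")
  g <- build_graph(genome, rec)
  tl <- Filter(function(s) length(s$contained_variant_ids) > 0,
               top_level_reference_snarls(g, find_snarls(g)))
  ## nodes: 1 = [0,150), 2 = [150,250), 3 = [250,400)
  ek_ref1 <- graphsv:::edge_key(side(1, "right"), side(2, "left"))
  ek_ref2 <- graphsv:::edge_key(side(2, "right"), side(3, "left"))
  ek_del <- graphsv:::edge_key(side(1, "right"), side(3, "left"))
  ec <- c(alt_edge, ref_edge %||% ref_cov, ref_edge %||% ref_cov)
  names(ec) <- c(ek_del, ek_ref1, ek_ref2)
  pack <- make_pack(g, node_cov = list(0, as.integer(ref_cov), 0),
                    edge_cov = ec)
  list(g = g, snarl = tl[[1]], pack = pack, rec = rec, ek_del = ek_del)
}

test_that("a biallelic snarl yields two traversals with the expected supports", {
  fx <- del_fixture(ref_cov = 10, alt_edge = 7)
  trs <- enumerate_traversals(fx$g, fx$snarl, fx$pack)
  expect_length(trs, 2)
  supp <- vapply(trs, function(tr) {
    traversal_support(fx$g, fx$pack, tr)$average_support
  }, numeric(1))
  ## reference traversal: 100 interior bases at 10 plus two edges at 10
  expect_equal(supp[1], (100 * 10 + 2 * 10) / 102)
  ## pure-deletion traversal: single bypass edge only
  expect_equal(supp[2], 7)
})

test_that("traversal support averages bases and edges exactly as printed", {
  g <- make_graph(c(A = "ACGT", B = "TTTT", C = "GGCA"),
                  edges = list(c("A", "right", "B", "left"),
                               c("B", "right", "C", "left")),
                  ref_path = c("A", "B", "C"))
  k1 <- graphsv:::edge_key(side(1, "right"), side(2, "left"))
  k2 <- graphsv:::edge_key(side(2, "right"), side(3, "left"))
  tr <- list(node_id = 1:3, rev = rep(FALSE, 3))
  ## interior node bases {10,10,10,10}, edges {10,10} -> 10
  p1 <- make_pack(g, node_cov = list(0, 10, 0),
                  edge_cov = stats::setNames(c(10, 10), c(k1, k2)))
  expect_equal(traversal_support(g, p1, tr)$average_support, 10)
  ## bases {8,8,8,8}, edges {4,4} -> 40/6
  p2 <- make_pack(g, node_cov = list(0, 8, 0),
                  edge_cov = stats::setNames(c(4, 4), c(k1, k2)))
  s <- traversal_support(g, p2, tr)
  expect_equal(s$average_support, (4 * 8 + 2 * 4) / 6)
  expect_equal(s$n_bases, 4)
  expect_equal(s$n_edges, 2)
})

test_that("the calling rules follow the printed thresholds", {
  ## hom-ref: 30 > 6 * 2
  fx <- del_fixture(ref_cov = 30, alt_edge = 2)
  cl <- genotype_snarl(fx$g, fx$snarl, fx$pack)
  expect_equal(unname(cl$genotype[[1]]["del"]), 0)
  expect_equal(unname(cl$genotype[[2]]["del"]), 0)
  ## het: best 14 (alt), second 11 (ref): ratio < 6, second > 1
  fx <- del_fixture(ref_cov = 11, alt_edge = 14)
  cl <- genotype_snarl(fx$g, fx$snarl, fx$pack)
  expect_setequal(c(cl$genotype[[1]]["del"], cl$genotype[[2]]["del"]), c(0, 1))
  ## no-call: both supports below the minimum
  fx <- del_fixture(ref_cov = 0.5, alt_edge = 0)
  fx$pack$node_base_coverage[[2]] <- rep(0L, 100)
  fx$pack$edge_coverage[] <- 0L
  fx$pack$edge_coverage[fx$ek_del] <- 0L
  cl <- genotype_snarl(fx$g, fx$snarl, fx$pack)
  expect_null(cl$genotype)
})

test_that("rule boundaries match a literal transcription over a support grid", {
  oracle <- function(s1, s2, ms = 1, B = 6) {
    if (s1 > ms && s1 > B * s2) return("hom")
    if (s2 > ms) return("het")
    if (s1 > ms) return("hom")
    "no_call"
  }
  params <- caller_params()
  grid <- expand.grid(s1 = c(0, 0.5, 0.99, 1, 1.01, 2, 5.9, 6, 6.01, 7, 12,
                             12.05, 30, 60),
                      s2 = c(0, 0.5, 0.99, 1, 1.01, 2, 3, 5, 10))
  grid <- grid[grid$s1 >= grid$s2, ]
  for (r in seq_len(nrow(grid))) {
    expect_identical(
      graphsv:::apply_genotype_rules(grid$s1[r], grid$s2[r], params),
      oracle(grid$s1[r], grid$s2[r]),
      info = paste(grid$s1[r], grid$s2[r]))
  }
  ## monotonicity: raising the best support never turns hom into het
  for (s2 in c(0, 0.5, 1, 2, 5)) {
    prev <- "no_call"
    for (s1 in seq(s2, 60, by = 0.25)) {
      d <- graphsv:::apply_genotype_rules(s1, s2, params)
      if (prev == "hom") expect_false(d == "het")
      prev <- d
    }
  }
})

test_that("a snarl holding two biallelic variants enumerates four traversals", {
  set.seed(42)
  genome <- c(chrG = random_dna(300))
  mk_ins <- function(pos, id, seq) data.table::data.table(
    chrom = "chrG", pos = pos, id = id,
    ref = substring(genome, pos, pos), alt = paste0(substring(genome, pos, pos), seq),
    qual = NA_real_, filter = ".", info = ".")
  recs <- rbind(mk_ins(100L, "insA", random_dna(30)),
                mk_ins(102L, "insB", random_dna(25)))
  g <- build_graph(genome, recs)
  ## a joint site spanning both insertion points (their own snarls nest as
  ## chained sites; the enumeration contract is per provided snarl)
  tab <- g$contigs$chrG
  sn <- list(
    start = side(tab$node_id[tab$offset + g$node_len[tab$node_id] == 100L], "right"),
    end = side(tab$node_id[tab$offset == 102L], "left"),
    contig = "chrG", ref_start = 100L, ref_end = 102L, parent = NA,
    contained_variant_ids = c("insA", "insB"))
  pack <- make_pack(g, node_cov = 0, edge_cov = 0)
  trs <- enumerate_traversals(g, sn, pack)
  expect_length(trs, 4)
  akeys <- sort(vapply(trs, function(t) paste(t$alleles, collapse = ","),
                       character(1)))
  expect_identical(akeys, c("0,0", "0,1", "1,0", "1,1"))

  ## het-like support for insA, none for insB: best (0,0), second (1,0)
  insA_node <- which(is.na(g$node_contig))[1]
  mid_node <- tab$node_id[tab$offset == 100L]
  start_node <- graphsv:::side_node(sn$start)
  end_node <- graphsv:::side_node(sn$end)
  cov <- as.list(rep(0, length(g$node_seq)))
  cov[[insA_node]] <- 10
  cov[[mid_node]] <- 20
  ek <- function(n1, e1, n2, e2) graphsv:::edge_key(side(n1, e1), side(n2, e2))
  pack2 <- make_pack(g, node_cov = cov, edge_cov = stats::setNames(
    c(10, 10, 10, 20),
    c(ek(start_node, "right", insA_node, "left"),
      ek(insA_node, "right", mid_node, "left"),
      ek(start_node, "right", mid_node, "left"),
      ek(mid_node, "right", end_node, "left"))))
  cl <- genotype_snarl(g, sn, pack2)
  vcf <- calls_to_vcf(g, list(cl), recs, "S")
  gts <- sub(":.*", "", vcf$S)
  expect_identical(gts, c("0/1", "0/0"))
})

test_that("a triallelic record enumerates three traversals", {
  set.seed(43)
  genome <- c(chrG = random_dna(300))
  rec <- data.table::data.table(
    chrom = "chrG", pos = 120L, id = "multi",
    ref = substring(genome, 120, 150),
    alt = paste0(substring(genome, 120, 120), ",",
                 substring(genome, 120, 120), random_dna(40)),
    qual = NA_real_, filter = ".", info = ".")
  g <- build_graph(genome, rec)
  tl <- Filter(function(s) length(s$contained_variant_ids) > 0,
               top_level_reference_snarls(g, find_snarls(g)))
  expect_length(tl, 1)
  pack <- make_pack(g, 0, 0)
  expect_length(enumerate_traversals(g, tl[[1]], pack), 3)
})

test_that("the traversal-count prefilter drops unsupported alleles", {
  set.seed(44)
  genome <- c(chrG = random_dna(800))
  recs <- data.table::rbindlist(lapply(1:20, function(i) {
    pos <- 300L + 2L * i
    data.table::data.table(
      chrom = "chrG", pos = pos, id = paste0("v", i),
      ref = substring(genome, pos, pos),
      alt = paste0(substring(genome, pos, pos), random_dna(8)),
      qual = NA_real_, filter = ".", info = ".")
  }))
  g <- build_graph(genome, recs)
  ## synthetic outer snarl containing all 20 variants (2^20 > 500,000)
  tab <- g$contigs$chrG
  a <- 302L; b <- 340L
  sn <- list(start = side(tab$node_id[which(tab$offset + g$node_len[tab$node_id] == a)], "right"),
             end = side(tab$node_id[which(tab$offset == b)], "left"),
             contig = "chrG", ref_start = a, ref_end = b, parent = NA,
             contained_variant_ids = recs$id)
  pack <- make_pack(g, 0, 0)   # nothing supported
  expect_equal(prod(vapply(g$variants, `[[`, integer(1), "n_alleles")), 2^20)
  trs <- enumerate_traversals(g, sn, pack, caller_params())
  expect_length(trs, 1)        # only the all-reference haplotype survives
  expect_true(all(trs[[1]]$alleles == 0))
})

test_that("genotype_graph is deterministic and an empty pack yields no-calls", {
  set.seed(45)
  rg <- random_vcf_graph(45, n_var = 3, len = 500, max_node_len = 256)
  pack0 <- make_pack(rg$graph, 0, 0)
  out1 <- genotype_graph(rg$graph, pack0, rg$records, sample_name = "S")
  expect_true(all(grepl("^\\./\\.", out1$S)))
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(out1, f1)
  write_vcf(genotype_graph(rg$graph, pack0, rg$records, sample_name = "S"), f2)
  expect_identical(readLines(f1), readLines(f2))
})
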