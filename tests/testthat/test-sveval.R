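sv_rec <- function(contig = "c1", start, end, svtype, alt_seq = "",
                   genotype = "het", quality = NA_real_, gq = NA_real_,
                   id = "x") {
  size <- if (svtype == "INS") nchar(alt_seq) else end - start
  data.table::data.table(contig = contig, start = as.integer(start),
                         end = as.integer(end), svtype = svtype,
                         alt_seq = alt_seq, size = as.integer(size),
                         genotype = genotype, quality = quality, gq = gq,
                         id = id)
}

test_that("normalization trims alleles and infers SV types and sizes", {
  recs <- data.table::data.table(
    chrom = c("c1", "c1", "c1"), pos = c(100L, 300L, 1000L),
    id = c("a", "b", "c"),
    ref = c("ATTT", "A", "A"),
    alt = c("AT", "A,ATTT", "<DEL>"),
    qual = NA_real_, filter = ".",
    info = c(".", ".", "SVTYPE=DEL;END=1200"))
  n <- normalize(recs)
  expect_equal(nrow(n), 4)   # multi-allelic split into two records
  a <- n[n$id == "a", ]
  expect_identical(a$svtype, "DEL")
  expect_equal(a$size, 2)
  b_ins <- n[n$id == "b" & n$svtype == "INS", ]
  expect_equal(b_ins$size, 3)
  cc <- n[n$id == "c", ]
  expect_equal(cc$size, 200)
  expect_equal(c(cc$start, cc$end), c(1000, 1200))
})

test_that("explicit inversions are recognised by reverse-complement alignment", {
  set.seed(51)
  seg <- random_dna(100)
  expect_true(classify_inversion(seg, revcomp(seg)))
  expect_false(classify_inversion(seg, random_dna(100)))
  expect_false(classify_inversion("ACGTACGT", revcomp("ACGTACGT")))  # <= 10 bp
  ## inversion with a few substitutions still classifies
  mut <- strsplit(revcomp(seg), "")[[1]]
  mut[c(10, 40, 70)] <- c("A", "C", "G")
  expect_true(classify_inversion(seg, paste(mut, collapse = "")))
})

test_that("reciprocal-overlap coverage follows the printed thresholds", {
  opts <- eval_options()
  call <- sv_rec(start = 100, end = 200, svtype = "DEL")
  truth <- sv_rec(start = 105, end = 195, svtype = "DEL")
  expect_equal(match_overlap(call, truth, opts), 0.90)
  expect_gt(match_overlap(truth, call, opts), 0.5)
  far <- sv_rec(start = 195, end = 400, svtype = "DEL")
  expect_equal(match_overlap(call, far, opts), 0)   # RO 5/300 below 10%
  ## union coverage from two fragmented partners
  big <- sv_rec(start = 0, end = 1000, svtype = "DEL")
  frags <- rbind(sv_rec(start = 0, end = 400, svtype = "DEL"),
                 sv_rec(start = 450, end = 1000, svtype = "DEL"))
  expect_equal(match_overlap(big, frags, opts), 0.95)
})

test_that("insertion matching uses the 20 bp gate and per-sequence proportions", {
  set.seed(52)
  opts <- eval_options()
  s <- random_dna(100)
  a <- sv_rec(start = 500, end = 500, svtype = "INS", alt_seq = s)
  b15 <- sv_rec(start = 515, end = 515, svtype = "INS", alt_seq = s)
  expect_equal(match_insertions(a, b15, opts), 1)
  expect_equal(match_insertions(b15, a, opts), 1)
  b25 <- sv_rec(start = 525, end = 525, svtype = "INS", alt_seq = s)
  expect_equal(match_insertions(a, b25, opts), 0)
  ## 100 bp call inside a 300 bp truth: call covered, truth not
  truth300 <- sv_rec(start = 505, end = 505, svtype = "INS",
                     alt_seq = paste0(random_dna(100), s, random_dna(100)))
  expect_gte(match_insertions(a, truth300, opts), 0.99)
  expect_lt(match_insertions(truth300, a, opts), 0.5)
  ## symbolic insertion without sequence is excluded with a warning
  nos <- sv_rec(start = 500, end = 500, svtype = "INS", alt_seq = "")
  nos$size <- 100L
  expect_warning(p <- match_insertions(nos, a, opts), "without sequence")
  expect_equal(p, 0)
})

test_that("het merging: fragments chain, duplicated hets collapse to hom-alt", {
  opts <- eval_options(genotype_mode = TRUE)
  frag <- rbind(sv_rec(start = 100, end = 200, svtype = "DEL", id = "f1"),
                sv_rec(start = 210, end = 300, svtype = "DEL", id = "f2"))
  m <- merge_for_genotype_eval(frag, opts)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 300))
  expect_identical(m$genotype, "het")

  dup <- rbind(sv_rec(start = 100, end = 200, svtype = "DEL", id = "d1"),
               sv_rec(start = 100, end = 200, svtype = "DEL", id = "d2"))
  m2 <- merge_for_genotype_eval(dup, opts)
  expect_equal(nrow(m2), 1)
  expect_identical(m2$genotype, "hom_alt")

  apart <- rbind(sv_rec(start = 100, end = 200, svtype = "DEL", id = "a1"),
                 sv_rec(start = 400, end = 500, svtype = "DEL", id = "a2"))
  m3 <- merge_for_genotype_eval(apart, opts)
  expect_equal(nrow(m3), 2)
  expect_true(all(m3$genotype == "het"))
})

test_that("overlapping het pairs with high RO become one hom-alt record", {
  opts <- eval_options(genotype_mode = TRUE)
  dup <- rbind(sv_rec(start = 100, end = 200, svtype = "DEL", id = "d1"),
               sv_rec(start = 102, end = 200, svtype = "DEL", id = "d2"))
  m <- merge_for_genotype_eval(dup, opts)
  expect_equal(nrow(m), 1)
  expect_identical(m$genotype, "hom_alt")
})

test_that("evaluation counts only records above the size threshold", {
  small <- rbind(sv_rec(start = 100, end = 149, svtype = "DEL", id = "s"),
                 sv_rec(start = 1000, end = 1050, svtype = "DEL", id = "l"))
  ev <- evaluate(small, small)
  expect_equal(ev$TP_call, 1)   # the 49 bp record is matched but not counted
  expect_equal(ev$FN, 0)
  expect_equal(ev$precision, 1)
})

test_that("self-comparison gives perfect precision and recall; empty calls give zero", {
  set.seed(53)
  cfg <- sim_config(n_per_type = 8, n_samples = 1)
  ts <- simulate_truth_set(cfg, seed = 53)
  x <- normalize(ts$truth, ts$genome, sample = "s1")
  ev <- evaluate(x, x)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
  evg <- evaluate(x, x, eval_options(genotype_mode = TRUE))
  expect_equal(evg$f1, 1)
  empty <- x[0, ]
  ev0 <- evaluate(empty, x)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$f1, 0)
})

test_that("coverage proportions are symmetric under role swap", {
  set.seed(54)
  for (rep in 1:20) {
    a <- sv_rec(start = 100, end = 100 + sample(50:500, 1), svtype = "DEL")
    b <- sv_rec(start = 100 + sample(-30:30, 1),
                end = 140 + sample(50:500, 1), svtype = "DEL")
    pab <- match_overlap(a, b)
    ## a's coverage of b computed with roles swapped must be the mirrored
    ## quantity: the same intersection over b's size
    pba <- match_overlap(b, a)
    inter <- max(0, min(a$end, b$end) - max(a$start, b$start))
    ro <- inter / max(a$size, b$size)
    if (ro >= 0.10) {
      expect_equal(pab, inter / a$size)
      expect_equal(pba, inter / b$size)
    } else {
      expect_equal(pab, 0)
      expect_equal(pba, 0)
    }
  }
})

test_that("union coverage agrees with per-base brute force on random cases", {
  set.seed(55)
  for (rep in 1:200) {
    a0 <- sample(0:500, 1)
    a1 <- a0 + sample(50:400, 1)
    call <- sv_rec(start = a0, end = a1, svtype = "DEL")
    nb <- sample(1:4, 1)
    bs <- sample(0:800, nb)
    truth <- data.table::rbindlist(lapply(seq_len(nb), function(j) {
      sv_rec(start = bs[j], end = bs[j] + sample(20:400, 1), svtype = "DEL",
             id = paste0("t", j))
    }))
    got <- match_overlap(call, truth)
    ## brute force: per-base union of candidates passing the RO gate
    covered <- rep(FALSE, a1 - a0)
    for (j in seq_len(nrow(truth))) {
      inter <- max(0, min(a1, truth$end[j]) - max(a0, truth$start[j]))
      ro <- inter / max(a1 - a0, truth$size[j])
      if (ro >= 0.10 && truth$size[j] > 1) {
        lo <- max(a0, truth$start[j]); hi <- min(a1, truth$end[j])
        if (hi > lo) covered[(lo - a0 + 1):(hi - a0)] <- TRUE
      }
    }
    expect_equal(got, sum(covered) / (a1 - a0), info = paste("rep", rep))
  }
})

test_that("breakpoint jitter within 5% of the length keeps all matches", {
  set.seed(56)
  sizes <- c(50, 120, 400, 1000, 5000, 10000)
  starts <- cumsum(c(1000, sizes[-length(sizes)] + 2000))
  truth <- data.table::rbindlist(lapply(seq_along(sizes), function(i) {
    sv_rec(start = starts[i], end = starts[i] + sizes[i], svtype = "DEL",
           id = paste0("t", i))
  }))
  jit <- data.table::copy(truth)
  shift <- pmax(1, floor(sizes * 0.05))
  jit$start <- jit$start + shift * sample(c(-1, 1), length(sizes), TRUE)
  jit$end <- jit$end + shift * sample(c(-1, 1), length(sizes), TRUE)
  jit$size <- jit$end - jit$start
  ev <- evaluate(jit, truth)
  expect_equal(ev$FP, 0)
  expect_equal(ev$FN, 0)
})

test_that("PR curve thresholds are monotone and max-F1 matches a direct scan", {
  set.seed(57)
  truth <- data.table::rbindlist(lapply(1:12, function(i) {
    sv_rec(start = i * 1000, end = i * 1000 + 100 + 10 * i, svtype = "DEL",
           id = paste0("t", i))
  }))
  calls <- data.table::copy(truth[1:9, ])           # 9 true calls
  calls$quality <- c(5, 10, 15, 20, 25, 30, 35, 40, 45)
  fake <- data.table::rbindlist(lapply(1:4, function(i) {
    sv_rec(start = 50000 + i * 1000, end = 50300 + i * 1000, svtype = "DEL",
           quality = c(2, 12, 22, 32)[i], id = paste0("f", i))
  }))
  calls <- rbind(calls, fake)
  pr <- pr_curve(calls, truth)
  expect_true(all(diff(pr$curve$recall) <= 1e-9))   # recall never rises
  ## brute-force max-F1 over every threshold
  f1s <- vapply(sort(unique(c(0, calls$quality))), function(t) {
    evaluate(calls[calls$quality >= t, ], truth)$f1
  }, numeric(1))
  expect_equal(pr$max_f1, max(f1s))
  ## all correct calls at one quality: precision 1 everywhere
  pr2 <- pr_curve(calls[1:9, ], truth)
  expect_true(all(pr2$curve$precision == 1))
})

test_that("region filtering keeps records with at least half their span inside", {
  regions <- data.table::data.table(contig = "c1", start = 0L, end = 1000L)
  del_in <- sv_rec(start = 100, end = 300, svtype = "DEL", id = "in")
  ins_out <- sv_rec(start = 5000, end = 5000, svtype = "INS",
                    alt_seq = random_dna(60), id = "out")
  straddle <- sv_rec(start = 880, end = 1080, svtype = "DEL", id = "str")  # 60% in
  mostly_out <- sv_rec(start = 950, end = 1150, svtype = "DEL", id = "mo") # 25% in
  recs <- rbind(del_in, ins_out, straddle, mostly_out)
  kept <- filter_regions(recs, regions)
  expect_setequal(kept$id, c("in", "str"))
})

test_that("the 90% minimum-coverage replicate is one option away", {
  call <- sv_rec(start = 100, end = 200, svtype = "DEL")
  truth <- sv_rec(start = 100, end = 170, svtype = "DEL")   # covers 70%
  ev50 <- evaluate(call, truth, eval_options(min_coverage = 0.5))
  ev90 <- evaluate(call, truth, eval_options(min_coverage = 0.9))
  expect_equal(ev50$TP_call, 1)
  expect_equal(ev90$TP_call, 0)
})
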