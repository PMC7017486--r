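#' Simulation configuration
#'
#' Parameters of the synthetic SV genotyping experiment: a random genome
#' carrying deletions, insertions, and inversions with an SV-like size
#' distribution, per-sample genotypes drawn uniformly from hom-ref /
#' heterozygous / hom-alt, an approximate-breakpoint catalog with 1-10 bp
#' errors, and paired-end reads over a grid of depths.
#'
#' The size distribution is a stand-in mixture resembling published SV
#' catalogs: 60% log-uniform on [50, 1000] bp, 30% normal(300, 30) truncated
#' at 50 bp (mobile-element-like peak), 10% log-uniform on [1000, 10000] bp.
#'
#' @param genome_length Genome length in bp; `NULL` (default) sizes the
#'   genome automatically to fit the requested catalog plus buffers.
#' @param n_per_type Number of SVs per type (default 1000).
#' @param buffer Minimum separation between consecutive variants in bp
#'   (default 500).
#' @param n_samples Number of diploid samples (default 3).
#' @param depths Sequencing depth grid (default 1, 3, 7, 10, 13, 20).
#' @param read_length Read length in bp (default 150).
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param error_rate Per-base substitution error probability (default 0.002).
#' @param max_bp_error Maximum breakpoint perturbation in bp (default 10).
#' @param size_mix Data frame describing the size mixture (columns `weight`,
#'   `kind` in `logunif`/`norm`, `p1`, `p2`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = NULL, n_per_type = 1000L, buffer = 500L,
                       n_samples = 3L, depths = c(1, 3, 7, 10, 13, 20),
                       read_length = 150L, fragment_mean = 400, fragment_sd = 50,
                       error_rate = 0.002, max_bp_error = 10L,
                       size_mix = NULL) {
  if (is.null(size_mix)) {
    size_mix <- data.frame(
      weight = c(0.6, 0.3, 0.1),
      kind = c("logunif", "norm", "logunif"),
      p1 = c(50, 300, 1000),
      p2 = c(1000, 30, 10000))
  }
  stopifnot(buffer >= 0, all(depths > 0), error_rate >= 0, error_rate <= 1,
            n_per_type > 0, read_length > 0)
  structure(list(genome_length = genome_length, n_per_type = as.integer(n_per_type),
                 buffer = as.integer(buffer), n_samples = as.integer(n_samples),
                 depths = depths, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 error_rate = error_rate, max_bp_error = as.integer(max_bp_error),
                 size_mix = size_mix), class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a random genome
#'
#' @param length Genome length in bp.
#' @param seed Optional RNG seed.
#' @param contig Contig name.
#' @return Named character vector of length one (a FASTA record).
#' @export
simulate_genome <- function(length, seed = NULL, contig = "chrS") {
  stopifnot(length > 0)
  with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    stats::setNames(s, contig)
  })
}

draw_sizes <- function(n, mix) {
  if (n == 0L) return(integer(0))
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  sz <- numeric(n)
  for (k in seq_len(nrow(mix))) {
    idx <- which(comp == k)
    if (!length(idx)) next
    if (mix$kind[k] == "logunif") {
      sz[idx] <- exp(stats::runif(length(idx), log(mix$p1[k]), log(mix$p2[k])))
    } else {
      sz[idx] <- stats::rnorm(length(idx), mix$p1[k], mix$p2[k])
    }
  }
  pmax(50L, as.integer(round(sz)))
}

#' Simulate an SV catalog with per-sample genotypes
#'
#' Places `n_per_type` deletions, insertions, and inversions on the genome in
#' random order, each separated from the next by at least `buffer` bp, with
#' explicit REF/ALT sequences and phased genotypes drawn uniformly from
#' hom-ref, het, and hom-alt for each sample.
#'
#' @param genome Named character vector of length one.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return VCF record table (samples attribute set; phased GT columns).
#' @export
simulate_svs <- function(genome, config = sim_config(), seed = NULL,
                         sizes = NULL) {
  with_seed(seed, {
    ctg <- names(genome)
    L <- nchar(genome[[1]])
    n <- config$n_per_type
    types <- sample(rep(c("DEL", "INS", "INV"), each = n))
    if (is.null(sizes)) sizes <- draw_sizes(length(types), config$size_mix)
    stopifnot(length(sizes) == length(types))
    span <- ifelse(types == "INS", 1L, sizes)
    required <- sum(span) + (length(types) + 1L) * (config$buffer + 2L)
    if (required > L) {
      stop_graphsv("genome too short for the requested catalog: need >= ",
                   required, " bp, have ", L,
                   " (increase genome_length or lower n_per_type)")
    }
    ## distribute the slack over the inter-variant gaps
    slack <- L - required
    cuts <- sort(sample.int(slack + 1L, length(types), replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    rs <- integer(length(types))
    cursor <- config$buffer + 2L + extra[1L]
    recs <- vector("list", length(types))
    n_by_type <- c(DEL = 0L, INS = 0L, INV = 0L)
    for (i in seq_along(types)) {
      rs[i] <- cursor
      ty <- types[i]
      n_by_type[ty] <- n_by_type[ty] + 1L
      id <- paste0("sv_", tolower(ty), "_", n_by_type[ty])
      sz <- sizes[i]
      pad <- substring(genome[[1]], rs[i], rs[i])  # padding base (1-based rs[i])
      if (ty == "DEL") {
        refa <- substring(genome[[1]], rs[i], rs[i] + sz)
        alta <- pad
        info <- paste0("SVTYPE=DEL;END=", rs[i] + sz, ";SVLEN=-", sz)
      } else if (ty == "INV") {
        seg <- substring(genome[[1]], rs[i] + 1L, rs[i] + sz)
        refa <- paste0(pad, seg)
        alta <- paste0(pad, revcomp(seg))
        info <- paste0("SVTYPE=INV;END=", rs[i] + sz, ";SVLEN=", sz)
      } else {
        insseq <- paste(sample(c("A", "C", "G", "T"), sz, replace = TRUE),
                        collapse = "")
        refa <- pad
        alta <- paste0(pad, insseq)
        info <- paste0("SVTYPE=INS;END=", rs[i], ";SVLEN=", sz)
      }
      recs[[i]] <- data.table::data.table(
        chrom = ctg, pos = rs[i], id = id, ref = refa, alta = alta,
        qual = NA_real_, filter = ".", info = info)
      cursor <- cursor + span[i] + config$buffer + 2L +
        if (i < length(types)) extra[i + 1L] else 0L
    }
    out <- data.table::rbindlist(recs)
    data.table::setnames(out, "alta", "alt")
    ## genotypes: uniform over hom-ref / het / hom-alt; het phase uniform
    samples <- paste0("s", seq_len(config$n_samples))
    out$format <- "GT"
    for (s in samples) {
      cls <- sample.int(3L, nrow(out), replace = TRUE)
      phase <- sample(c("0|1", "1|0"), nrow(out), replace = TRUE)
      out[[s]] <- c("0|0", NA, "1|1")[cls]
      out[[s]][cls == 2L] <- phase[cls == 2L]
    }
    data.table::setattr(out, "samples", samples)
    out[]
  })
}

#' Perturb SV breakpoints to emulate an approximate catalog
#'
#' Shifts one or both breakpoints of deletions and inversions by 1 to
#' `max_bp_error` bp; insertions are either shifted or shortened at the
#' flanks by up to `max_bp_error` bp. REF/ALT sequences are recomputed from
#' the genome so every perturbed record stays internally consistent.
#' Genotype columns are dropped (the perturbed VCF is a catalog, not a
#' truth set). `max_bp_error = 0` returns the records unchanged (still
#' without genotypes).
#'
#' @param genome Named character vector of length one.
#' @param truth Record table from [simulate_svs()].
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return Perturbed VCF record table without genotype columns.
#' @export
perturb_breakpoints <- function(genome, truth, config = sim_config(), seed = NULL) {
  with_seed(seed, {
    L <- nchar(genome[[1]])
    maxe <- config$max_bp_error
    out <- data.table::copy(truth[, c("chrom", "pos", "id", "ref", "alt",
                                      "qual", "filter", "info"), with = FALSE])
    if (maxe == 0L) {
      data.table::setattr(out, "samples", character(0))
      return(out[])
    }
    svtype <- info_get(truth$info, "SVTYPE")
    for (i in seq_len(nrow(out))) {
      ty <- svtype[i]
      pos <- truth$pos[i]
      if (ty %in% c("DEL", "INV")) {
        end <- as.integer(info_get(truth$info[i], "END"))
        sz <- end - pos
        repeat {
          mode <- sample(c("start", "end", "both"), 1L)
          d1 <- sample.int(maxe, 1L) * sample(c(-1L, 1L), 1L)
          d2 <- sample.int(maxe, 1L) * sample(c(-1L, 1L), 1L)
          nrs <- pos + if (mode %in% c("start", "both")) d1 else 0L
          nre <- end + if (mode %in% c("end", "both")) d2 else 0L
          if (nre - nrs >= 50L && nrs >= 1L && nre <= L - 1L) break
        }
        pad <- substring(genome[[1]], nrs, nrs)
        seg <- substring(genome[[1]], nrs + 1L, nre)
        out$pos[i] <- nrs
        if (ty == "DEL") {
          out$ref[i] <- paste0(pad, seg)
          out$alt[i] <- pad
          out$info[i] <- paste0("SVTYPE=DEL;END=", nre, ";SVLEN=-", nre - nrs)
        } else {
          out$ref[i] <- paste0(pad, seg)
          out$alt[i] <- paste0(pad, revcomp(seg))
          out$info[i] <- paste0("SVTYPE=INV;END=", nre, ";SVLEN=", nre - nrs)
        }
      } else { # INS: shift the variant or shorten the inserted sequence
        insseq <- substring(truth$alt[i], 2L)
        repeat {
          mode <- sample(c("shift", "shorten"), 1L)
          if (mode == "shift") {
            npos <- pos + sample.int(maxe, 1L) * sample(c(-1L, 1L), 1L)
            nseq <- insseq
          } else {
            npos <- pos
            flank <- sample(c("left", "right", "both"), 1L)
            tl <- if (flank %in% c("left", "both")) sample.int(maxe, 1L) else 0L
            tr <- if (flank %in% c("right", "both")) sample.int(maxe, 1L) else 0L
            nseq <- substring(insseq, 1L + tl, nchar(insseq) - tr)
          }
          if (nchar(nseq) >= 50L && npos >= 1L && npos <= L - 1L) break
        }
        pad <- substring(genome[[1]], npos, npos)
        out$pos[i] <- npos
        out$ref[i] <- pad
        out$alt[i] <- paste0(pad, nseq)
        out$info[i] <- paste0("SVTYPE=INS;END=", npos, ";SVLEN=", nchar(nseq))
      }
    }
    data.table::setattr(out, "samples", character(0))
    out[]
  })
}

#' Apply a sample's genotypes to obtain its two haplotype sequences
#'
#' Variants carrying allele 1 on a haplotype are applied left to right. A
#' liftover table mapping haplotype intervals back to reference intervals is
#' returned for each haplotype.
#'
#' @param genome Named character vector of length one.
#' @param truth Record table from [simulate_svs()] (phased genotypes).
#' @param sample Sample column name.
#' @return List with `haplotypes` (character vector of two sequences) and
#'   `liftover` (list of two `data.table`s with `hap_start`, `hap_end`,
#'   `ref_start`, `ref_end`, 0-based half-open).
#' @export
apply_genotypes <- function(genome, truth, sample) {
  gt <- gt_alleles(truth[[sample]])
  L <- nchar(genome[[1]])
  svtype <- info_get(truth$info, "SVTYPE")
  end <- as.integer(info_get(truth$info, "END"))
  haps <- character(2)
  lift <- vector("list", 2)
  for (h in 1:2) {
    alleles <- gt[, h]
    idx <- which(!is.na(alleles) & alleles == 1L)
    if (any(diff(truth$pos[idx]) < 0)) stop_graphsv("variants out of order")
    cursor <- 0L   # 0-based reference cursor
    hcur <- 0L
    pieces <- character(0)
    rows <- list()
    for (i in idx) {
      rs <- truth$pos[i]           # 0-based core start (padding base is rs-1)
      re <- if (svtype[i] == "INS") rs else end[i]
      if (rs < cursor) stop_graphsv("overlapping variants cannot be applied: ",
                                    truth$id[i])
      pre <- substring(genome[[1]], cursor + 1L, rs)
      core <- switch(svtype[i],
        DEL = "",
        INS = substring(truth$alt[i], 2L),
        INV = revcomp(substring(genome[[1]], rs + 1L, re)))
      pieces <- c(pieces, pre, core)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        hap_start = hcur, hap_end = hcur + nchar(pre),
        ref_start = cursor, ref_end = rs, type = "ref")
      hcur <- hcur + nchar(pre)
      if (nchar(core)) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          hap_start = hcur, hap_end = hcur + nchar(core),
          ref_start = rs, ref_end = re, type = svtype[i])
        hcur <- hcur + nchar(core)
      }
      cursor <- re
    }
    pieces <- c(pieces, substring(genome[[1]], cursor + 1L, L))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      hap_start = hcur, hap_end = hcur + (L - cursor),
      ref_start = cursor, ref_end = L, type = "ref")
    haps[h] <- paste(pieces, collapse = "")
    lift[[h]] <- data.table::rbindlist(rows)
  }
  list(haplotypes = haps, liftover = lift)
}

#' Simulate paired-end reads from a diploid sample
#'
#' Fragments are drawn uniformly along each haplotype (half the requested
#' depth per haplotype); the two mates read the fragment ends from opposite
#' strands. Substitution errors are injected independently per base.
#'
#' @param haplotypes Character vector of two haplotype sequences.
#' @param depth Total diploid depth (x coverage).
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return List with `r1` and `r2`, each `name`/`seq`/`qual` vectors.
#' @export
simulate_reads <- function(haplotypes, depth, config = sim_config(), seed = NULL) {
  with_seed(seed, {
    rl <- config$read_length
    names_all <- seqs1 <- seqs2 <- character(0)
    for (h in seq_along(haplotypes)) {
      hl <- nchar(haplotypes[h])
      if (config$fragment_mean < rl) {
        stop_graphsv("read_length exceeds the mean fragment length")
      }
      nfrag <- round((depth / length(haplotypes)) * hl / (2 * rl))
      if (nfrag < 1) next
      flen <- pmin(hl, pmax(rl, round(stats::rnorm(nfrag, config$fragment_mean,
                                                   config$fragment_sd))))
      fstart <- floor(stats::runif(nfrag, 0, hl - flen + 1))  # 0-based
      fwd <- substring(haplotypes[h], fstart + 1L, fstart + rl)
      rev <- revcomp(substring(haplotypes[h], fstart + flen - rl + 1L,
                               fstart + flen))
      ## which physical strand the fragment was sequenced from
      swap <- stats::runif(nfrag) < 0.5
      r1 <- ifelse(swap, rev, fwd)
      r2 <- ifelse(swap, fwd, rev)
      nm <- paste0("h", h, "_frag", seq_len(nfrag))
      names_all <- c(names_all, nm)
      seqs1 <- c(seqs1, r1)
      seqs2 <- c(seqs2, r2)
    }
    add_errors <- function(seqs, rate) {
      if (rate <= 0) return(seqs)
      nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(nchar(seqs[i]), nerr[i])
        chars <- strsplit(seqs[i], "")[[1]]
        for (p in pos) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        }
        seqs[i] <- paste(chars, collapse = "")
      }
      seqs
    }
    seqs1 <- add_errors(seqs1, config$error_rate)
    seqs2 <- add_errors(seqs2, config$error_rate)
    q <- if (config$error_rate > 0) {
      min(40L, as.integer(round(-10 * log10(config$error_rate))))
    } else 40L
    qc <- strrep(rawToChar(as.raw(33L + q)), config$read_length)
    list(r1 = list(name = names_all, seq = seqs1, qual = rep(qc, length(seqs1))),
         r2 = list(name = names_all, seq = seqs2, qual = rep(qc, length(seqs2))))
  })
}

#' Generate the full synthetic truth set
#'
#' Convenience wrapper: sizes the genome (when `genome_length` is `NULL`),
#' simulates the genome, the genotyped truth catalog, and the
#' breakpoint-perturbed catalog.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return List with `genome`, `truth` (record table), `perturbed`.
#' @export
simulate_truth_set <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    L <- config$genome_length
    sizes <- NULL
    if (is.null(L)) {
      sizes <- draw_sizes(3L * config$n_per_type, config$size_mix)
      L <- as.integer(ceiling(1.25 * (sum(sizes) +
        (3 * config$n_per_type + 1) * (config$buffer + 2))))
    }
    genome <- simulate_genome(L)
    truth <- simulate_svs(genome, config, sizes = sizes)
    perturbed <- perturb_breakpoints(genome, truth, config)
    list(genome = genome, truth = truth, perturbed = perturbed)
  })
}
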