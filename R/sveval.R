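#' Options for SV call-set evaluation
#'
#' Defaults follow the standard SV benchmarking procedure: candidate matches
#' need at least 10% reciprocal overlap; a deletion/inversion is covered when
#' more than 50% of its span is covered by candidates in the other set;
#' insertion pairs at most 20 bp apart are compared by local alignment of
#' their inserted sequences, covered at 50% aligned or more; variants smaller
#' than 50 bp are not counted as TP/FP/FN (but anything larger than 1 bp
#' still contributes coverage); for genotype-level evaluation, heterozygous
#' fragments closer than 20 bp are merged first and heterozygous pairs with
#' 80% reciprocal overlap collapse to a homozygous record.
#'
#' @param min_size Minimum SV size counted in TP/FP/FN (default 50).
#' @param min_ro Minimum reciprocal overlap for candidate partners (0.10).
#' @param min_coverage Coverage proportion for a record to be covered (0.50;
#'   the replicate setting 0.90 is selected by passing `min_coverage = 0.9`).
#' @param ins_max_gap Maximum distance between insertion partners (20 bp).
#' @param genotype_mode Evaluate het/hom-alt strata separately (FALSE).
#' @param regions Optional high-confidence regions (`data.table` with
#'   `contig`, `start`, `end`, 0-based half-open, e.g. from [read_bed()]).
#' @param merge_ro Reciprocal overlap collapsing het pairs to hom-alt (0.80).
#' @param merge_gap Distance for merging fragmented het records (20 bp).
#' @param contributor_min_size Minimum size of coverage contributors (2 bp,
#'   i.e. anything larger than 1 bp).
#' @return List of options.
#' @export
eval_options <- function(min_size = 50L, min_ro = 0.10, min_coverage = 0.50,
                         ins_max_gap = 20L, genotype_mode = FALSE,
                         regions = NULL, merge_ro = 0.80, merge_gap = 20L,
                         contributor_min_size = 2L) {
  list(min_size = as.integer(min_size), min_ro = min_ro,
       min_coverage = min_coverage, ins_max_gap = as.integer(ins_max_gap),
       genotype_mode = isTRUE(genotype_mode), regions = regions,
       merge_ro = merge_ro, merge_gap = as.integer(merge_gap),
       contributor_min_size = as.integer(contributor_min_size))
}

#' Read a BED file of regions
#'
#' @param path BED path (first three columns used).
#' @return `data.table` with `contig`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, select = 1:3,
                          col.names = c("contig", "start", "end"))
  dt[order(dt$contig, dt$start)]
}

#' Classify an explicit ALT allele as an inversion
#'
#' When REF and ALT are both longer than 10 bp, the reverse-complement of
#' the ALT sequence is locally aligned to the REF sequence; the record is an
#' inversion when more than 80% of the shorter sequence aligns.
#'
#' @param ref_seq,alt_seq Core (trimmed) REF and ALT sequences.
#' @return TRUE when classified as an inversion.
#' @export
classify_inversion <- function(ref_seq, alt_seq) {
  if (nchar(ref_seq) <= 10L || nchar(alt_seq) <= 10L) return(FALSE)
  if (revcomp(alt_seq) == ref_seq) return(TRUE)
  al <- sw_align(revcomp(alt_seq), ref_seq)
  short <- min(nchar(ref_seq), nchar(alt_seq))
  max(al$width1, al$width2) / short > 0.80
}

## Smith-Waterman local alignment (match +1, mismatch -1, gap open -3,
## gap extend -1); returns the aligned widths on each sequence.
sw_align <- function(s1, s2, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    ## short bucket key (env variable names are length-limited); exact
    ## sequences verified within the bucket
    key <- paste0(nchar(s1), "_", nchar(s2), "_", substr(s1, 1, 40), "_",
                  substr(s2, 1, 40))
    bucket <- cache[[key]]
    if (!is.null(bucket)) {
      for (ent in bucket) {
        if (ent$s1 == s1 && ent$s2 == s2) return(ent$res)
      }
    }
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(s1, s2, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 3, gapExtension = 1)
  ## aligned width on each sequence: bases of that sequence spanned by the
  ## optimal local alignment
  out <- list(width1 = Biostrings::width(Biostrings::pattern(al)),
              width2 = Biostrings::width(Biostrings::subject(al)))
  if (!is.null(cache)) {
    cache[[key]] <- c(cache[[key]], list(list(s1 = s1, s2 = s2, res = out)))
  }
  out
}

#' Normalize VCF records into SV records
#'
#' Multi-allelic records are split into biallelics; explicit alleles are
#' right-trimmed then left-trimmed; the SV type is inferred from the allele
#' lengths (deletion when REF is longer, insertion when ALT is longer),
#' with explicit inversions recognised by aligning the reverse-complement
#' of the ALT to the REF ([classify_inversion()]). Symbolic
#' `<DEL>`/`<INV>`/`<INS>` alleles are resolved from INFO END/SVLEN (and
#' SEQ for insertions).
#'
#' @param records VCF path or record table from [read_vcf()].
#' @param reference Optional named character vector; REF alleles that do not
#'   match trigger a warning (the record is kept as stated).
#' @param sample Sample column for genotypes (default: first sample; absent
#'   genotypes are marked `missing` and treated as present calls).
#' @return `data.table` of SV records: `contig`, `start`, `end` (0-based
#'   half-open; `end == start` for insertions), `svtype`, `alt_seq`, `size`,
#'   `genotype`, `quality`, `gq`, `id`.
#' @export
normalize <- function(records, reference = NULL, sample = NULL) {
  if (is.character(records)) records <- read_vcf(records)
  samples <- attr(records, "samples") %||% character(0)
  if (is.null(sample) && length(samples)) sample <- samples[1L]
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    alts <- strsplit(rec$alt, ",", fixed = TRUE)[[1]]
    gt <- NULL
    if (!is.null(sample) && sample %in% names(records)) {
      gt <- gt_alleles(rec[[sample]])[1L, ]
    }
    gq <- NA_real_
    if (!is.null(sample) && sample %in% names(records) &&
        !is.null(rec$format) && grepl("GQ", rec$format)) {
      keys <- strsplit(rec$format, ":", fixed = TRUE)[[1]]
      vals <- strsplit(rec[[sample]], ":", fixed = TRUE)[[1]]
      gq <- suppressWarnings(as.numeric(vals[match("GQ", keys)]))
    }
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      genotype <- if (is.null(gt) || all(is.na(gt))) {
        "missing"
      } else {
        n_alt <- sum(gt == ai, na.rm = TRUE)
        if (n_alt == 2L) "hom_alt" else if (n_alt == 1L) "het" else "hom_ref"
      }
      if (grepl("^<", alt)) {
        svtype <- gsub("[<>]", "", alt)
        if (!svtype %in% c("DEL", "INS", "INV")) next
        end <- suppressWarnings(as.integer(info_get(rec$info, "END")))
        svlen <- suppressWarnings(as.integer(info_get(rec$info, "SVLEN")))
        if (is.na(end) && !is.na(svlen)) end <- rec$pos + abs(svlen)
        if (svtype == "INS") {
          seq <- info_get(rec$info, "SEQ")
          size <- if (!is.na(seq)) nchar(seq)
                  else if (!is.na(svlen)) abs(svlen) else NA_integer_
          out[[length(out) + 1L]] <- data.table::data.table(
            contig = rec$chrom, start = rec$pos, end = rec$pos,
            svtype = "INS", alt_seq = if (is.na(seq)) "" else toupper(seq),
            size = size, genotype = genotype, quality = rec$qual, gq = gq,
            id = rec$id)
        } else {
          if (is.na(end) || end <= rec$pos) {
            warning("record ", rec$id, ": symbolic ", alt,
                    " without usable END/SVLEN; skipped")
            next
          }
          out[[length(out) + 1L]] <- data.table::data.table(
            contig = rec$chrom, start = rec$pos, end = end, svtype = svtype,
            alt_seq = "", size = end - rec$pos, genotype = genotype,
            quality = rec$qual, gq = gq, id = rec$id)
        }
      } else {
        refa <- rec$ref
        if (!is.null(reference) && rec$chrom %in% names(reference)) {
          have <- substring(reference[[rec$chrom]], rec$pos,
                            rec$pos + nchar(refa) - 1L)
          if (have != refa) {
            warning("record ", rec$id, ": REF does not match the reference; ",
                    "kept as stated")
          }
        }
        tr <- trim_alleles(refa, alt)
        rs <- rec$pos - 1L + tr$prefix
        re <- rec$pos - 1L + nchar(refa) - tr$suffix
        core_ref <- substring(refa, tr$prefix + 1L, nchar(refa) - tr$suffix)
        core_alt <- substring(alt, tr$prefix + 1L, nchar(alt) - tr$suffix)
        if (classify_inversion(core_ref, core_alt)) {
          out[[length(out) + 1L]] <- data.table::data.table(
            contig = rec$chrom, start = rs, end = re, svtype = "INV",
            alt_seq = "", size = re - rs, genotype = genotype,
            quality = rec$qual, gq = gq, id = rec$id)
        } else if (nchar(core_ref) >= nchar(core_alt)) {
          out[[length(out) + 1L]] <- data.table::data.table(
            contig = rec$chrom, start = rs, end = re, svtype = "DEL",
            alt_seq = core_alt, size = re - rs, genotype = genotype,
            quality = rec$qual, gq = gq, id = rec$id)
        } else {
          out[[length(out) + 1L]] <- data.table::data.table(
            contig = rec$chrom, start = rs, end = re, svtype = "INS",
            alt_seq = core_alt, size = nchar(core_alt), genotype = genotype,
            quality = rec$qual, gq = gq, id = rec$id)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(
      contig = character(0), start = integer(0), end = integer(0),
      svtype = character(0), alt_seq = character(0), size = integer(0),
      genotype = character(0), quality = numeric(0), gq = numeric(0),
      id = character(0)))
  }
  res <- data.table::rbindlist(out)
  res[order(res$contig, res$start, res$end)]
}

#' Coverage annotation by reciprocal overlap (deletions and inversions)
#'
#' For every record of `a`, the proportion of its span covered by the union
#' of records in `b` of the same type that reciprocally overlap it by at
#' least `min_ro` (only contributors larger than 1 bp count); the record is
#' covered when the proportion exceeds `min_coverage`. Applied symmetrically
#' by swapping the arguments.
#'
#' @param a,b SV record tables of one svtype (DEL or INV).
#' @param opts [eval_options()].
#' @return Numeric vector of coverage proportions for the rows of `a`.
#' @export
match_overlap <- function(a, b, opts = eval_options()) {
  prop <- numeric(nrow(a))
  if (!nrow(a) || !nrow(b)) return(prop)
  b <- b[b$size >= opts$contributor_min_size, ]
  if (!nrow(b)) return(prop)
  for (ctg in unique(a$contig)) {
    ai <- which(a$contig == ctg)
    bi <- which(b$contig == ctg)
    if (!length(bi)) next
    ira <- IRanges::IRanges(a$start[ai] + 1L, a$end[ai])
    irb <- IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    ov <- IRanges::findOverlaps(ira, irb)
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    inter <- IRanges::pintersect(ira[q], irb[s])
    w <- IRanges::width(inter)
    ro <- w / pmax(IRanges::width(ira)[q], IRanges::width(irb)[s])
    keep <- ro >= opts$min_ro
    if (!any(keep)) next
    q <- q[keep]; inter <- inter[keep]
    for (qq in unique(q)) {
      u <- IRanges::reduce(inter[q == qq])
      prop[ai[qq]] <- sum(IRanges::width(u)) / IRanges::width(ira)[qq]
    }
  }
  prop
}

#' Coverage annotation by inserted-sequence alignment (insertions)
#'
#' Candidate partners are insertions located no farther than `ins_max_gap`
#' bp apart; their inserted sequences are compared by Smith-Waterman local
#' alignment and each record's proportion is the aligned fraction of its own
#' sequence (maximum over partners). A record is covered when the proportion
#' is at least `min_coverage`.
#'
#' @param a,b Insertion record tables.
#' @param opts [eval_options()].
#' @param cache Optional environment memoising alignments.
#' @return Numeric vector of aligned proportions for the rows of `a`.
#' @export
match_insertions <- function(a, b, opts = eval_options(), cache = NULL) {
  prop <- numeric(nrow(a))
  if (!nrow(a) || !nrow(b)) return(prop)
  noseq <- !nzchar(a$alt_seq)
  if (any(noseq)) {
    warning(sum(noseq), " insertion(s) without sequence excluded from matching")
  }
  b <- b[nzchar(b$alt_seq) & b$size >= opts$contributor_min_size, ]
  if (!nrow(b)) return(prop)
  for (i in which(!noseq)) {
    cand <- which(b$contig == a$contig[i] &
                  abs(b$start - a$start[i]) <= opts$ins_max_gap)
    best <- 0
    for (j in cand) {
      al <- sw_align(a$alt_seq[i], b$alt_seq[j], cache)
      best <- max(best, al$width1 / a$size[i])
    }
    prop[i] <- best
  }
  prop
}

#' Merge heterozygous records for genotype-level evaluation
#'
#' First, chains of heterozygous records of the same type closer than
#' `merge_gap` bp are merged into larger heterozygous records (intervals
#' unioned, insertion sequences concatenated); then pairs of heterozygous
#' records with reciprocal overlap of at least `merge_ro` are collapsed into
#' one homozygous-ALT record.
#'
#' @param records Normalized SV records.
#' @param opts [eval_options()].
#' @return Merged record table.
#' @export
merge_for_genotype_eval <- function(records, opts = eval_options()) {
  out <- list()
  keep <- records[records$genotype != "het", ]
  if (nrow(keep)) out[[length(out) + 1L]] <- keep
  hets <- records[records$genotype == "het", ]
  if (nrow(hets)) {
    hets <- hets[order(hets$contig, hets$start, hets$end)]
    for (ctg in unique(hets$contig)) {
      for (ty in unique(hets$svtype)) {
        hh <- hets[hets$contig == ctg & hets$svtype == ty, ]
        if (!nrow(hh)) next
        ## chain-merge fragments closer than merge_gap; near-duplicate pairs
        ## (reciprocal overlap >= merge_ro) are left for the hom-alt collapse
        pair_ro <- function(i, j) {
          if (ty == "INS") {
            if (abs(hh$start[j] - hh$start[i]) <= opts$merge_gap) {
              min(hh$size[i], hh$size[j]) / max(hh$size[i], hh$size[j])
            } else 0
          } else {
            inter <- max(0L, min(hh$end[i], hh$end[j]) -
                           max(hh$start[i], hh$start[j]))
            inter / max(hh$end[i] - hh$start[i], hh$end[j] - hh$start[j])
          }
        }
        grp <- integer(nrow(hh))
        grp[1L] <- 1L
        if (nrow(hh) > 1L) {
          max_end <- hh$end[1L]
          for (i in 2L:nrow(hh)) {
            gap <- hh$start[i] - max_end
            chain <- gap <= opts$merge_gap && pair_ro(i - 1L, i) < opts$merge_ro
            grp[i] <- if (chain) grp[i - 1L] else grp[i - 1L] + 1L
            max_end <- max(max_end, hh$end[i])
          }
        }
        merged <- hh[, {
          list(start = min(start), end = max(end),
               alt_seq = paste(alt_seq, collapse = ""),
               size = if (ty == "INS") sum(size) else max(end) - min(start),
               genotype = "het", quality = max(quality, na.rm = FALSE),
               gq = suppressWarnings(max(gq)), id = paste(id, collapse = ";"),
               n = .N)
        }, by = list(grp = grp)]
        merged$contig <- ctg; merged$svtype <- ty
        ## collapse het pairs with high reciprocal overlap to hom-alt
        m <- merged
        used <- rep(FALSE, nrow(m))
        for (i in seq_len(nrow(m))) {
          if (used[i]) next
          for (j in seq_len(nrow(m))) {
            if (j <= i || used[j]) next
            ro <- if (ty == "INS") {
              if (abs(m$start[j] - m$start[i]) <= opts$merge_gap) {
                min(m$size[i], m$size[j]) / max(m$size[i], m$size[j])
              } else 0
            } else {
              inter <- max(0L, min(m$end[i], m$end[j]) - max(m$start[i], m$start[j]))
              inter / max(m$end[i] - m$start[i], m$end[j] - m$start[j])
            }
            if (ro >= opts$merge_ro) {
              used[j] <- TRUE
              m$genotype[i] <- "hom_alt"
              m$quality[i] <- max(m$quality[i], m$quality[j], na.rm = FALSE)
            }
          }
        }
        m <- m[!used, ]
        out[[length(out) + 1L]] <- m[, c("contig", "start", "end", "svtype",
                                         "alt_seq", "size", "genotype",
                                         "quality", "gq", "id"), with = FALSE]
      }
    }
  }
  res <- data.table::rbindlist(out, fill = TRUE)
  cols <- c("contig", "start", "end", "svtype", "alt_seq", "size",
            "genotype", "quality", "gq", "id")
  res <- res[, intersect(cols, names(res)), with = FALSE]
  res[order(res$contig, res$start, res$end)]
}

#' Filter records to high-confidence regions
#'
#' A record is retained when at least half of its reference span (the
#' insertion point for insertions) lies within the region set.
#'
#' @param records Normalized SV records.
#' @param regions `data.table` with `contig`, `start`, `end` (0-based
#'   half-open).
#' @return Filtered record table.
#' @export
filter_regions <- function(records, regions) {
  if (is.null(regions) || !nrow(records)) return(records)
  keep <- logical(nrow(records))
  for (ctg in unique(records$contig)) {
    ri <- which(records$contig == ctg)
    rg <- regions[regions$contig == ctg, ]
    if (!nrow(rg)) next
    irr <- IRanges::reduce(IRanges::IRanges(rg$start + 1L, rg$end))
    spans <- IRanges::IRanges(records$start[ri] + 1L,
                              pmax(records$end[ri], records$start[ri] + 1L))
    ov <- IRanges::findOverlaps(spans, irr)
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov)
    w <- IRanges::width(IRanges::pintersect(spans[q],
                                            irr[S4Vectors::subjectHits(ov)]))
    cw <- tapply(w, q, sum)
    qq <- as.integer(names(cw))
    keep[ri[qq]] <- cw / IRanges::width(spans)[qq] >= 0.5
  }
  records[keep, ]
}

## effective quality per the PR-curve rule: QUAL unless missing/all-zero,
## then GQ, then 0.
effective_quality <- function(records) {
  q <- records$quality
  if (all(is.na(q) | q == 0)) q <- records$gq
  q[is.na(q)] <- 0
  q
}

#' Evaluate an SV call set against a truth set
#'
#' Per SV type, calls and truth records are matched by reciprocal overlap
#' (DEL/INV) or inserted-sequence alignment (INS); covered records of the
#' call set are true positives for the precision, covered records of the
#' truth set true positives for the recall; only records of at least
#' `min_size` bp are counted (smaller ones, above 1 bp, still contribute
#' coverage). In genotype mode both sets are merged with
#' [merge_for_genotype_eval()] and the heterozygous and homozygous strata
#' are evaluated separately and summed.
#'
#' @param calls,truth Normalized SV records ([normalize()]).
#' @param opts [eval_options()].
#' @param cache Optional environment for alignment memoisation.
#' @return An `sv_eval` list: counts (`TP_call`, `FP`, `TP_truth`, `FN`),
#'   `precision`, `recall`, `f1`, a per-type `data.table` in `by_type`, and
#'   the annotated record tables.
#' @export
evaluate <- function(calls, truth, opts = eval_options(), cache = NULL) {
  if (!is.null(opts$regions)) {
    calls <- filter_regions(calls, opts$regions)
    truth <- filter_regions(truth, opts$regions)
  }
  calls <- calls[calls$genotype %in% c("het", "hom_alt", "missing"), ]
  truth <- truth[truth$genotype %in% c("het", "hom_alt", "missing"), ]
  miss_ctg <- setdiff(unique(calls$contig), unique(truth$contig))
  if (length(miss_ctg)) {
    warning("contig(s) absent from the truth set: ",
            paste(miss_ctg, collapse = ", "), " (calls there are all FP)")
  }
  strata <- if (opts$genotype_mode) {
    calls <- merge_for_genotype_eval(calls, opts)
    truth <- merge_for_genotype_eval(truth, opts)
    list(het = "het", hom = c("hom_alt", "missing"))
  } else {
    list(presence = c("het", "hom_alt", "missing"))
  }
  rows <- list()
  ann_calls <- list(); ann_truth <- list()
  for (sname in names(strata)) {
    gts <- strata[[sname]]
    for (ty in c("DEL", "INS", "INV")) {
      A <- calls[calls$svtype == ty & calls$genotype %in% gts, ]
      B <- truth[truth$svtype == ty & truth$genotype %in% gts, ]
      if (ty == "INS") {
        pa <- match_insertions(A, B, opts, cache)
        pb <- match_insertions(B, A, opts, cache)
        cov_a <- pa >= opts$min_coverage
        cov_b <- pb >= opts$min_coverage
      } else {
        pa <- match_overlap(A, B, opts)
        pb <- match_overlap(B, A, opts)
        cov_a <- pa > opts$min_coverage
        cov_b <- pb > opts$min_coverage
      }
      a_cnt <- A$size >= opts$min_size
      b_cnt <- B$size >= opts$min_size
      rows[[length(rows) + 1L]] <- data.table::data.table(
        stratum = sname, svtype = ty,
        TP_call = sum(cov_a & a_cnt), FP = sum(!cov_a & a_cnt),
        TP_truth = sum(cov_b & b_cnt), FN = sum(!cov_b & b_cnt))
      if (nrow(A)) {
        A <- data.table::copy(A); A$coverage_prop <- pa; A$covered <- cov_a
        A$stratum <- sname
        ann_calls[[length(ann_calls) + 1L]] <- A
      }
      if (nrow(B)) {
        B <- data.table::copy(B); B$coverage_prop <- pb; B$covered <- cov_b
        B$stratum <- sname
        ann_truth[[length(ann_truth) + 1L]] <- B
      }
    }
  }
  by_type <- data.table::rbindlist(rows)
  tot <- by_type[, lapply(.SD, sum), .SDcols = c("TP_call", "FP", "TP_truth", "FN")]
  prec <- if (tot$TP_call + tot$FP > 0) tot$TP_call / (tot$TP_call + tot$FP) else 0
  rec <- if (tot$TP_truth + tot$FN > 0) tot$TP_truth / (tot$TP_truth + tot$FN) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(TP_call = tot$TP_call, FP = tot$FP, TP_truth = tot$TP_truth,
                 FN = tot$FN, precision = prec, recall = rec, f1 = f1,
                 by_type = by_type,
                 calls = data.table::rbindlist(ann_calls, fill = TRUE),
                 truth = data.table::rbindlist(ann_truth, fill = TRUE)),
            class = "sv_eval")
}

#' @export
print.sv_eval <- function(x, ...) {
  cat(sprintf("sv_eval: TPcall %d FP %d | TPtruth %d FN %d | P %.4f R %.4f F1 %.4f\n",
              x$TP_call, x$FP, x$TP_truth, x$FN, x$precision, x$recall, x$f1))
  print(x$by_type)
  invisible(x)
}

#' Precision-recall curve over quality thresholds
#'
#' Successively filters out low-quality calls: thresholds are the sorted
#' unique call qualities (plus 0); at each threshold the full evaluation is
#' recomputed with calls of at least that quality. Qualities come from QUAL,
#' or GQ when QUAL is missing or all zero.
#'
#' @param calls,truth Normalized SV records.
#' @param opts [eval_options()].
#' @return List with `curve` (`data.table`: threshold, counts, precision,
#'   recall, F1), `max_f1`, and `auc` (trapezoidal area over recall).
#' @export
pr_curve <- function(calls, truth, opts = eval_options()) {
  q <- effective_quality(calls)
  thr <- sort(unique(c(0, q)))
  cache <- new.env(parent = emptyenv())
  pts <- vector("list", length(thr))
  for (i in seq_along(thr)) {
    ev <- evaluate(calls[q >= thr[i], ], truth, opts, cache)
    pts[[i]] <- data.table::data.table(
      threshold = thr[i], TP_call = ev$TP_call, FP = ev$FP,
      TP_truth = ev$TP_truth, FN = ev$FN,
      precision = ev$precision, recall = ev$recall, f1 = ev$f1)
  }
  curve <- data.table::rbindlist(pts)
  o <- order(curve$recall)
  auc <- 0
  r <- curve$recall[o]; p <- curve$precision[o]
  if (length(r) > 1L) auc <- sum(diff(r) * (p[-1L] + p[-length(p)]) / 2)
  list(curve = curve, max_f1 = max(curve$f1), auc = auc)
}
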