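#' Read a VCF file into a record table
#'
#' Parses a plain or bgzipped VCF 4.x file. Fixed fields become columns
#' `chrom`, `pos`, `id`, `ref`, `alt`, `qual`, `filter`, `info`; per-sample
#' columns (raw FORMAT strings) follow, with the sample names recorded in
#' `attr(x, "samples")` and the FORMAT string in column `format`.
#'
#' @param path Path to a VCF file.
#' @return A `data.table` of records (sorted as in the file).
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  rec <- data.table::data.table(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", as.character(fix[, "ID"])),
    ref = toupper(as.character(fix[, "REF"])),
    alt = toupper(as.character(fix[, "ALT"])),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", as.character(fix[, "FILTER"])),
    info = ifelse(is.na(fix[, "INFO"]), ".", as.character(fix[, "INFO"]))
  )
  ## symbolic ALTs (<DEL> etc.) must keep their case-insensitive canonical form
  rec$alt <- gsub("<del>", "<DEL>", rec$alt, ignore.case = TRUE)
  samples <- character(0)
  if (ncol(v@gt) > 1L) {
    gt <- v@gt
    rec$format <- as.character(gt[, "FORMAT"])
    samples <- colnames(gt)[-1L]
    for (s in samples) rec[[s]] <- as.character(gt[, s])
  }
  ids_missing <- rec$id == "."
  if (any(ids_missing)) {
    rec$id[ids_missing] <- paste0("var_", which(ids_missing))
  }
  data.table::setattr(rec, "samples", samples)
  rec[]
}

#' Write a record table to VCF
#'
#' @param records Record table as produced by [read_vcf()] or the simulator.
#' @param path Output path.
#' @param samples Character vector of sample columns to write (default: the
#'   `samples` attribute of `records`).
#' @param extra_header Additional header lines (without trailing newline).
#' @return The path, invisibly.
#' @export
write_vcf <- function(records, path, samples = NULL, extra_header = character(0)) {
  samples <- samples %||% attr(records, "samples") %||% character(0)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=graphsv",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Length of the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth (site support)\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic read support\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  qual <- ifelse(is.na(records$qual), ".", format(records$qual, trim = TRUE, scientific = FALSE))
  body <- paste(records$chrom, records$pos, records$id, records$ref, records$alt,
                qual, records$filter %||% ".", records$info %||% ".", sep = "\t")
  if (length(samples)) {
    fmt <- records$format %||% rep("GT", nrow(records))
    body <- paste(body, fmt, sep = "\t")
    for (s in samples) body <- paste(body, records[[s]], sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

## Extract a key from a VCF INFO string; NA when absent.
info_get <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_, character(1))
}

## Parse genotype strings ("0/1", "1|0", "./.") into a 2-column allele matrix
## (NA for missing alleles).
gt_alleles <- function(gt) {
  gt <- sub(":.*$", "", gt)
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p) {
    if (length(p) >= 2L) p[2L] else NA_character_
  }, character(1))))
  cbind(a1, a2)
}
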