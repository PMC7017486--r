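#' Run the simulated SV genotyping experiment
#'
#' Full pipeline on synthetic data: simulate a genome, an SV catalog with
#' genotyped samples and a breakpoint-perturbed copy; per depth and catalog
#' (exact / perturbed breakpoints), build the graph, map reads simulated
#' from the true haplotypes, compute the pack index, genotype, and evaluate
#' against the true genotypes (presence and genotype level, overall and per
#' SV type, with the maximum F1 over quality thresholds).
#'
#' @param config A [sim_config()].
#' @param seed Master seed; all sub-seeds derive from it.
#' @param depths Depth grid (default: `config$depths`).
#' @param catalogs Subset of `c("exact", "perturbed")`.
#' @param samples Sample columns to run (default: first sample).
#' @param truth_set Optional pre-simulated output of [simulate_truth_set()].
#' @param params [map_params()] for mapping.
#' @param cparams [caller_params()] for genotyping.
#' @return `data.table` with columns sample, depth, catalog, level, svtype,
#'   TP/FP/FN counts, precision, recall, f1, max_f1.
#' @export
run_simulation_experiment <- function(config = sim_config(), seed = 1L,
                                      depths = NULL,
                                      catalogs = c("exact", "perturbed"),
                                      samples = NULL, truth_set = NULL,
                                      params = map_params(),
                                      cparams = caller_params()) {
  depths <- depths %||% config$depths
  ts <- truth_set %||% simulate_truth_set(config, seed)
  samples <- samples %||% attr(ts$truth, "samples")[1L]
  graphs <- list()
  idxs <- list()
  snarls <- list()
  recs <- list(exact = ts$truth, perturbed = ts$perturbed)
  for (cat in catalogs) {
    graphs[[cat]] <- build_graph(ts$genome, recs[[cat]])
    idxs[[cat]] <- graph_index(graphs[[cat]], k = params$k)
    snarls[[cat]] <- top_level_reference_snarls(graphs[[cat]],
                                                find_snarls(graphs[[cat]]))
  }
  rows <- list()
  for (smp in samples) {
    hp <- apply_genotypes(ts$genome, ts$truth, smp)
    truth_n <- normalize(ts$truth, ts$genome, sample = smp)
    for (d in depths) {
      rd_seed <- (seed * 1009L + round(d) * 31L +
                  match(smp, samples)) %% .Machine$integer.max
      rd <- simulate_reads(hp$haplotypes, d, config, seed = rd_seed)
      reads <- list(name = c(paste0(rd$r1$name, "/1"), paste0(rd$r2$name, "/2")),
                    seq = c(rd$r1$seq, rd$r2$seq))
      for (cat in catalogs) {
        g <- graphs[[cat]]
        aln <- map_reads(g, idxs[[cat]], reads, params)
        pack <- compute_pack(g, aln)
        called <- genotype_graph(g, pack, recs[[cat]], cparams,
                                 sample_name = smp, snarls = snarls[[cat]])
        calls_n <- normalize(called, ts$genome, sample = smp)
        for (level in c("presence", "genotype")) {
          opts <- eval_options(genotype_mode = level == "genotype")
          ev <- evaluate(calls_n, truth_n, opts)
          pr_all <- pr_curve(calls_n, truth_n, opts)
          add_row <- function(ty, cnts, maxf1) {
            p <- if (cnts$TP_call + cnts$FP > 0)
              cnts$TP_call / (cnts$TP_call + cnts$FP) else 0
            r <- if (cnts$TP_truth + cnts$FN > 0)
              cnts$TP_truth / (cnts$TP_truth + cnts$FN) else 0
            f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
            rows[[length(rows) + 1L]] <<- data.table::data.table(
              sample = smp, depth = d, catalog = cat, level = level,
              svtype = ty, TP_call = cnts$TP_call, FP = cnts$FP,
              TP_truth = cnts$TP_truth, FN = cnts$FN,
              precision = p, recall = r, f1 = f1, max_f1 = maxf1)
          }
          add_row("ALL", list(TP_call = ev$TP_call, FP = ev$FP,
                              TP_truth = ev$TP_truth, FN = ev$FN),
                  pr_all$max_f1)
          for (ty in c("DEL", "INS", "INV")) {
            cnts <- ev$by_type[ev$by_type$svtype == ty,
                               lapply(.SD, sum),
                               .SDcols = c("TP_call", "FP", "TP_truth", "FN")]
            pr_ty <- pr_curve(calls_n[calls_n$svtype == ty, ],
                              truth_n[truth_n$svtype == ty, ], opts)
            add_row(ty, as.list(cnts), pr_ty$max_f1)
          }
        }
      }
    }
  }
  data.table::rbindlist(rows)
}
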