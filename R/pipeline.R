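## End-to-end orchestration: simulate (optional) -> per-mark consensus ->
## summit windows -> counting -> NB exact testing -> DBR calling ->
## enhancer-state classification -> promoter annotation -> bivalency
## overlap test -> truth evaluation, with every stage persisted and a
## machine-readable report.

.default_params <- function() {
  list(min_support = 2, consensus_extent = "support",
       half_width = 500, half_width_by_mark = list(H3K4me3 = 150),
       alpha = 0.05, max_gap = 1000,
       promoter_upstream = 5000, promoter_downstream = 100,
       trim_m = 0.3, trim_a = 0.05, prior_df = 10, pseudo = 0.125)
}

.log_to <- function(logfile) {
  function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
}

#' Run the full differential enhancer-state pipeline
#'
#' `config` is a YAML file path or an equivalent list with either a
#' `simulate` block (arguments for [sim_config()]; `TRUE`/empty for the
#' defaults) or explicit inputs: `samples` (data.frame/TSV with columns
#' `mark`, `condition`, `replicate`, `peak_path`, `fragment_path`) and
#' `genes` (path). A `params` block overrides the analysis defaults,
#' which are the conventional ones: consensus 2 of 3, summit half-width
#' 500 bp (150 bp for H3K4me3), FDR threshold 0.05, cross-mark gap
#' 1000 bp, promoter window 5000 bp upstream / 100 bp downstream.
#'
#' All stages are deterministic after simulation; rerunning an identical
#' config reproduces the report. Artifacts (consensus BED, DBR TSV/BED,
#' enhancer-call TSV, annotation TSV, `report.json`, `pipeline.log`) are
#' written under `out_dir`.
#'
#' @param config YAML path or list.
#' @param out_dir Output directory.
#' @return Invisibly, the report list (also serialized to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(.default_params(), config$params %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "pipeline.log")
  cat("", file = logfile)
  log <- .log_to(logfile)
  report <- list(parameters = params[c("min_support", "half_width",
                                       "half_width_by_mark", "alpha",
                                       "max_gap", "promoter_upstream",
                                       "promoter_downstream")],
                 stages = list())

  ## -- inputs ---------------------------------------------------------
  truth_path <- NULL
  if (!is.null(config$simulate)) {
    simargs <- if (isTRUE(config$simulate)) list() else config$simulate
    ## YAML represents named vectors (genome, n_diff_per_mark) as maps
    simargs <- lapply(simargs, function(x) if (is.list(x)) unlist(x) else x)
    cfg <- do.call(sim_config, simargs)
    log("simulating planted experiment (seed ", cfg$seed, ")")
    sim <- simulate_experiment(cfg, file.path(out_dir, "sim"))
    samples <- sim$samples
    genes_path <- sim$genes_path
    truth_path <- sim$truth_path
    report$simulation_seed <- cfg$seed
  } else {
    samples <- config$samples
    if (is.character(samples)) {
      samples <- utils::read.table(samples, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    }
    genes_path <- config$genes
  }
  need <- c("mark", "condition", "replicate", "peak_path", "fragment_path")
  if (!all(need %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  missing_files <- c(samples$peak_path, samples$fragment_path, genes_path)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files) > 0L) {
    stop("missing input file(s): ", paste(missing_files, collapse = ", "))
  }

  marks <- unique(samples$mark)
  conds <- unique(samples$condition)
  if (length(conds) != 2L) stop("exactly two conditions required, found: ",
                                paste(conds, collapse = ", "))
  ref_cond <- if ("WT" %in% conds) "WT" else conds[1L]
  ko_cond <- setdiff(conds, ref_cond)

  ## -- per-mark consensus, windows, counting, testing -----------------
  consensus <- list()
  dbr <- list()
  dbr_sets <- list()
  for (mark in marks) {
    hw <- params$half_width_by_mark[[mark]] %||% params$half_width
    log(mark, ": consensus (min_support ", params$min_support,
        ") and ", 2 * hw, " bp summit windows")
    peaks <- list()
    for (cond in conds) {
      sel <- samples[samples$mark == mark & samples$condition == cond, ]
      reps <- lapply(sel$peak_path, read_regions)
      names(reps) <- basename(sel$peak_path)
      .check_chrom_dialect(reps)
      consensus[[mark]][[cond]] <- consensus_peaks(
        reps, min_support = params$min_support,
        extent = params$consensus_extent)
      write_regions(consensus[[mark]][[cond]],
                    file.path(out_dir, sprintf("consensus_%s_%s.bed",
                                               mark, cond)))
    }
    testing <- merge_intervals(
      suppressWarnings(c(consensus[[mark]][[ref_cond]],
                         consensus[[mark]][[ko_cond]])), max_gap = 0)
    windows <- summit_windows(testing, half_width = hw)
    sel <- samples[samples$mark == mark, ]
    frags <- lapply(sel$fragment_path, read_regions, dialect = "bed3")
    ids <- sprintf("%s_%s_rep%d", sel$mark, sel$condition, sel$replicate)
    names(frags) <- ids
    groups <- setNames(sel$condition, ids)
    cm <- count_fragments(windows, frags, groups)
    res <- test_differential_binding(cm, alpha = params$alpha,
                                     trim_m = params$trim_m,
                                     trim_a = params$trim_a,
                                     prior_df = params$prior_df,
                                     reference = ref_cond,
                                     pseudo = params$pseudo)
    dbr[[mark]] <- res
    sets <- call_dbrs(res, alpha = params$alpha)
    dbr_sets[[mark]] <- sets
    mc <- S4Vectors::mcols(res)
    tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(res)),
                      start = BiocGenerics::start(res) - 1L,
                      end = BiocGenerics::end(res),
                      log2fc = mc$log2fc, pvalue = mc$pvalue,
                      qvalue = mc$qvalue, call = mc$call)
    utils::write.table(tab, file.path(out_dir, sprintf("dbr_%s.tsv", mark)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions(sets$gained,
                  file.path(out_dir, sprintf("dbr_%s_gained.bed", mark)))
    write_regions(sets$lost,
                  file.path(out_dir, sprintf("dbr_%s_lost.bed", mark)))
    report$stages[[mark]] <- list(
      consensus = setNames(lapply(conds, function(cn)
        length(consensus[[mark]][[cn]])), conds),
      tested_windows = length(windows),
      gained = sum(mc$call == "gained"), lost = sum(mc$call == "lost"),
      ns = sum(mc$call == "ns"))
    log(mark, ": ", length(windows), " windows tested, ",
        sum(mc$call == "gained"), " gained / ", sum(mc$call == "lost"),
        " lost at FDR < ", params$alpha)
  }

  ## -- enhancer-state classification ----------------------------------
  calls <- NULL
  if (all(c("H3K4me1", "H3K27ac") %in% marks)) {
    log("classifying differential enhancer states (max_gap ",
        params$max_gap, " bp)")
    calls <- classify_differential_enhancers(
      dbr_sets$H3K4me1$gained, dbr_sets$H3K4me1$lost,
      dbr_sets$H3K27ac$gained, dbr_sets$H3K27ac$lost,
      consensus$H3K4me1[[ko_cond]], consensus$H3K27ac[[ko_cond]],
      max_gap = params$max_gap)
    mc <- S4Vectors::mcols(calls)
    tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(calls)),
                      start = BiocGenerics::start(calls) - 1L,
                      end = BiocGenerics::end(calls),
                      state = mc$state, evidence_mark = mc$evidence_mark,
                      evidence_direction = mc$evidence_direction)
    utils::write.table(tab, file.path(out_dir, "enhancer_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$enhancer_states <- as.list(table(mc$state))
  }

  ## -- promoter annotation and bivalency overlap ----------------------
  if (all(c("H3K4me3", "H3K27me3") %in% marks) && !is.null(genes_path)) {
    log("annotating H3K4me3/H3K27me3 DBRs and testing gene-set overlap")
    genes <- read_gene_models(genes_path)
    ann_gain <- annotate_regions(dbr_sets$H3K4me3$gained, genes,
                                 upstream = params$promoter_upstream,
                                 downstream = params$promoter_downstream)
    ann_loss <- annotate_regions(dbr_sets$H3K27me3$lost, genes,
                                 upstream = params$promoter_upstream,
                                 downstream = params$promoter_downstream)
    utils::write.table(ann_gain, file.path(out_dir, "genes_H3K4me3_gained.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ann_loss, file.path(out_dir, "genes_H3K27me3_lost.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    set_a <- gene_sets_from_dbrs(ann_gain)
    set_b <- gene_sets_from_dbrs(ann_loss)
    ## universe: genes reachable from any tested window of either mark
    uni <- union(
      gene_sets_from_dbrs(annotate_regions(
        dbr$H3K4me3, genes, params$promoter_upstream,
        params$promoter_downstream)),
      gene_sets_from_dbrs(annotate_regions(
        dbr$H3K27me3, genes, params$promoter_upstream,
        params$promoter_downstream)))
    report$bivalency <- list(n_genes_H3K4me3_gained = length(set_a),
                             n_genes_H3K27me3_lost = length(set_b),
                             universe = length(uni))
    if (length(set_a) > 0L && length(set_b) > 0L && length(uni) >= 4L) {
      ov <- overlap_chi_squared(set_a, set_b, uni)
      report$bivalency$overlap <- ov$overlap
      report$bivalency$chi_squared <- ov$statistic
      report$bivalency$pvalue <- ov$pvalue
      log("bivalency overlap: ", ov$overlap, " genes, chi-squared ",
          signif(ov$statistic, 4), ", p ", signif(ov$pvalue, 3))
    }
  }

  ## -- truth evaluation -----------------------------------------------
  if (!is.null(truth_path) && !is.null(calls)) {
    metrics <- evaluate_against_truth(calls, truth_path, dbr_results = dbr)
    report$truth_metrics <- list(
      enhancer = metrics$enhancer, dbr = metrics$dbr)
    ov_acc <- metrics$enhancer$sensitivity[
      metrics$enhancer$state == "overall"]
    log("enhancer-state accuracy against truth: ", round(ov_acc, 3))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  log("done")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
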