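#' Demo pipeline configuration on simulated data
#'
#' Builds a complete [run_full()] configuration that simulates a study,
#' derives a tiling gene annotation and a set of gene-set networks from it,
#' and runs every stage. Useful as a smoke test and as a template for real
#' configurations.
#'
#' @param out_dir output directory for the run's artifacts.
#' @param seed master seed.
#' @param n_snps,n_target simulation scale (kept small by default so the
#'   demo runs in seconds).
#' @return a configuration list accepted by [run_full()].
#' @export
demo_config <- function(out_dir = tempfile("prscan_run_"), seed = 1L,
                        n_snps = 2000L, n_target = 1000L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_snps = as.integer(n_snps), n_blocks = 40L,
                    n_target = as.integer(n_target), n_causal = 80L,
                    shared_fraction = 0.5, h2_base = 0.4,
                    h2_liability = 0.4),
    genes = list(p_cut = 1e-4, window = 100000, annot = "auto"),
    enrich = list(networks = "auto", n_networks = 5L, network_size = 30L),
    combine = list(beta_rule = "mean"),
    prs = list(thresholds = default_thresholds(), clump_kb = 250,
               clump_r2 = 0.1, clump_p = 1.0),
    fdr = list(method = "bootstrap-qvalue", n_boot = 100L,
               family = "pooled")
  )
}

#' Validate a pipeline configuration
#'
#' Checks presence and types of the fields [run_full()] relies on and
#' reports every violation with a JSON-pointer-style path.
#'
#' @param config configuration list (or path to a YAML file).
#' @return the (normalized) configuration, invisibly on success.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  need <- function(path, test, why) {
    parts <- strsplit(sub("^/", "", path), "/")[[1]]
    val <- config
    for (p in parts) {
      val <- if (is.list(val)) val[[p]] else NULL
    }
    if (!test(val)) problems <<- c(problems, sprintf("%s: %s", path, why))
  }
  is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  need("/seed", is_num1, "must be a single integer seed")
  need("/out_dir", function(x) is.character(x) && length(x) == 1L,
       "must be a single output directory path")
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    problems <- c(problems,
                  "/simulate or /inputs: exactly one input source required")
  }
  if (has_inputs) {
    need("/inputs/hdl", function(x) is.character(x) && file.exists(x),
         "must point to an existing summary-statistics TSV")
    need("/inputs/ldl", function(x) is.character(x) && file.exists(x),
         "must point to an existing summary-statistics TSV")
  }
  if (!is.null(config$prs)) {
    need("/prs/thresholds", function(x) is.null(x) ||
           (is.numeric(x) && all(x > 0 & x <= 1)),
         "must be p-value thresholds in (0, 1]")
  }
  if (!is.null(config$fdr)) {
    need("/fdr/family", function(x) is.null(x) ||
           x %in% c("pooled", "per_trait"),
         "must be 'pooled' or 'per_trait'")
    need("/fdr/method", function(x) is.null(x) ||
           x %in% c("bootstrap-qvalue", "BY"),
         "must be 'bootstrap-qvalue' or 'BY'")
  }
  if (length(problems)) {
    prscan_abort(c("configuration is invalid:", problems),
                 "prscan_config_error")
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or load inputs), candidate-gene
#' selection, network enrichment, combined-trait construction, one PRS scan
#' per base set, FDR correction, report — writing TSV/JSON artifacts and a
#' run manifest to `out_dir`. Any stage failure aborts the run with the
#' manifest written up to the failed stage.
#'
#' @param config configuration list (see [demo_config()] for the shape) or
#'   path to a YAML file with the same structure.
#' @return list with `candidates` (a `candidate_gene_set` or `NULL`),
#'   `enrichment` (data.frame or `NULL`), `scans` (named list of
#'   `prs_scan`), `scan_table` (all scans stacked, with `q` and `stars`),
#'   `fdr` (named list of `fdr_result` per family), `manifest`.
#' @export
run_full <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = config,
    software = list(package = "prscan",
                    version = as.character(packageVersion("prscan"))),
    seeds = list(master = config$seed),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  note_stage <- function(name, counts) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      c(list(stage = name), as.list(counts))
  }
  flush_manifest <- function() {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  log_stage <- function(name, ...) {
    message(sprintf("[prscan] %-10s %s", name, sprintf(...)))
  }
  on_failure <- function(e) {
    note_stage("failed", list(error = conditionMessage(e)))
    flush_manifest()
    stop(e)
  }

  tryCatch({
    ## ---- stage: simulate or load -------------------------------------
    if (!is.null(config$simulate)) {
      sim_args <- modifyList(config$simulate, list(seed = config$seed))
      cfg <- do.call(sim_config, sim_args)
      study <- simulate_study(cfg)
      hdl <- study$hdl
      ldl <- study$ldl
      target <- study$target
      write_sim_truth(study$truth,
                      file.path(config$out_dir, "sim_truth.json"))
      note_stage("simulate",
                 list(n_snps = cfg$n_snps, n_target = cfg$n_target,
                      n_cases = sum(target$phenotype),
                      n_causal = cfg$n_causal))
      log_stage("simulate", "%d SNPs x %d samples", cfg$n_snps,
                cfg$n_target)
      input_checksums <- NULL
    } else {
      paths <- config$inputs
      hdl <- read_summary_stats(paths$hdl, dialect = paths$dialect,
                                trait_name = "HDL")
      ldl <- read_summary_stats(paths$ldl, dialect = paths$dialect,
                                trait_name = "LDL")
      target <- if (!is.null(paths$vcf)) {
        read_target_cohort(paths$vcf, paths$phenotype)
      } else {
        read_dosage_cohort(paths$dosages, paths$snp_index,
                           paths$phenotype)
      }
      input_checksums <- as.list(tools::md5sum(unlist(Filter(
        is.character, paths))))
      note_stage("load", list(n_hdl = nrow(hdl), n_ldl = nrow(ldl),
                              n_samples = length(target$sample_ids)))
      log_stage("load", "%d + %d SNPs, %d samples", nrow(hdl), nrow(ldl),
                length(target$sample_ids))
    }
    manifest$input_checksums <- input_checksums

    ## ---- stage: candidate genes --------------------------------------
    candidates <- NULL
    annot <- NULL
    if (!is.null(config$genes)) {
      gcfg <- config$genes
      annot <- if (identical(gcfg$annot, "auto")) {
        tiling_annotation(hdl)
      } else if (is.character(gcfg$annot)) {
        read_gene_annotation(gcfg$annot)
      } else {
        gcfg$annot
      }
      per_study <- lapply(list(hdl, ldl), function(ss) {
        map_snps_to_genes(select_snps(ss, gcfg$p_cut %||% 1e-4), annot,
                          window = gcfg$window %||% 100000L)
      })
      candidates <- merge_candidate_sets(per_study)
      write_results(candidates,
                    file.path(config$out_dir, "candidates.tsv"), "tsv")
      write_results(candidates,
                    file.path(config$out_dir, "candidates.json"), "json")
      note_stage("genes", list(n_genes = length(candidates$genes),
                               n_support = nrow(candidates$provenance)))
      log_stage("genes", "%d candidate genes", length(candidates$genes))
    }

    ## ---- stage: network enrichment -----------------------------------
    enrichment <- NULL
    if (!is.null(config$enrich) && !is.null(candidates)) {
      ecfg <- config$enrich
      universe <- if (!is.null(annot)) annot$genes$gene_id else
        readLines(ecfg$universe)
      networks <- if (identical(ecfg$networks, "auto")) {
        demo_networks(universe, n_networks = ecfg$n_networks %||% 5L,
                      size = ecfg$network_size %||% 30L,
                      candidates = candidates$genes,
                      seed = derive_seed(config$seed, 11L))
      } else if (is.character(ecfg$networks)) {
        read_networks_gmt(ecfg$networks)
      } else {
        ecfg$networks
      }
      enrichment <- score_networks(candidates, networks, universe)
      write_results(enrichment,
                    file.path(config$out_dir, "enrichment.tsv"), "tsv")
      write_results(enrichment,
                    file.path(config$out_dir, "enrichment.json"), "json")
      note_stage("enrich", list(n_networks = length(networks),
                                top_score = max(enrichment$score)))
      log_stage("enrich", "%d networks, top score %.2f",
                length(networks), max(enrichment$score))
    }

    ## ---- stage: combined traits --------------------------------------
    base_sets <- list(HDL = hdl, LDL = ldl)
    if (!is.null(config$combine)) {
      combined <- suppressMessages(
        combine_traits(hdl, ldl,
                       beta_rule = config$combine$beta_rule %||% "mean"))
      base_sets <- c(base_sets, combined)
      note_stage("combine", as.list(attr(combined, "counts")))
      log_stage("combine", "%d combined base sets (%d matched SNPs)",
                length(combined), attr(combined, "counts")[["matched"]])
    }

    ## ---- stage: PRS scans --------------------------------------------
    pcfg <- config$prs %||% list()
    ld <- ld_reference(target,
                       window_bp = as.integer((pcfg$clump_kb %||% 250) *
                                                1000))
    scans <- lapply(base_sets, function(bs) {
      scan_thresholds(bs, target,
                      thresholds = pcfg$thresholds %||%
                        default_thresholds(),
                      clump_kb = pcfg$clump_kb %||% 250,
                      clump_r2 = pcfg$clump_r2 %||% 0.1,
                      clump_p = pcfg$clump_p %||% 1.0,
                      ld = ld)
    })
    scan_table <- do.call(rbind, lapply(scans, `[[`, "table"))
    rownames(scan_table) <- NULL
    for (nm in names(scans)) {
      note_stage(paste0("prs:", nm),
                 c(as.list(scans[[nm]]$counts),
                   list(n_index = length(scans[[nm]]$index_snps),
                        best_threshold = scans[[nm]]$best_threshold)))
    }
    log_stage("prs", "%d base sets x %d thresholds", length(scans),
              length(pcfg$thresholds %||% default_thresholds()))

    ## ---- stage: FDR ---------------------------------------------------
    fcfg <- config$fdr %||% list()
    family <- fcfg$family %||% "pooled"
    usable <- !scan_table$skipped
    scan_table$q <- NA_real_
    fdr_results <- list()
    adjust <- function(p) {
      suppressMessages(fdr_adjust(
        p, method = fcfg$method %||% "bootstrap-qvalue",
        n_boot = fcfg$n_boot %||% 100L,
        seed = derive_seed(config$seed, 13L),
        force_pi0_estimation = isTRUE(fcfg$force_pi0_estimation)))
    }
    if (family == "pooled") {
      fdr_results$pooled <- adjust(scan_table$assoc_p[usable])
      scan_table$q[usable] <- fdr_results$pooled$q
    } else {
      for (tr in unique(scan_table$trait)) {
        rows <- usable & scan_table$trait == tr
        fdr_results[[tr]] <- adjust(scan_table$assoc_p[rows])
        scan_table$q[rows] <- fdr_results[[tr]]$q
      }
    }
    scan_table$stars <- ""
    scan_table$stars[usable] <- star_significance(scan_table$q[usable])
    write_results(scan_table, file.path(config$out_dir, "scan.tsv"), "tsv")
    write_results(scan_table, file.path(config$out_dir, "scan.json"),
                  "json")
    note_stage("fdr", list(family = family, n_tests = sum(usable),
                           n_significant = sum(scan_table$q < 0.05,
                                               na.rm = TRUE)))
    log_stage("fdr", "%d tests, %d with q < 0.05", sum(usable),
              sum(scan_table$q < 0.05, na.rm = TRUE))

    ## ---- stage: report ------------------------------------------------
    results <- list(candidates = candidates, enrichment = enrichment,
                    scans = scans, scan_table = scan_table,
                    fdr = fdr_results)
    report <- make_report(results, dir = config$out_dir)
    results$report <- report
    note_stage("report", list(n_panels = length(unique(
      scan_table$trait))))
    flush_manifest()
    results$manifest <- manifest
    results
  }, error = on_failure)
}

#' Tiling gene annotation over a simulated region
#'
#' Synthetic stand-in annotation for simulated studies: genes of fixed
#' width tiled across the positions covered by the summary statistics.
#'
#' @param stats a [summary_stats] giving the covered region.
#' @param gene_bp gene width in bp.
#' @param gap_bp gap between consecutive genes.
#' @return a [gene_annotation] with genes named `SIMG0001`, ...
#' @export
tiling_annotation <- function(stats, gene_bp = 50000L, gap_bp = 50000L) {
  out <- lapply(split(stats$pos, stats$chrom), range)
  genes <- do.call(rbind, lapply(names(out), function(chr) {
    starts <- seq(max(1L, out[[chr]][1] - gene_bp), out[[chr]][2],
                  by = gene_bp + gap_bp)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(starts + gene_bp - 1L))
  }))
  genes$gene_id <- sprintf("SIMG%04d", seq_len(nrow(genes)))
  gene_annotation(genes[c("gene_id", "chrom", "start", "end")])
}

#' Deterministic synthetic gene-set networks for demo runs
#'
#' Draws `n_networks` node sets from the universe, biased to include some
#' candidate genes so enrichment scores vary; purely a demonstration
#' device, labelled synthetic by its network ids.
#'
#' @param universe character vector of gene ids.
#' @param n_networks,size number and size of the sets.
#' @param candidates gene ids to over-sample into the first network.
#' @param seed integer seed.
#' @return list of [interaction_network] objects named `SYNNET1`, ...
#' @export
demo_networks <- function(universe, n_networks = 5L, size = 30L,
                          candidates = character(0), seed = 1L) {
  size <- min(size, length(universe))
  is_cand <- universe %in% candidates
  with_seed(seed, {
    lapply(seq_len(n_networks), function(i) {
      # earlier networks over-sample candidates, later ones are near-uniform
      weight <- ifelse(is_cand, n_networks - i + 2, 1)
      nodes <- sample(universe, size, prob = weight)
      interaction_network(sprintf("SYNNET%d", i), nodes)
    })
  })
}

#' Bar-plot report of a finished run
#'
#' One panel per base set: model fit (Nagelkerke R-squared) per p-value
#' threshold, with FDR stars above the bars (`*` for q < 0.05, `**` for
#' q < 0.01). Also writes a short markdown summary of the run.
#'
#' @param results the result list of [run_full()] (needs `scan_table`, and
#'   optionally `candidates`/`enrichment` for the summary).
#' @param dir output directory; `NULL` skips writing files.
#' @return list with `plot` (a ggplot object) and `summary_md` (character
#'   vector of markdown lines), invisibly.
#' @export
make_report <- function(results, dir = NULL) {
  tab <- results$scan_table
  tab <- tab[!tab$skipped, , drop = FALSE]
  tab$threshold_f <- factor(tab$threshold,
                            levels = sort(unique(tab$threshold)))
  plot <- ggplot2::ggplot(tab, ggplot2::aes(x = threshold_f,
                                            y = r2_nagelkerke)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = stars), vjust = -0.2,
                       size = 5) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = expression(p[T]), y = "Nagelkerke R²",
                  title = "Shared-etiology scan across p-value thresholds",
                  subtitle = "* q < 0.05, ** q < 0.01 (FDR-corrected)") +
    ggplot2::theme_minimal()
  md <- c("# Shared-etiology scan report", "",
          sprintf("- base sets scanned: %d",
                  length(unique(tab$trait))),
          sprintf("- thresholds per set: %d",
                  length(unique(tab$threshold))),
          sprintf("- FDR-significant results (q < 0.05): %d",
                  sum(tab$q < 0.05, na.rm = TRUE)))
  if (!is.null(results$candidates)) {
    md <- c(md, sprintf("- candidate genes: %d",
                        length(results$candidates$genes)))
  }
  if (!is.null(results$enrichment)) {
    md <- c(md, sprintf("- top network enrichment score: %.2f (%s)",
                        results$enrichment$score[1],
                        results$enrichment$network_id[1]))
  }
  best <- tab[!is.na(tab$assoc_p), , drop = FALSE]
  if (nrow(best)) {
    by_trait <- split(best, best$trait)
    md <- c(md, "", "## Most predictive threshold per base set", "")
    for (tr in names(by_trait)) {
      b <- by_trait[[tr]]
      i <- which.min(b$assoc_p)
      md <- c(md, sprintf("- %s: p_T = %g (p = %.3g%s)", tr,
                          b$threshold[i], b$assoc_p[i],
                          ifelse(nzchar(b$stars[i]),
                                 paste0(", ", b$stars[i]), "")))
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(file.path(dir, "scan.png"), plot, width = 9,
                    height = 6, dpi = 120)
    writeLines(md, file.path(dir, "report.md"))
  }
  invisible(list(plot = plot, summary_md = md))
}
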