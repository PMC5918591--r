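## Pipeline orchestration: one structured config, seeded stages, logging and
## report tables. Stages persist their state into the run directory so a
## later stage can resume from an earlier run.

PIPELINE_STAGES <- c("simulate", "qc", "kinship", "flk", "hapflk",
                     "trajtest", "bayescpi", "posthoc", "report")

default_config <- function() {
  list(
    seed = 1L,
    sim = list(n_founders = 200L, n_snp = 2000L, n_chr = 5L,
               spacing = 60000L, n_ancestral_haplotypes = 10L,
               n_qtl = 100L, h2 = c(0.4, 0.4), rg = 0.54,
               large_qtl_var = 0.1, generations = 5L,
               offspring_per_line = 280L, n_genotyped_sires = 20L,
               n_genotyped_sires_g0 = 51L, g6_males = 253L,
               g6_females = 305L),
    qc = list(maf_min = 0.05, snp_callrate_min = 0.95,
              ind_callrate_min = 0.95),
    hapflk = list(K = 12L, n_em_runs = 3L, max_iter = 50L),
    fdr_level = 0.05,
    merge_distance = 1e6,
    bf_threshold = 20,
    flank = 1e6,
    mcmc = list(n_iter = 40000L, burn_in = 8000L, thin = 40L),
    traj = list(n_sims = 1e5, n_top_snps = 5L),
    ld = list(max_distance = 5e5, maf_min = 0.1)
  )
}

#' Build and validate a pipeline configuration
#'
#' @param config named list of overrides, or path to a JSON file; unknown
#'   keys are a schema error before anything runs.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  base <- default_config()
  merge_cfg <- function(base, upd, path = "") {
    bad <- setdiff(names(upd), names(base))
    if (length(bad)) stop("unknown config key(s): ",
                          paste0(path, bad, collapse = ", "))
    for (k in names(upd)) {
      if (is.list(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- merge_cfg(base[[k]], upd[[k]], paste0(path, k, "."))
      } else base[[k]] <- upd[[k]]
    }
    base
  }
  cfg <- merge_cfg(base, config)
  stopifnot(cfg$fdr_level > 0, cfg$fdr_level < 1, cfg$bf_threshold > 0,
            cfg$hapflk$K >= 1, cfg$mcmc$burn_in < cfg$mcmc$n_iter)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(cfg, stage) {
  (as.integer(cfg$seed) * 113L + match(stage, PIPELINE_STAGES) * 7919L) %%
    2147483647L
}

log_line <- function(run_dir, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = file.path(run_dir, "pipeline.log"), append = TRUE)
}

load_state <- function(run_dir, needed, stage) {
  f <- file.path(run_dir, "state.rds")
  state <- if (file.exists(f)) readRDS(f) else list()
  missing <- setdiff(needed, names(state))
  if (length(missing)) {
    stop("stage '", stage, "' needs artifacts from earlier stages (",
         paste(missing, collapse = ", "),
         "): run the producing stage first")
  }
  state
}

save_state <- function(run_dir, state) {
  saveRDS(state, file.path(run_dir, "state.rds"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order. Each stage derives its
#' own seed from the global config seed, logs its parameters, and writes its
#' outputs (TSV tables, Newick trees) under `run_dir`. Stage state is also
#' persisted so later stages can resume from an earlier call.
#'
#' @param config a [pipeline_config()] (or override list / JSON path)
#' @param stages subset of
#'   `c("simulate","qc","kinship","flk","hapflk","trajtest","bayescpi",
#'   "posthoc","report")`
#' @param run_dir output directory
#' @return `run_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = PIPELINE_STAGES,
                         run_dir = tempfile("divscan-run-")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in stages) {
    log_line(run_dir, "stage ", st, " start (seed ", stage_seed(config, st),
             ")")
    do.call(paste0("stage_", st), list(cfg = config, run_dir = run_dir))
    log_line(run_dir, "stage ", st, " done")
  }
  invisible(run_dir)
}

stage_simulate <- function(cfg, run_dir) {
  set.seed(stage_seed(cfg, "simulate"))
  s <- cfg$sim
  founders <- simulate_founders(n_ind = s$n_founders, n_snp = s$n_snp,
                                n_chr = s$n_chr, spacing = s$spacing,
                                n_ancestral_haplotypes =
                                  s$n_ancestral_haplotypes)
  arch <- simulate_architecture(founders, n_qtl = s$n_qtl, h2 = s$h2,
                                rg = s$rg, large_qtl_var = s$large_qtl_var)
  design <- breeding_design(generations = s$generations,
                            n_founders = s$n_founders,
                            offspring_per_line = s$offspring_per_line,
                            n_genotyped_sires_g0 = s$n_genotyped_sires_g0,
                            n_genotyped_sires = s$n_genotyped_sires,
                            g6_males = s$g6_males, g6_females = s$g6_females)
  exp <- run_breeding_experiment(founders, arch, design)
  export_study_layout(exp, file.path(run_dir, "data"))
  state <- load_state(run_dir, character(), "simulate")
  state$exp <- exp
  save_state(run_dir, state)
}

stage_qc <- function(cfg, run_dir) {
  state <- load_state(run_dir, "exp", "qc")
  q <- cfg$qc
  gens <- seq_len(state$exp$design$generations)
  state$cohorts <- lapply(gens, function(g) {
    filter_genotypes(scan_cohort(state$exp, g), q$maf_min,
                     q$snp_callrate_min, q$ind_callrate_min)
  })
  names(state$cohorts) <- paste0("G", gens)
  state$g6 <- filter_genotypes(state$exp$genotypes$G6, q$maf_min,
                               q$snp_callrate_min, q$ind_callrate_min)
  save_state(run_dir, state)
}

stage_kinship <- function(cfg, run_dir) {
  state <- load_state(run_dir, "cohorts", "kinship")
  state$freqs <- lapply(state$cohorts, allele_frequencies)
  state$kinship <- lapply(state$freqs, estimate_kinship, outgroup = "G0")
  for (g in names(state$kinship)) {
    export_kinship(state$kinship[[g]],
                   tree_path = file.path(run_dir, paste0("tree_", g, ".nwk")),
                   f_path = file.path(run_dir, paste0("kinship_", g, ".tsv")))
  }
  save_state(run_dir, state)
}

stage_flk <- function(cfg, run_dir) {
  state <- load_state(run_dir, c("freqs", "kinship"), "flk")
  state$flk <- lapply(names(state$freqs), function(g) {
    sc <- flk_scan(state$freqs[[g]], state$kinship[[g]])
    write_scan(sc, file.path(run_dir, paste0("flk_", g, ".tsv")))
    sc
  })
  names(state$flk) <- names(state$freqs)
  state$flk_regions <- lapply(state$flk, build_flk_regions,
                              q_threshold = cfg$fdr_level,
                              merge_distance = cfg$merge_distance)
  save_state(run_dir, state)
}

stage_hapflk <- function(cfg, run_dir) {
  state <- load_state(run_dir, c("cohorts", "kinship"), "hapflk")
  set.seed(stage_seed(cfg, "hapflk"))
  h <- cfg$hapflk
  scans <- list(); regions <- list()
  for (g in names(state$cohorts)) {
    model <- fit_cluster_model(state$cohorts[[g]], K = h$K,
                               n_em_runs = h$n_em_runs,
                               max_iter = h$max_iter)
    res <- hapflk_scan(model, state$kinship[[g]],
                       q_threshold = cfg$fdr_level,
                       merge_distance = cfg$merge_distance)
    write_scan(res$scan, file.path(run_dir, paste0("hapflk_", g, ".tsv")))
    scans[[g]] <- res$scan
    regions[[sub("^G", "", g)]] <- res$regions
  }
  state$hapflk <- scans
  state$hapflk_regions_pergen <- regions
  state$hapflk_regions <- merge_generation_regions(regions,
                                                   state$exp$snp_map)
  write_regions(state$hapflk_regions,
                file.path(run_dir, "hapflk_regions.tsv"))
  save_state(run_dir, state)
}

stage_trajtest <- function(cfg, run_dir) {
  state <- load_state(run_dir, c("flk", "freqs", "kinship"), "trajtest")
  set.seed(stage_seed(cfg, "trajtest"))
  g_last <- tail(names(state$flk), 1L)
  sc <- state$flk[[g_last]]
  ord <- order(sc$p_value)
  top <- head(ord[!is.na(sc$p_value[ord])], cfg$traj$n_top_snps)
  fr <- state$freqs[[g_last]]$freq
  tab <- data.frame(snp = sc$snp[top], p0 = fr[top, "G0"],
                    pf_minus = fr[top, "pHu-"], pf_plus = fr[top, "pHu+"],
                    stringsAsFactors = FALSE)
  g <- state$exp$design$generations
  ne <- vapply(c("pHu-", "pHu+"), function(ln) {
    ne_from_inbreeding(state$kinship[[g_last]]$F[ln, ln], g)
  }, numeric(1))
  tab_wf <- trajectory_test_batch(tab, g = g, model = "wright-fisher",
                                  N = round(2 * ne),
                                  n_sims = cfg$traj$n_sims)
  counts <- design_sex_counts(state$exp$design)
  tab_sex <- trajectory_test_batch(tab, g = g, model = "sex-structured",
                                   counts_minus = counts,
                                   counts_plus = counts,
                                   n_sims = cfg$traj$n_sims)
  tab_wf$model <- "wright-fisher"; tab_sex$model <- "sex-structured"
  state$trajtest <- rbind(tab_wf, tab_sex)
  write.table(state$trajtest, file.path(run_dir, "trajtest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  save_state(run_dir, state)
}

stage_bayescpi <- function(cfg, run_dir) {
  state <- load_state(run_dir, "g6", "bayescpi")
  g6 <- state$g6
  ph <- state$exp$phenotypes
  ph <- ph[match(g6$individuals$id, ph$id), ]
  m <- cfg$mcmc
  res <- list()
  for (trait in c("PM_pHu", "SART_pHu")) {
    for (with_line in c(FALSE, TRUE)) {
      cov <- ph[, c("sex", "hatch", if (with_line) "line")]
      y <- precorrect_phenotypes(ph[[trait]], cov)
      seed <- stage_seed(cfg, "bayescpi") + 11L * with_line +
        101L * (trait == "SART_pHu")
      fit <- run_bayescpi(y, g6, mcmc = mcmc_spec(m$n_iter, m$burn_in,
                                                  m$thin, seed = seed))
      nm <- paste0(trait, if (with_line) "_line" else "")
      write_scan(fit, file.path(run_dir, paste0("bayescpi_", nm, ".tsv")))
      res[[nm]] <- fit
    }
  }
  state$qtl <- res
  state$qtl_regions <- lapply(res[c("PM_pHu", "SART_pHu")],
                              build_qtl_regions,
                              bf_threshold = cfg$bf_threshold,
                              merge_distance = cfg$merge_distance,
                              flank = cfg$flank)
  save_state(run_dir, state)
}

stage_posthoc <- function(cfg, run_dir) {
  state <- load_state(run_dir, c("qtl", "hapflk_regions", "flk_regions"),
                      "posthoc")
  g0 <- state$exp$genotypes$G0
  pairs <- ld_r2(g0, cfg$ld$max_distance, cfg$ld$maf_min)
  sig_hap <- state$hapflk_regions
  flk_only <- do.call(rbind, lapply(names(state$flk), function(g) {
    as.data.frame(build_flk_regions(state$flk[[g]],
                                    q_threshold = cfg$fdr_level,
                                    merge_distance = cfg$merge_distance,
                                    exclude = sig_hap))
  }))
  flk_only <- if (!is.null(flk_only) && nrow(flk_only)) {
    genomic_regions(chr = flk_only$chr, start = flk_only$start,
                    end = flk_only$end, peak_snp = flk_only$peak_snp,
                    score = flk_only$score, n_snp = flk_only$n_snp)
  } else empty_regions()
  cats <- rbind(cbind(as.data.frame(sig_hap), category = "hapFLK"),
                cbind(as.data.frame(flk_only), category = "FLK"))
  class(cats) <- c("genomic_regions", "data.frame")
  state$ld_summary <- region_mean_r2(pairs, cats)
  qtl <- state$qtl$PM_pHu
  inside <- in_any_region(qtl$chr, qtl$bp, sig_hap) |
    in_any_region(qtl$chr, qtl$bp, flk_only)
  state$enrichment <- if (sum(inside) >= 2 && sum(!inside) >= 2) {
    enrichment_test(qtl$bf[inside], qtl$bf[!inside])
  } else list(t = NA, p_value = NA)
  state$flk_only_regions <- flk_only
  write.table(state$ld_summary, file.path(run_dir, "ld_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  save_state(run_dir, state)
}

stage_report <- function(cfg, run_dir) {
  state <- load_state(run_dir, c("hapflk_regions", "qtl"), "report")
  map <- state$exp$snp_map
  t1 <- region_report(state$hapflk_regions, map, prefix = "hapFLK")
  write.table(t1, file.path(run_dir, "table1_hapflk_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  flk_only <- state$flk_only_regions
  if (!is.null(flk_only)) {
    t2 <- region_report(flk_only, map, prefix = "FLK")
    write.table(t2, file.path(run_dir, "table2_flk_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sigs <- state$hapflk_regions
  t3 <- rbind(
    qtl_report(state$qtl$PM_pHu, state$qtl$PM_pHu_line,
               regions = state$qtl_regions$PM_pHu, signatures = sigs,
               trait = "PM_pHu", bf_threshold = cfg$bf_threshold),
    qtl_report(state$qtl$SART_pHu, state$qtl$SART_pHu_line,
               regions = state$qtl_regions$SART_pHu, signatures = sigs,
               trait = "SART_pHu", bf_threshold = cfg$bf_threshold))
  write.table(t3, file.path(run_dir, "table3_qtl.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (g in names(state$hapflk)) {
    man <- state$hapflk[[g]]
    write.table(data.frame(chr = man$chr, bp = man$bp,
                           minus_log10_p = -log10(pmax(man$p_value,
                                                       1e-300))),
                file.path(run_dir, paste0("manhattan_hapflk_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  man <- state$qtl$PM_pHu
  write.table(data.frame(chr = man$chr, bp = man$bp, bf = man$bf),
              file.path(run_dir, "manhattan_bayescpi_PM.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  save_state(run_dir, state)
}

#' Command-line entry point
#'
#' `divscan <stage|pipeline|trajtest> [--config cfg.json] [--run-dir dir]`
#' plus, for `trajtest`, `--p0 --pf --g --model --N --nm-list --nf-list
#' --nsims --seed`. Used by the `inst/cli/divscan` script.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly.
#' @export
divscan_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: divscan <", paste(c(PIPELINE_STAGES, "pipeline", "trajtest"),
                                  collapse = "|"), "> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- args[-1L]
  get_opt <- function(name, default = NULL) {
    i <- which(opts == paste0("--", name))
    if (length(i)) opts[i[1L] + 1L] else default
  }
  if (cmd == "trajtest") {
    model <- get_opt("model", "wright-fisher")
    counts <- NULL
    if (model == "sex-structured") {
      counts <- sex_counts(
        as.integer(strsplit(get_opt("nm-list"), ",")[[1L]]),
        as.integer(strsplit(get_opt("nf-list"), ",")[[1L]]))
    }
    res <- trajectory_pvalue(
      p0 = as.numeric(get_opt("p0")), pf = as.numeric(get_opt("pf")),
      g = as.integer(get_opt("g", 5)), model = model,
      N = as.numeric(get_opt("N")), counts = counts,
      n_sims = as.numeric(get_opt("nsims", 1e5)),
      seed = as.integer(get_opt("seed", 1)))
    cat(sprintf("p_value\t%g\nse\t%g\n", res$p_value, res$se))
    return(invisible(0L))
  }
  stages <- if (cmd == "pipeline") PIPELINE_STAGES else cmd
  cfg <- pipeline_config(if (!is.null(get_opt("config")))
    get_opt("config") else list())
  rd <- run_pipeline(cfg, stages,
                     run_dir = get_opt("run-dir", "divscan-run"))
  cat("run directory:", rd, "\n")
  invisible(0L)
}
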