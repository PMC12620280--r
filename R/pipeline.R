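#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the discovery
#' cascade's published gates (200 bp length, 0.5 RPKM, FDR 0.05, fold change
#' 1.5, 3 kb promoter/downstream windows, sDSS threshold 1) plus the
#' simulation settings, and validates it. Values can come from a YAML file,
#' from `...` overrides, or both (explicit overrides win over the file).
#'
#' @param yaml Optional path to a YAML file whose keys mirror the defaults.
#' @param ... Individual overrides.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  cfg <- list(
    out_dir = "lncdiscover_run",
    seed = 1L,
    simulate = TRUE,
    # paths used when simulate = FALSE (pre-existing inputs)
    assembled_gtf = NULL, reference_gtf = NULL, counts_tsv = NULL,
    groups_tsv = NULL, dnase_bed = NULL, h3k4me3_bed = NULL,
    # discovery gates
    min_length = 200L, min_mean_rpkm = 0.5, fdr = 0.05, min_abs_fc = 1.5,
    max_exon_bp = 10000L, tss_window = 1000L,
    location_mode = "gene_span", stranded = FALSE,
    group_a = "AML", group_b = "NBM",
    # chirp
    promoter_bp = 3000L, downstream_bp = 3000L, min_overlap_bp = 1L,
    consensus_merge = "union", n_shuffles = 200L,
    # drug screen
    sdss_threshold = 1.0, activity_threshold = 10
  )
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stop("config file not found: ", yaml)
    from_file <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown)) stop("unknown config key(s) in ", yaml, ": ",
                              paste(unknown, collapse = ", "))
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  if (!isTRUE(cfg$simulate)) {
    needed <- c("assembled_gtf", "reference_gtf", "counts_tsv", "groups_tsv",
                "dnase_bed", "h3k4me3_bed")
    for (key in needed) {
      if (is.null(cfg[[key]])) stop("config key '", key,
                                    "' required when simulate = FALSE")
      if (!file.exists(cfg[[key]])) stop("input path does not exist: ",
                                         cfg[[key]], " (", key, ")")
    }
  }
  structure(cfg, class = "pipeline_config")
}

.read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Run the full discovery-and-characterization pipeline
#'
#' Executes simulate (optional) -> discover -> isoform -> cohort -> chirp ->
#' drugscreen, writing each stage's tables into its own sub-directory of
#' `out_dir` plus a machine-readable `summary.json` (stable across reruns
#' with the same config) and a human-readable `report.md` (carries the
#' timestamp). Every parameter actually used, including defaults, is
#' serialized into `config_used.yaml`.
#'
#' With `simulate = TRUE` all inputs come from [simulate_study()] under the
#' config seed; otherwise the discovery stage reads the configured paths and
#' the stages requiring planted inputs (isoform, cohort, chirp, drugscreen)
#' run only if simulation data is present.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by it).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml = config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(s) {
    d <- file.path(config$out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  yaml::write_yaml(unclass(config), file.path(config$out_dir,
                                              "config_used.yaml"))
  summary <- list(seed = config$seed,
                  parameters = unclass(config)[c(
                    "min_length", "min_mean_rpkm", "fdr", "min_abs_fc",
                    "max_exon_bp", "tss_window", "location_mode",
                    "promoter_bp", "downstream_bp", "sdss_threshold")])
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- NULL
  if (isTRUE(config$simulate)) {
    run_stage("simulate", function() {
      sim <<- simulate_study(sim_config(seed = config$seed))
      write_simulation(sim, stage_dir("simulate"))
    })
    assembled <- sim$assembled; reference <- sim$reference
    counts <- sim$counts; groups <- sim$groups
    dnase <- sim$tracks$dnase; h3k4me3 <- sim$tracks$h3k4me3
  } else {
    assembled <- read_annotation(config$assembled_gtf)
    reference <- read_annotation(config$reference_gtf)
    counts <- .read_counts_tsv(config$counts_tsv)
    gdf <- utils::read.delim(config$groups_tsv, stringsAsFactors = FALSE)
    groups <- setNames(gdf$group, gdf$sample_id)
    dnase <- read_peaks(config$dnase_bed)
    h3k4me3 <- read_peaks(config$h3k4me3_bed)
  }

  # --- discover
  disc <- NULL
  run_stage("discover", function() {
    disc <<- run_cascade(assembled, reference, counts, groups, dnase,
                         h3k4me3,
                         group_a = config$group_a, group_b = config$group_b,
                         min_length = config$min_length,
                         min_mean_rpkm = config$min_mean_rpkm,
                         fdr = config$fdr, min_abs_fc = config$min_abs_fc,
                         max_exon_bp = config$max_exon_bp,
                         tss_window = config$tss_window,
                         location_mode = config$location_mode,
                         stranded = config$stranded)
    d <- stage_dir("discover")
    utils::write.table(disc$records, file.path(d, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(disc$attrition),
                         file.path(d, "attrition.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  summary$discovery <- list(n_transcripts = unname(disc$attrition[["n_transcripts"]]),
                            n_candidates = unname(disc$attrition[["n_candidates"]]),
                            candidates = disc$candidates,
                            attrition = as.list(disc$attrition),
                            direction = disc$direction)

  if (!is.null(sim)) {
    # --- isoform usage
    run_stage("isoform", function() {
      iso <- sim$isoform
      d <- stage_dir("isoform")
      for (set_name in c("start", "termination")) {
        ids <- iso$exon_info$exon_id[iso$exon_info$set == set_name]
        usage <- exon_usage(iso$exon_counts,
                            setNames(iso$exon_info$length,
                                     iso$exon_info$exon_id),
                            ids, "all_positive")
        cmp <- compare_usage(usage)
        utils::write.table(usage, file.path(d, paste0(set_name, "_usage.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        shares <- tapply(usage$usage_share, usage$exon_id, mean)[ids]
        summary$isoform[[set_name]] <<- list(
          mean_share = as.list(round(shares, 4)),
          n_dropped = attr(usage, "n_dropped"),
          p = cmp$p)
      }
    })

    # --- cohort characterization
    run_stage("cohort", function() {
      coh <- sim$cohort
      d <- stage_dir("cohort")
      bins <- bin_expressors(coh$expression)
      utils::write.table(
        data.frame(sample_id = coh$sample_id, expression = coh$expression,
                   bin = as.character(bins)),
        file.path(d, "bins.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      assoc <- group_association(coh$expression, coh$FAB)
      utils::write.table(assoc$pairwise, file.path(d, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      grp <- median_split(coh$expression)
      km <- km_logrank(coh$os_days, coh$os_event, grp,
                       transplant_time = coh$transplant_days)
      ph_data <- data.frame(time = coh$os_days, event = coh$os_event,
                            expr_high = as.integer(grp == "high"),
                            age = coh$age, NPM1 = as.integer(coh$NPM1))
      ph <- ph_multivariable(ph_data, c("expr_high", "age", "NPM1"),
                             transplant_time = coh$transplant_days)
      utils::write.table(ph, file.path(d, "ph_model.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$cohort <<- list(
        bin_counts = as.list(unclass(attr(bins, "counts"))),
        kw_p = assoc$p, logrank_p = km$p,
        hr_expr_high = ph$HR[ph$covariate == "expr_high"])
    })

    # --- chirp
    run_stage("chirp", function() {
      d <- stage_dir("chirp")
      cons <- replicate_consensus(sim$tracks$chirp_rep1,
                                  sim$tracks$chirp_rep2,
                                  min_overlap_bp = config$min_overlap_bp,
                                  merge = config$consensus_merge)
      write_peaks(cons, file.path(d, "consensus.narrowPeak"), "narrowPeak")
      ann <- annotate_peaks(cons, sim$reference,
                            promoter_bp = config$promoter_bp,
                            downstream_bp = config$downstream_bp)
      utils::write.table(ann, file.path(d, "peak_annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      enr <- state_enrichment(cons, sim$tracks$states,
                              n_shuffles = config$n_shuffles,
                              seed = config$seed)
      utils::write.table(enr, file.path(d, "state_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      genes <- peaks_to_genes(ann)
      writeLines(genes, file.path(d, "bound_genes.txt"))
      ov <- set_overlap_test(genes, sim$truth$chirp_genes,
                             universe_n = length(sim$reference$genes))
      jsonlite::write_json(ov, file.path(d, "overlap_test.json"),
                           auto_unbox = TRUE, digits = NA)
      summary$chirp <<- list(
        n_consensus = length(cons),
        category_counts = as.list(table(ann$category)),
        n_bound_genes = length(genes),
        overlap_p = ov$p)
    })

    # --- drug screen
    run_stage("drugscreen", function() {
      d <- stage_dir("drugscreen")
      scr <- sdss_screen(sim$plates, "KO", "WT",
                         threshold = config$sdss_threshold,
                         activity_threshold = config$activity_threshold)
      utils::write.table(scr, file.path(d, "sdss.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$drugscreen <<- list(
        n_drugs = nrow(scr),
        hits = scr$drug[scr$passes_filter],
        top_sdss = if (nrow(scr)) scr$sdss[1] else NA_real_,
        direction = attr(scr, "direction"))
    })
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- c(
    "# lncRNA discovery pipeline report",
    paste0("Generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("Seed: ", config$seed),
    "",
    "## Discovery",
    paste0("- transcripts assessed: ", summary$discovery$n_transcripts),
    paste0("- candidates: ", summary$discovery$n_candidates, " (",
           paste(summary$discovery$candidates, collapse = ", "), ")"),
    paste0("- ", summary$discovery$direction)
  )
  if (!is.null(summary$cohort)) {
    report <- c(report, "", "## Cohort",
                paste0("- log-rank p: ", signif(summary$cohort$logrank_p, 3)),
                paste0("- HR (high expression): ",
                       signif(summary$cohort$hr_expr_high, 3)))
  }
  if (!is.null(summary$drugscreen)) {
    report <- c(report, "", "## Drug screen",
                paste0("- hits (|sDSS| over threshold): ",
                       paste(summary$drugscreen$hits, collapse = ", ")))
  }
  writeLines(report, file.path(config$out_dir, "report.md"))
  invisible(summary)
}
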