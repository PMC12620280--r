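#' Normalize a count matrix
#'
#' `CPM` scales each sample to one million (column sums of the result are
#' exactly 1e6); `RPKM` and `length_norm_CPM` additionally divide by feature
#' length in kb; `log2CPM1` is log2(CPM + 1).
#'
#' @param counts Non-negative feature x sample matrix with dimnames.
#' @param method One of `"CPM"`, `"RPKM"`, `"log2CPM1"`, `"length_norm_CPM"`.
#' @param lengths Named vector of feature lengths in bp (required for the
#'   length-normalized methods).
#' @return Numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts,
                             method = c("CPM", "RPKM", "log2CPM1",
                                        "length_norm_CPM"),
                             lengths = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  if (method == "CPM") return(cpm)
  if (method == "log2CPM1") return(log2(cpm + 1))
  if (is.null(lengths)) stop("'lengths' required for method ", method)
  len <- lengths[rownames(counts)]
  if (anyNA(len)) {
    stop("missing length for feature(s): ",
         paste(rownames(counts)[is.na(len)], collapse = ", "))
  }
  cpm / (len / 1000)  # RPKM and length_norm_CPM share this definition
}

# vectorised two-sided Welch (unequal variance) t-test over matrix rows
.welch_rows <- function(x, ia, ib) {
  na <- length(ia); nb <- length(ib)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & ma == mb] <- 1      # identical constant values in both groups
  p[degenerate & ma != mb] <- 0
  list(statistic = tstat, df = df, p = p)
}

#' Differential expression between two groups
#'
#' A deliberate lightweight substitution for an assembler-integrated DE
#' engine: a two-sided Welch t-test on log2(CPM+1) per feature, fold change
#' on the CPM scale with a pseudocount of 1 CPM
#' (`log2FC = log2((meanCPM_a + 1) / (meanCPM_b + 1))`; positive means higher
#' in `group_a`), Benjamini-Hochberg q-values, and a call at
#' `q < fdr & |FC| > min_abs_fc`.
#'
#' @param counts Feature x sample count matrix.
#' @param groups Named character vector mapping sample to group label.
#' @param group_a,group_b Group labels to contrast (direction a minus b).
#' @param fdr FDR threshold (default 0.05).
#' @param min_abs_fc Minimum linear fold change (default 1.5).
#' @return data.frame: `feature_id`, `log2FC`, `p`, `q`, `called`.
#' @export
differential_expression <- function(counts, groups, group_a = "AML",
                                    group_b = "NBM", fdr = 0.05,
                                    min_abs_fc = 1.5) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  g <- groups[colnames(counts)]
  ia <- which(g == group_a); ib <- which(g == group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("need >= 2 samples per group (", group_a, ": ", length(ia), ", ",
         group_b, ": ", length(ib), ")")
  }
  cpm <- normalize_counts(counts, "CPM")
  lg <- log2(cpm + 1)
  wt <- .welch_rows(lg, ia, ib)
  log2fc <- log2((rowMeans(cpm[, ia, drop = FALSE]) + 1) /
                   (rowMeans(cpm[, ib, drop = FALSE]) + 1))
  q <- stats::p.adjust(wt$p, method = "BH")
  data.frame(
    feature_id = rownames(counts),
    log2FC = log2fc, p = wt$p, q = q,
    called = q < fdr & abs(log2fc) > log2(min_abs_fc),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Splicing-structure filter
#'
#' Flags transcripts that look like retained introns rather than spliced
#' products: single-exon structures and abnormally long exons.
#'
#' @param ann A `gene_annotation`.
#' @param max_exon_bp Longest acceptable exon (default 10000 bp).
#' @return data.frame: `transcript_id`, `multi_exon`, `exon_size_ok`.
#' @export
splicing_structure_filter <- function(ann, max_exon_bp = 10000L) {
  stopifnot(inherits(ann, "gene_annotation"))
  w <- BiocGenerics::width(ann$exons_by_tx)
  data.frame(
    transcript_id = names(ann$exons_by_tx),
    multi_exon = lengths(w) >= 2L,
    exon_size_ok = vapply(w, max, numeric(1)) <= max_exon_bp,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Promoter epigenomic support
#'
#' A transcript is supported by a track when the window `TSS +/- tss_window`
#' intersects at least one peak (strand-agnostic).
#'
#' @param ann A `gene_annotation`.
#' @param dnase,h3k4me3 Peak `GRanges` (e.g. from [read_peaks()]).
#' @param tss_window Half-width of the TSS window in bp (default 1000).
#' @return data.frame: `transcript_id`, `dnase_support`, `h3k4me3_support`.
#' @export
epigenomic_support <- function(ann, dnase, h3k4me3, tss_window = 1000L) {
  stopifnot(inherits(ann, "gene_annotation"), tss_window >= 0L)
  win <- suppressWarnings(GenomicRanges::resize(
    tss(ann), width = 2L * tss_window + 1L, fix = "center"))
  sup <- function(track) {
    if (length(track) == 0L) return(rep(FALSE, length(win)))
    suppressWarnings(IRanges::overlapsAny(win, track, ignore.strand = TRUE))
  }
  data.frame(
    transcript_id = names(win),
    dnase_support = sup(dnase),
    h3k4me3_support = sup(h3k4me3),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Candidate-lncRNA discovery cascade
#'
#' Computes all eight discovery flags for every assembled transcript --
#' independently, with no short-circuiting, so failure attribution is
#' complete: spliced length > 200 bp, intergenic location relative to the
#' reference annotation, mean RPKM >= 0.5 over all samples (both groups),
#' DNase and H3K4me3 support at the TSS, multi-exon structure, exon-size
#' bound, and differential-expression call between the two groups. A
#' transcript is a candidate when every flag is true.
#'
#' Transcripts with no row in the count matrix are dropped with a warning.
#'
#' @param assembled Assembled transcripts (`gene_annotation`).
#' @param reference Reference annotation (`gene_annotation`).
#' @param counts Transcript x sample count matrix.
#' @param groups Named sample-to-group vector.
#' @param dnase,h3k4me3 Peak `GRanges`.
#' @param group_a,group_b Group labels contrasted by the DE stage.
#' @param min_length Transcript length gate in bp (exclusive; default 200).
#' @param min_mean_rpkm Mean expression gate (inclusive; default 0.5).
#' @param fdr,min_abs_fc DE thresholds (defaults 0.05 and 1.5).
#' @param max_exon_bp Long-exon bound (default 10000).
#' @param tss_window TSS support half-window (default 1000).
#' @param location_mode,stranded Passed to [classify_location()].
#' @return List of class `discovery_result`: `records` (one row per
#'   transcript with all flags, `log2FC`, `p`, `q`, `passes_all`),
#'   `candidates` (ids passing all flags), `attrition` (named failure counts
#'   per criterion plus `n_transcripts` and `n_candidates`), and the DE
#'   direction convention in `direction`.
#' @export
run_cascade <- function(assembled, reference, counts, groups, dnase, h3k4me3,
                        group_a = "AML", group_b = "NBM",
                        min_length = 200L, min_mean_rpkm = 0.5,
                        fdr = 0.05, min_abs_fc = 1.5,
                        max_exon_bp = 10000L, tss_window = 1000L,
                        location_mode = "gene_span", stranded = FALSE) {
  stopifnot(inherits(reference, "gene_annotation"))
  if (is.null(assembled)) return(.empty_cascade())
  stopifnot(inherits(assembled, "gene_annotation"))
  tx_ids <- assembled$tx$transcript_id
  if (length(tx_ids) == 0L || is.null(counts)) return(.empty_cascade())
  missing <- setdiff(tx_ids, rownames(counts))
  if (length(missing)) {
    warning("no counts for ", length(missing),
            " transcript(s); excluded: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ...")
    tx_ids <- setdiff(tx_ids, missing)
  }
  if (length(tx_ids) == 0L) return(.empty_cascade())
  counts <- counts[tx_ids, , drop = FALSE]

  lens <- spliced_length(assembled)[tx_ids]
  loc <- classify_location(assembled, reference, mode = location_mode,
                           stranded = stranded)[tx_ids]
  rpkm <- normalize_counts(counts, "RPKM", lengths = lens)
  struct <- splicing_structure_filter(assembled, max_exon_bp = max_exon_bp)
  struct <- struct[match(tx_ids, struct$transcript_id), ]
  epi <- epigenomic_support(assembled, dnase, h3k4me3, tss_window = tss_window)
  epi <- epi[match(tx_ids, epi$transcript_id), ]
  de <- differential_expression(counts, groups, group_a, group_b,
                                fdr = fdr, min_abs_fc = min_abs_fc)
  de <- de[match(tx_ids, de$feature_id), ]

  records <- data.frame(
    transcript_id = tx_ids,
    length_gt_200 = unname(lens > min_length),
    intergenic = unname(loc == "intergenic"),
    mean_rpkm_ge_0.5 = unname(rowMeans(rpkm) >= min_mean_rpkm),
    dnase_support = epi$dnase_support,
    h3k4me3_support = epi$h3k4me3_support,
    multi_exon = struct$multi_exon,
    exon_size_ok = struct$exon_size_ok,
    de_significant = de$called,
    log2FC = de$log2FC, p = de$p, q = de$q,
    row.names = NULL, stringsAsFactors = FALSE
  )
  # order-invariant output
  records <- records[order(records$transcript_id), ]
  rownames(records) <- NULL
  flag_cols <- c("length_gt_200", "intergenic", "mean_rpkm_ge_0.5",
                 "dnase_support", "h3k4me3_support", "multi_exon",
                 "exon_size_ok", "de_significant")
  records$passes_all <- Reduce(`&`, records[flag_cols])
  attrition <- c(n_transcripts = nrow(records),
                 vapply(records[flag_cols],
                        function(f) sum(!f), integer(1)),
                 n_candidates = sum(records$passes_all))
  structure(
    list(records = records,
         candidates = records$transcript_id[records$passes_all],
         attrition = attrition,
         direction = sprintf("log2FC > 0 means higher in %s", group_a)),
    class = "discovery_result"
  )
}

.empty_cascade <- function() {
  flag_cols <- c("length_gt_200", "intergenic", "mean_rpkm_ge_0.5",
                 "dnase_support", "h3k4me3_support", "multi_exon",
                 "exon_size_ok", "de_significant")
  records <- data.frame(transcript_id = character(0))
  for (f in flag_cols) records[[f]] <- logical(0)
  records$log2FC <- numeric(0); records$p <- numeric(0)
  records$q <- numeric(0); records$passes_all <- logical(0)
  structure(
    list(records = records, candidates = character(0),
         attrition = c(n_transcripts = 0L,
                       setNames(rep(0L, length(flag_cols)), flag_cols),
                       n_candidates = 0L),
         direction = "log2FC > 0 means higher in group_a"),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("Discovery cascade:", x$attrition[["n_transcripts"]], "transcripts ->",
      x$attrition[["n_candidates"]], "candidate(s)\n")
  cat(x$direction, "\n")
  fails <- x$attrition[!names(x$attrition) %in%
                         c("n_transcripts", "n_candidates")]
  for (nm in names(fails)) cat(sprintf("  fail %-18s %d\n", nm, fails[[nm]]))
  invisible(x)
}
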