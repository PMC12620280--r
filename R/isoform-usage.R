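#' Exon-level isoform usage
#'
#' Quantifies alternative start-exon (or termination-exon) usage from an
#' exon-level count matrix. Per sample and exon it reports CPM (computed from
#' the full exon matrix's library sizes), length-normalized log2(CPM+1)
#' (the plotting/statistics scale), and the usage share -- the
#' length-normalized *linear* CPM of the exon divided by the set total, so
#' shares over the exon set sum to 1 per retained sample.
#'
#' With `min_expr_filter = "all_positive"` (the cohort figure's rule) samples
#' with CPM = 0 in any exon of the set are dropped; the number dropped is
#' reported in `attr(, "n_dropped")`.
#'
#' @param exon_counts Exon x sample count matrix.
#' @param exon_lengths Named exon length vector (bp).
#' @param exon_set Character vector of exon ids forming the alternative set.
#' @param min_expr_filter `"all_positive"` or `"none"`.
#' @return Long data.frame (`sample_id`, `exon_id`, `cpm`,
#'   `norm_log_expr`, `usage_share`) of class `isoform_usage`, with
#'   attributes `n_dropped` and `exon_set`.
#' @export
exon_usage <- function(exon_counts, exon_lengths, exon_set,
                       min_expr_filter = c("all_positive", "none")) {
  min_expr_filter <- match.arg(min_expr_filter)
  stopifnot(is.matrix(exon_counts))
  if (length(exon_set) == 0L) stop("exon_set must not be empty")
  if (!all(exon_set %in% rownames(exon_counts))) {
    stop("exon_set members missing from counts: ",
         paste(setdiff(exon_set, rownames(exon_counts)), collapse = ", "))
  }
  cpm <- normalize_counts(exon_counts, "CPM")[exon_set, , drop = FALSE]
  keep <- rep(TRUE, ncol(cpm))
  if (min_expr_filter == "all_positive") keep <- colSums(cpm == 0) == 0L
  n_dropped <- sum(!keep)
  cpm <- cpm[, keep, drop = FALSE]
  len_kb <- exon_lengths[exon_set] / 1000
  if (anyNA(len_kb)) stop("missing exon length(s)")
  norm_cpm <- cpm / len_kb                 # linear, per kb: share denominator
  share <- sweep(norm_cpm, 2L, colSums(norm_cpm), "/")
  share[, colSums(norm_cpm) == 0] <- NA_real_
  out <- data.frame(
    sample_id = rep(colnames(cpm), each = length(exon_set)),
    exon_id = rep(exon_set, times = ncol(cpm)),
    cpm = as.vector(cpm),
    norm_log_expr = as.vector(log2(norm_cpm + 1)),
    usage_share = as.vector(share),
    stringsAsFactors = FALSE
  )
  structure(out, n_dropped = n_dropped, exon_set = exon_set,
            class = c("isoform_usage", "data.frame"))
}

#' Compare exon usage across an alternative exon set
#'
#' Two-exon sets are compared with a paired two-sided t-test across samples
#' on the length-normalized log2(CPM+1) scale. Sets with more exons use a
#' repeated-measures (randomized-block) ANOVA with sample as the block,
#' followed by pairwise paired t-tests with Holm adjustment.
#'
#' @param usage An `isoform_usage` table from [exon_usage()].
#' @return List: `design` (`"paired_two"` or `"repeated_multi"`),
#'   `statistic`, `df`, `p`, and `pairwise` (data.frame `exon_a`, `exon_b`,
#'   `statistic`, `p`, `p_adj`; for the two-exon design it repeats the
#'   single contrast).
#' @export
compare_usage <- function(usage) {
  stopifnot(inherits(usage, "isoform_usage"))
  exons <- attr(usage, "exon_set")
  if (length(exons) < 2L) stop("need >= 2 exons in the set")
  wide <- matrix(usage$norm_log_expr,
                 nrow = length(exons),
                 dimnames = list(usage$exon_id[seq_along(exons)], NULL))
  n <- ncol(wide)
  if (n < 3L) stop("need >= 3 samples, got ", n)

  pair_t <- function(a, b) {
    d <- wide[a, ] - wide[b, ]
    if (all(d == 0)) return(list(statistic = 0, df = n - 1L, p = 1))
    tt <- stats::t.test(d)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  }

  pairs <- utils::combn(exons, 2L)
  pw <- data.frame(exon_a = pairs[1, ], exon_b = pairs[2, ],
                   statistic = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    r <- pair_t(pairs[1, i], pairs[2, i])
    pw$statistic[i] <- r$statistic; pw$p[i] <- r$p
  }
  pw$p_adj <- stats::p.adjust(pw$p, method = "holm")

  if (length(exons) == 2L) {
    return(list(design = "paired_two", statistic = pw$statistic[1],
                df = n - 1L, p = pw$p[1], pairwise = pw))
  }
  long <- data.frame(
    y = as.vector(wide),
    exon = factor(rep(exons, times = n), levels = exons),
    sample = factor(rep(seq_len(n), each = length(exons)))
  )
  if (stats::sd(long$y) == 0) {
    return(list(design = "repeated_multi", statistic = 0,
                df = c(length(exons) - 1L, (length(exons) - 1L) * (n - 1L)),
                p = 1, pairwise = pw))
  }
  fit <- stats::aov(y ~ exon + sample, data = long)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  list(design = "repeated_multi",
       statistic = tab["exon", "F value"],
       df = c(tab["exon", "Df"], tab["Residuals", "Df"]),
       p = tab["exon", "Pr(>F)"],
       pairwise = pw)
}
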