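#' Replicate consensus of two peak sets
#'
#' Retains peaks of `rep1` that overlap at least one `rep2` peak by
#' `min_overlap_bp` bases. Under `merge = "union"` each retained peak is
#' extended to the union with its overlapping `rep2` partners (conservative
#' boundaries); under `"intersection"` it is trimmed to the intersection.
#' Overlapping output peaks are coalesced, so
#' `replicate_consensus(x, x)` equals `reduce(x)` (idempotence).
#'
#' @param rep1,rep2 Peak `GRanges`.
#' @param min_overlap_bp Minimum shared bases (default 1).
#' @param merge `"union"` or `"intersection"`.
#' @return Sorted, coalesced `GRanges`.
#' @export
replicate_consensus <- function(rep1, rep2, min_overlap_bp = 1L,
                                merge = c("union", "intersection")) {
  merge <- match.arg(merge)
  stopifnot(is(rep1, "GRanges"), is(rep2, "GRanges"), min_overlap_bp >= 1L)
  if (length(rep1) == 0L || length(rep2) == 0L) {
    return(GenomicRanges::GRanges())
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    rep1, rep2, minoverlap = min_overlap_bp, ignore.strand = TRUE))
  if (length(hits) == 0L) return(GenomicRanges::GRanges())
  a <- GenomicRanges::granges(rep1[S4Vectors::queryHits(hits)])
  b <- GenomicRanges::granges(rep2[S4Vectors::subjectHits(hits)])
  merged <- if (merge == "union") GenomicRanges::punion(a, b)
  else GenomicRanges::pintersect(a, b)
  S4Vectors::mcols(merged) <- NULL
  GenomicRanges::reduce(GenomicRanges::sort(merged, ignore.strand = TRUE),
                        ignore.strand = TRUE)
}

#' Annotate peaks with genomic-feature categories
#'
#' Assigns exactly one category per peak by precedence
#' promoter > five_utr > three_utr > exon > intron > downstream >
#' distal_intergenic, testing overlap against: the TSS window
#' (`promoter_bp` up- and downstream of each TSS), annotated 5'/3' UTRs,
#' coding exons excluding UTRs (exons of CDS-less transcripts count here
#' too), introns, up to `downstream_bp` past the TES, and otherwise distal.
#' The nearest gene and signed distance from peak midpoint to the nearest
#' TSS (positive = downstream of the TSS in transcription direction) are
#' reported for every peak.
#'
#' @param peaks Peak `GRanges`.
#' @param ann Reference `gene_annotation` (UTRs derived from CDS records
#'   when present).
#' @param promoter_bp Promoter half-window around the TSS (default 3000).
#' @param downstream_bp Downstream window past the TES (default 3000).
#' @return data.frame: `peak_id`, `chrom`, `start`, `end`, `category`
#'   (factor over all seven levels), `nearest_gene`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, ann, promoter_bp = 3000L,
                           downstream_bp = 3000L) {
  stopifnot(is(peaks, "GRanges"), inherits(ann, "gene_annotation"))
  levels <- c("promoter", "five_utr", "three_utr", "exon", "intron",
              "downstream", "distal_intergenic")
  n <- length(peaks)
  if (n == 0L) {
    return(data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      category = factor(character(0), levels = levels),
                      nearest_gene = character(0),
                      distance_to_tss = integer(0)))
  }
  feats <- transcript_features(ann)
  tss_gr <- tss(ann)
  tes_gr <- tes(ann)
  prom <- suppressWarnings(GenomicRanges::resize(
    tss_gr, width = 2L * promoter_bp + 1L, fix = "center"))
  down <- suppressWarnings(GenomicRanges::flank(
    tes_gr, width = downstream_bp, start = FALSE))
  exon_feat <- c(feats$coding_exons, feats$noncoding_exons)

  regions <- list(promoter = prom, five_utr = feats$five_utr,
                  three_utr = feats$three_utr, exon = exon_feat,
                  intron = feats$introns, downstream = down)
  category <- rep("distal_intergenic", n)
  unassigned <- rep(TRUE, n)
  for (nm in names(regions)) {
    reg <- regions[[nm]]
    if (length(reg) == 0L) next
    hit <- suppressWarnings(IRanges::overlapsAny(peaks, reg,
                                                 ignore.strand = TRUE))
    category[unassigned & hit] <- nm
    unassigned <- unassigned & !hit
  }

  mid_pos <- (BiocGenerics::start(peaks) + BiocGenerics::end(peaks)) %/% 2L
  mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                                 IRanges::IRanges(mid_pos, width = 1L))
  nearest <- suppressWarnings(GenomicRanges::distanceToNearest(
    mids, tss_gr, ignore.strand = TRUE))
  nearest_gene <- rep(NA_character_, n)
  distance_to_tss <- rep(NA_integer_, n)
  qh <- S4Vectors::queryHits(nearest); sh <- S4Vectors::subjectHits(nearest)
  tx_of_tss <- names(tss_gr)
  nearest_gene[qh] <- ann$tx[tx_of_tss[sh], "gene_id"]
  delta <- mid_pos[qh] - BiocGenerics::start(tss_gr)[sh]
  minus <- as.character(BiocGenerics::strand(tss_gr))[sh] == "-"
  distance_to_tss[qh] <- ifelse(minus, -delta, delta)

  data.frame(
    peak_id = if (!is.null(names(peaks)) && any(nzchar(names(peaks))))
      names(peaks) else sprintf("peak_%d", seq_len(n)),
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = BiocGenerics::start(peaks),
    end = BiocGenerics::end(peaks),
    category = factor(category, levels = levels),
    nearest_gene = nearest_gene,
    distance_to_tss = distance_to_tss,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Chromatin-state enrichment of a peak set
#'
#' Counts peaks whose midpoint falls in each state of a chromatin-state
#' partition and compares with uniform random placement of the same number
#' of midpoints over the partitioned genome (`n_shuffles` permutations,
#' seeded), giving fold enrichment and an add-one empirical two-sided
#' p-value. With `n_shuffles = 0` the analytic expectation
#' (state coverage fraction x number of peaks) is used and `p` is NA.
#'
#' @param peaks Peak `GRanges`.
#' @param states `GRanges` with a `state` column that partitions each
#'   chromosome (no gaps, no overlaps); error otherwise.
#' @param n_shuffles Number of random placements (default 200).
#' @param seed Seed for the placements.
#' @return data.frame: `state`, `observed`, `expected`, `fold`, `p`.
#' @export
state_enrichment <- function(peaks, states, n_shuffles = 200L, seed = 1L) {
  stopifnot(is(peaks, "GRanges"), is(states, "GRanges"),
            !is.null(states$state))
  # partition check per chromosome
  for (chrom in unique(as.character(GenomeInfoDb::seqnames(states)))) {
    s <- states[as.character(GenomeInfoDb::seqnames(states)) == chrom]
    s <- GenomicRanges::sort(s, ignore.strand = TRUE)
    st <- BiocGenerics::start(s); en <- BiocGenerics::end(s)
    if (length(s) > 1L && any(st[-1] != en[-length(en)] + 1L)) {
      stop("states do not partition ", chrom, " (gap or overlap)")
    }
  }
  state_names <- sort(unique(states$state))
  mid_pos <- (BiocGenerics::start(peaks) + BiocGenerics::end(peaks)) %/% 2L
  mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                                 IRanges::IRanges(mid_pos, width = 1L))
  count_states <- function(gr) {
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, states,
                                                       ignore.strand = TRUE))
    tab <- table(factor(states$state[S4Vectors::subjectHits(ov)],
                        levels = state_names))
    as.vector(tab)
  }
  observed <- count_states(mids)
  n_peaks <- length(mids)

  w <- BiocGenerics::width(states)
  total <- sum(as.numeric(w))
  if (n_shuffles == 0L) {
    cov_frac <- as.vector(tapply(as.numeric(w), states$state, sum))[
      match(state_names, sort(unique(states$state)))]
    expected <- n_peaks * cov_frac / total
    fold <- ifelse(expected > 0, observed / expected, NA_real_)
    return(data.frame(state = state_names, observed = observed,
                      expected = expected, fold = fold, p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  cum <- cumsum(as.numeric(w))
  perm <- withr::with_seed(seed, {
    m <- matrix(0L, n_shuffles, length(state_names))
    for (i in seq_len(n_shuffles)) {
      u <- stats::runif(n_peaks, 0, total)
      seg <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
      seg[seg > length(w)] <- length(w)
      m[i, ] <- as.vector(table(factor(states$state[seg],
                                       levels = state_names)))
    }
    m
  })
  expected <- colMeans(perm)
  fold <- ifelse(expected > 0, observed / expected, NA_real_)
  p <- vapply(seq_along(state_names), function(k) {
    hi <- (1 + sum(perm[, k] >= observed[k])) / (n_shuffles + 1)
    lo <- (1 + sum(perm[, k] <= observed[k])) / (n_shuffles + 1)
    min(1, 2 * min(hi, lo))
  }, numeric(1))
  data.frame(state = state_names, observed = observed, expected = expected,
             fold = fold, p = p, stringsAsFactors = FALSE)
}

#' Genes associated with annotated peaks
#'
#' The set of genes having at least one peak in any non-distal category;
#' optionally distal peaks are included through their nearest gene.
#'
#' @param annots data.frame from [annotate_peaks()].
#' @param include_distal Include distal peaks via nearest gene?
#' @return Sorted character vector of gene ids.
#' @export
peaks_to_genes <- function(annots, include_distal = FALSE) {
  stopifnot(all(c("category", "nearest_gene") %in% names(annots)))
  keep <- if (include_distal) rep(TRUE, nrow(annots))
  else annots$category != "distal_intergenic"
  sort(unique(stats::na.omit(annots$nearest_gene[keep])))
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability `P[X >= k]` of observing at least
#' the actual overlap between two gene sets drawn from a universe of
#' `universe_n` genes, plus the Jaccard index. The universe must be stated
#' explicitly: the p-value depends strongly on it.
#'
#' @param a,b Character vectors (gene sets; de-duplicated).
#' @param universe_n Universe size (>= size of either set).
#' @return List: `k` (overlap), `n_a`, `n_b`, `universe_n`, `p`, `jaccard`.
#' @export
set_overlap_test <- function(a, b, universe_n) {
  a <- unique(a); b <- unique(b)
  if (length(a) > universe_n || length(b) > universe_n) {
    stop("set larger than universe")
  }
  k <- length(intersect(a, b))
  if (k > min(length(a), length(b))) stop("impossible overlap")  # defensive
  p <- stats::phyper(k - 1, length(a), universe_n - length(a), length(b),
                     lower.tail = FALSE)
  uni <- length(union(a, b))
  list(k = k, n_a = length(a), n_b = length(b), universe_n = universe_n,
       p = p, jaccard = if (uni == 0) NA_real_ else k / uni)
}

#' Three-way overlap region counts
#'
#' Venn-region cardinalities for three gene sets.
#'
#' @param a,b,c Character vectors.
#' @return Named integer vector: `a_only`, `b_only`, `c_only`, `ab_only`,
#'   `ac_only`, `bc_only`, `abc`.
#' @export
three_way_overlap <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  all_ids <- union(union(a, b), c)
  ina <- all_ids %in% a; inb <- all_ids %in% b; inc <- all_ids %in% c
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}
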