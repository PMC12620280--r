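#' @importFrom methods is
#' @importFrom stats setNames
NULL

#' Build a gene annotation from an exon table
#'
#' The central annotation container used by every stage. Exons are stored as a
#' [GenomicRanges::GRanges] (1-based, closed intervals, the native convention
#' of the Bioconductor interval stack); GTF and BED dialects are converted at
#' the I/O boundary by [read_annotation()] / [read_peaks()].
#'
#' @param exons A `GRanges` with metadata columns `transcript_id` and
#'   `gene_id` (optionally `biotype`), one range per exon.
#' @param cds Optional `GRanges` of coding regions with a `transcript_id`
#'   column; used to derive UTRs for peak annotation.
#'
#' @return An object of class `gene_annotation`, a list with elements
#'   `exons` (sorted `GRanges`), `exons_by_tx` (`GRangesList` keyed by
#'   transcript id, exons in genomic order), `tx` (per-transcript table with
#'   `transcript_id`, `gene_id`, `biotype`, `n_exons`, `spliced_length`),
#'   `tx_ranges` (stranded transcript spans), `genes` (per-gene spans), and
#'   `cds`.
#' @export
gene_annotation <- function(exons, cds = NULL) {
  stopifnot(is(exons, "GRanges"))
  m <- S4Vectors::mcols(exons)
  if (is.null(m$transcript_id) || is.null(m$gene_id)) {
    stop("exons must carry 'transcript_id' and 'gene_id' metadata columns")
  }
  if (length(exons) == 0L) stop("annotation must contain at least one exon")
  if (anyNA(m$transcript_id) || anyNA(m$gene_id)) {
    stop("transcript_id / gene_id must not be NA")
  }
  if (is.null(m$biotype)) exons$biotype <- NA_character_

  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)
  by_tx <- S4Vectors::split(exons, exons$transcript_id)

  # per-transcript invariants: one chrom, one strand, disjoint exon chain
  n_chrom <- vapply(by_tx, function(g)
    length(unique(as.character(GenomeInfoDb::seqnames(g)))), integer(1))
  n_strand <- vapply(by_tx, function(g)
    length(unique(as.character(BiocGenerics::strand(g)))), integer(1))
  if (any(n_chrom != 1L) || any(n_strand != 1L)) {
    bad <- names(by_tx)[n_chrom != 1L | n_strand != 1L]
    stop("transcript(s) with exons on multiple chromosomes/strands: ",
         paste(bad, collapse = ", "))
  }
  disjoint <- vapply(by_tx, IRanges::isDisjoint, logical(1))
  if (!all(disjoint)) {
    stop("transcript(s) with overlapping exons: ",
         paste(names(by_tx)[!disjoint], collapse = ", "))
  }

  first_idx <- !duplicated(exons$transcript_id)
  tx <- data.frame(
    transcript_id = exons$transcript_id[first_idx],
    gene_id       = exons$gene_id[first_idx],
    biotype       = exons$biotype[first_idx],
    stringsAsFactors = FALSE
  )
  tx <- tx[match(names(by_tx), tx$transcript_id), , drop = FALSE]
  tx$n_exons <- as.integer(lengths(by_tx))
  tx$spliced_length <- as.integer(sum(IRanges::width(by_tx)))
  rownames(tx) <- tx$transcript_id

  tx_ranges <- unlist(range(by_tx))  # keeps strand; one range per transcript

  gene_split <- S4Vectors::split(
    GenomicRanges::granges(tx_ranges),
    tx$gene_id[match(names(tx_ranges), tx$transcript_id)]
  )
  genes <- unlist(range(gene_split, ignore.strand = TRUE))
  # keep gene strand when all its transcripts agree
  gstrand <- vapply(gene_split, function(g) {
    s <- unique(as.character(BiocGenerics::strand(g)))
    if (length(s) == 1L) s else "*"
  }, character(1))
  BiocGenerics::strand(genes) <- gstrand[names(genes)]
  genes$gene_id <- names(genes)

  structure(
    list(exons = exons, exons_by_tx = by_tx, tx = tx,
         tx_ranges = tx_ranges, genes = genes, cds = cds),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d transcripts, %d genes, %d exons on %d sequence(s)\n",
              nrow(x$tx), length(x$genes), length(x$exons),
              length(unique(as.character(GenomeInfoDb::seqnames(x$exons))))))
  invisible(x)
}

#' Transcription start / end sites
#'
#' `tss()` returns the first transcribed base of each transcript and `tes()`
#' the last, as width-1 `GRanges` named by transcript id (strand-aware: on the
#' minus strand the TSS is the exon chain's maximum coordinate).
#'
#' @param ann A `gene_annotation`.
#' @return A width-1 `GRanges`, one range per transcript.
#' @export
tss <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  GenomicRanges::resize(ann$tx_ranges, width = 1L, fix = "start")
}

#' @rdname tss
#' @export
tes <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  GenomicRanges::resize(ann$tx_ranges, width = 1L, fix = "end")
}

#' Spliced transcript lengths
#'
#' @param ann A `gene_annotation`.
#' @return Named integer vector of summed exon widths per transcript.
#' @export
spliced_length <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  setNames(ann$tx$spliced_length, ann$tx$transcript_id)
}

#' Pairwise interval overlap with a minimum-width requirement
#'
#' True where intervals `a[i]` and `b[i]` share at least `min_bp` bases on the
#' same chromosome. Vectors recycle in the usual way (either argument may have
#' length 1).
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @param min_bp Minimum overlap in bp (>= 1).
#' @param stranded If `TRUE`, ranges on different strands never overlap
#'   (`*` matches either).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b, min_bp = 1L, stranded = FALSE) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), min_bp >= 1L)
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same_chrom <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  ov <- pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
    pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L
  out <- same_chrom & ov >= min_bp
  if (stranded) {
    sa <- as.character(BiocGenerics::strand(a))
    sb <- as.character(BiocGenerics::strand(b))
    out <- out & (sa == "*" | sb == "*" | sa == sb)
  }
  out
}

#' Classify transcripts as intergenic or gene-overlapping
#'
#' A transcript is `intergenic` when none of its exons overlaps the reference
#' annotation; otherwise `genic_overlap`. In `gene_span` mode (the default)
#' the reference is the full per-gene span, so introns of annotated genes
#' count as genic; in `exonic` mode only annotated exons count. The default is
#' strand-agnostic: a lincRNA must avoid annotated loci on either strand.
#'
#' Transcripts on chromosomes absent from the reference are classified
#' `intergenic` with a warning.
#'
#' @param query A `gene_annotation` (the assembled transcripts) or a `GRanges`
#'   of exons with a `transcript_id` column.
#' @param reference A `gene_annotation`.
#' @param mode `"gene_span"` or `"exonic"`.
#' @param stranded Require same-strand overlap?
#' @return Named character vector (`"intergenic"` / `"genic_overlap"`), one
#'   entry per query transcript.
#' @export
classify_location <- function(query, reference,
                              mode = c("gene_span", "exonic"),
                              stranded = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "gene_annotation"))
  qex <- if (inherits(query, "gene_annotation")) query$exons else query
  stopifnot(is(qex, "GRanges"), !is.null(qex$transcript_id))
  tx_ids <- unique(qex$transcript_id)

  subject <- if (mode == "gene_span") reference$genes else reference$exons
  q_chr <- as.character(GenomeInfoDb::seqnames(qex))
  s_chr <- unique(as.character(GenomeInfoDb::seqnames(subject)))
  missing_chr <- setdiff(unique(q_chr), s_chr)
  if (length(missing_chr)) {
    warning("chromosome(s) absent from reference annotation, transcripts ",
            "there treated as intergenic: ", paste(missing_chr, collapse = ", "))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    qex, subject, ignore.strand = !stranded))
  hit_tx <- unique(qex$transcript_id[S4Vectors::queryHits(hits)])
  setNames(ifelse(tx_ids %in% hit_tx, "genic_overlap", "intergenic"), tx_ids)
}

#' Derive UTR and intron structure from an annotation
#'
#' For transcripts that carry CDS information, UTRs are the exonic bases
#' outside the CDS, split into 5' and 3' by their position relative to the CDS
#' in transcription direction. Exons of transcripts without CDS are reported
#' under `noncoding_exons`. Introns are the gaps of each exon chain.
#'
#' @param ann A `gene_annotation`.
#' @return List of `GRanges`: `five_utr`, `three_utr`, `coding_exons`,
#'   `noncoding_exons`, `introns` (each with a `transcript_id` column where
#'   applicable).
#' @export
transcript_features <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  introns <- unlist(GenomicRanges::psetdiff(ann$tx_ranges,
                                            ann$exons_by_tx[names(ann$tx_ranges)]))
  if (length(introns)) {
    introns$transcript_id <- names(introns)
    names(introns) <- NULL
  }
  empty <- GenomicRanges::GRanges()
  if (is.null(ann$cds) || length(ann$cds) == 0L) {
    return(list(five_utr = empty, three_utr = empty, coding_exons = empty,
                noncoding_exons = GenomicRanges::granges(ann$exons),
                introns = introns))
  }
  # UTR pieces: exonic bases outside the CDS genomic span of their transcript.
  # (The CDS occupies every exonic base between its first and last position,
  # so clipping exons against the per-transcript CDS span is exact.)
  cds_tx <- unique(ann$cds$transcript_id)
  cds_lo <- tapply(BiocGenerics::start(ann$cds), ann$cds$transcript_id, min)
  cds_hi <- tapply(BiocGenerics::end(ann$cds), ann$cds$transcript_id, max)
  ex <- ann$exons[ann$exons$transcript_id %in% cds_tx]
  lo <- unname(cds_lo[ex$transcript_id]); hi <- unname(cds_hi[ex$transcript_id])
  es <- BiocGenerics::start(ex); ee <- BiocGenerics::end(ex)
  chr <- as.character(GenomeInfoDb::seqnames(ex))
  str <- as.character(BiocGenerics::strand(ex))
  mk_side <- function(ps, pe, left_of_cds) {
    keep <- ps <= pe
    if (!any(keep)) return(list(five = empty, three = empty))
    gr <- GenomicRanges::GRanges(chr[keep], IRanges::IRanges(ps[keep], pe[keep]),
                                 strand = str[keep],
                                 transcript_id = ex$transcript_id[keep])
    plus <- str[keep] != "-"
    is_five <- if (left_of_cds) plus else !plus
    list(five = gr[is_five], three = gr[!is_five])
  }
  left <- mk_side(es, pmin(ee, lo - 1L), TRUE)
  right <- mk_side(pmax(es, hi + 1L), ee, FALSE)
  nc <- ann$exons[!(ann$exons$transcript_id %in% cds_tx)]
  list(five_utr = c(left$five, right$five),
       three_utr = c(left$three, right$three),
       coding_exons = GenomicRanges::granges(ann$cds),
       noncoding_exons = GenomicRanges::granges(nc),
       introns = introns)
}
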