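#' Read a gene annotation from GTF
#'
#' Exon (and, when present, CDS) records are assembled into a
#' [gene_annotation()]. rtracklayer performs the GTF dialect conversion
#' (1-based closed on disk) into `GRanges`.
#'
#' @param path Path to a GTF file.
#' @return A `gene_annotation`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "': ", conditionMessage(e))
  )
  if (is.null(gr$type)) stop("GTF '", path, "' lacks a feature type column")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("GTF '", path, "' contains no exon records")
  if (anyNA(ex$transcript_id)) {
    stop("GTF '", path, "': exon record(s) without transcript_id")
  }
  keep <- intersect(c("transcript_id", "gene_id", "biotype"),
                    colnames(S4Vectors::mcols(ex)))
  S4Vectors::mcols(ex) <- S4Vectors::mcols(ex)[, keep, drop = FALSE]
  cds <- gr[gr$type == "CDS"]
  if (length(cds)) {
    S4Vectors::mcols(cds) <-
      S4Vectors::mcols(cds)[, intersect(c("transcript_id", "gene_id"),
                                        colnames(S4Vectors::mcols(cds))),
                            drop = FALSE]
  } else {
    cds <- NULL
  }
  gene_annotation(ex, cds = cds)
}

#' Write a gene annotation to GTF
#'
#' @param ann A `gene_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  ex <- ann$exons
  ex$type <- "exon"
  ex$source <- "lncdiscover"
  out <- ex
  if (!is.null(ann$cds) && length(ann$cds)) {
    cds <- ann$cds
    cds$gene_id <- ann$tx[cds$transcript_id, "gene_id"]
    cds$biotype <- NA_character_
    cds$type <- "CDS"
    cds$source <- "lncdiscover"
    # reading frame per CDS piece, in transcription order
    cds$phase <- 0L
    for (txid in unique(cds$transcript_id)) {
      i <- which(cds$transcript_id == txid)
      o <- if (as.character(BiocGenerics::strand(cds)[i[1]]) == "-") {
        i[order(-BiocGenerics::start(cds)[i])]
      } else {
        i[order(BiocGenerics::start(cds)[i])]
      }
      w <- BiocGenerics::width(cds)[o]
      cds$phase[o] <- as.integer((3L - cumsum(c(0L, utils::head(w, -1L))) %% 3L) %% 3L)
    }
    ex$phase <- NA_integer_
    out <- c(ex, cds)
  }
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read a peak track (BED or narrowPeak)
#'
#' Files with >= 10 columns are treated as narrowPeak (BED6+4) and the
#' `score` metadata column is set from column 7 (`signalValue`); otherwise the
#' file is read as plain BED and the BED score column (5) is used when
#' present. BED's 0-based half-open coordinates are converted to the 1-based
#' closed `GRanges` convention by rtracklayer. The result is sorted.
#'
#' @param path Path to a BED / narrowPeak file.
#' @param name Optional track name stored as metadata.
#' @param replicate_id Optional replicate label stored as metadata.
#' @return A sorted `GRanges` with a numeric `score` column (NA when the file
#'   carries no score), and `name`/`replicate_id` in [S4Vectors::metadata()].
#' @export
read_peaks <- function(path, name = NA_character_, replicate_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) &
                   !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
  } else {
    ncols <- length(strsplit(lines[[1]], "[\t ]+")[[1]])
    if (ncols >= 10L) {
      gr <- rtracklayer::import(
        path, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer"))
      gr$score <- gr$signalValue
    } else {
      gr <- rtracklayer::import(path, format = "BED")
      if (is.null(gr$score)) gr$score <- NA_real_
    }
    if (any(!is.finite(gr$score) & !is.na(gr$score))) {
      stop("non-finite peak score(s) in ", path)
    }
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  }
  S4Vectors::metadata(gr)$name <- name
  S4Vectors::metadata(gr)$replicate_id <- replicate_id
  gr
}

#' Write peaks as BED or narrowPeak
#'
#' narrowPeak output carries the 10-column BED6+4 layout with the `score`
#' metadata column written to `signalValue` (column 7); summit offset is set
#' to -1 (unknown).
#'
#' @param peaks A `GRanges`, optionally with `score`.
#' @param path Output path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  stopifnot(is(peaks, "GRanges"))
  if (format == "bed") {
    out <- peaks
    if (!is.null(out$score) && anyNA(out$score)) out$score <- NULL
    rtracklayer::export(out, path, format = "BED")
  } else {
    score <- if (is.null(peaks$score)) rep(0, length(peaks)) else peaks$score
    score[is.na(score)] <- 0
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(peaks)),
      start = BiocGenerics::start(peaks) - 1L,  # to 0-based half-open
      end = BiocGenerics::end(peaks),
      name = if (is.null(names(peaks)) || !any(nzchar(names(peaks))))
        sprintf("peak_%d", seq_along(peaks)) else names(peaks),
      score = 0L,
      strand = sub("\\*", ".", as.character(BiocGenerics::strand(peaks))),
      signalValue = score,
      pValue = -1,
      qValue = -1,
      peak = -1L
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write a chromatin-state segmentation (BED with state names)
#'
#' The state label is taken from the BED `name` column.
#'
#' @param path BED file path.
#' @return `GRanges` with a `state` column.
#' @export
read_states <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) stop("state BED '", path, "' lacks a name column")
  gr$state <- gr$name
  gr$name <- NULL
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_states
#' @param states `GRanges` with a `state` column.
#' @export
write_states <- function(states, path) {
  stopifnot(is(states, "GRanges"), !is.null(states$state))
  out <- GenomicRanges::granges(states)
  out$name <- states$state
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
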