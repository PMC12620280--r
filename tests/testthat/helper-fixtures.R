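suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# plain GRanges shorthand with a fixture-wide chromosome set
gr <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(factor(chrom, levels = c("chr1", "chr2", "chrX")),
                         IRanges::IRanges(start, end), strand = strand, ...)
}

# two-gene toy reference with CDS (gene A on +, gene B on -), one lncRNA
toy_reference <- function() {
  exons <- c(
    gr("chr1", c(1000, 2000, 3000), c(1199, 2399, 3499), "+",
       transcript_id = "gA.t1", gene_id = "gA", biotype = "protein_coding"),
    gr("chr1", c(10000, 12000), c(10499, 12799), "-",
       transcript_id = "gB.t1", gene_id = "gB", biotype = "protein_coding"),
    gr("chr2", c(5000, 6000), c(5299, 6399), "+",
       transcript_id = "gC.t1", gene_id = "gC", biotype = "lincRNA")
  )
  # gA spliced length 1000; CDS = spliced [151, 850]:
  #   exon1 has 1000..1199 (200 bp, spliced 1..200) -> CDS from 1150
  #   exon2 spliced 201..600 fully coding; exon3 spliced 601..1100 -> to 3249
  cds <- c(
    gr("chr1", c(1150, 2000, 3000), c(1199, 2399, 3249), "+",
       transcript_id = "gA.t1"),
    gr("chr1", c(10100, 12000), c(10499, 12599), "-",
       transcript_id = "gB.t1")
  )
  gene_annotation(exons, cds = cds)
}

# random annotation fixture: n_tx multi-exon transcripts over a small genome
random_annotation <- function(n_tx, chroms = c("chr1", "chr2"),
                              genome_bp = 2e5, p_cds = 0) {
  ids <- sprintf("t%03d", seq_len(n_tx))
  rows <- lapply(seq_len(n_tx), function(i) {
    n_ex <- sample(1:4, 1)
    w <- sample(50:300, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(100:1000, n_ex - 1, replace = TRUE)
    else integer(0)
    start0 <- sample(seq_len(genome_bp - 10000), 1)
    starts <- start0 + cumsum(c(0, head(w, -1) + gaps))
    data.frame(chrom = sample(chroms, 1), start = starts,
               end = starts + w - 1,
               strand = sample(c("+", "-"), 1), id = ids[i])
  })
  df <- do.call(rbind, rows)
  gene_annotation(gr(df$chrom, df$start, df$end, df$strand,
                     transcript_id = df$id, gene_id = df$id))
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), genome_bp = 2e5,
                         w_range = c(50, 500)) {
  w <- sample(w_range[1]:w_range[2], n, replace = TRUE)
  s <- sample(seq_len(genome_bp), n, replace = TRUE)
  sort(gr(sample(chroms, n, replace = TRUE), s, s + w - 1), ignore.strand = TRUE)
}

# reduced-size simulation config used by per-module tests
small_cfg <- function(seed = 1) {
  sim_config(seed = seed, n_genes = 40L, n_candidates = 4L,
             n_decoys_per_class = 2L, n_background = 30L,
             chrom_length = 1.2e6,
             chirp_n_promoter = 8L, chirp_n_intron = 6L, chirp_n_exon = 4L,
             chirp_n_distal = 5L, chirp_n_noise = 5L,
             n_patients = 150L)
}

# share one default-condition study across acceptance tests
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_study(sim_config(seed = seed))
  }
  .sim_cache[[key]]
}

# expected structural-flag failures per decoy class
decoy_expected_fails <- function(class) {
  switch(class,
         too_short = "length_gt_200",
         genic = "intergenic",
         low_expression = "mean_rpkm_ge_0.5",
         no_marks = c("dnase_support", "h3k4me3_support"),
         single_exon = "multi_exon",
         monster_exon = "exon_size_ok",
         not_DE = character(0))
}

STRUCT_FLAGS <- c("length_gt_200", "intergenic", "mean_rpkm_ge_0.5",
                  "dnase_support", "h3k4me3_support", "multi_exon",
                  "exon_size_ok")

# brute-force all-pairs intergenic classifier (arithmetic only, no index)
brute_classify <- function(query_ann, ref_ann, mode = "gene_span") {
  subj <- if (mode == "gene_span") ref_ann$genes else ref_ann$exons
  s_chr <- as.character(seqnames(subj))
  s_lo <- start(subj); s_hi <- end(subj)
  out <- character(nrow(query_ann$tx))
  names(out) <- query_ann$tx$transcript_id
  for (id in names(out)) {
    ex <- query_ann$exons_by_tx[[id]]
    hit <- FALSE
    for (k in seq_along(ex)) {
      same <- s_chr == as.character(seqnames(ex))[k]
      ov <- pmin(s_hi, end(ex)[k]) - pmax(s_lo, start(ex)[k]) + 1L
      if (any(same & ov >= 1L)) { hit <- TRUE; break }
    }
    out[id] <- if (hit) "genic_overlap" else "intergenic"
  }
  out
}

# brute-force replicate consensus (union merge), all-pairs scan
brute_consensus <- function(rep1, rep2, min_bp = 1L) {
  c1 <- as.character(seqnames(rep1)); c2 <- as.character(seqnames(rep2))
  out_s <- integer(0); out_e <- integer(0); out_c <- character(0)
  for (i in seq_along(rep1)) {
    same <- c2 == c1[i]
    ov <- pmin(end(rep2), end(rep1)[i]) - pmax(start(rep2), start(rep1)[i]) + 1L
    j <- which(same & ov >= min_bp)
    if (length(j)) {
      out_s <- c(out_s, min(start(rep1)[i], start(rep2)[j]))
      out_e <- c(out_e, max(end(rep1)[i], end(rep2)[j]))
      out_c <- c(out_c, c1[i])
    }
  }
  if (!length(out_s)) return(GRanges())
  reduce(sort(gr(out_c, out_s, out_e), ignore.strand = TRUE),
         ignore.strand = TRUE)
}

# brute-force per-peak category classifier built from first principles
brute_annotate <- function(peaks, ann, promoter_bp = 3000, downstream_bp = 3000) {
  feats <- list()
  tx_ids <- ann$tx$transcript_id
  cds_tx <- if (is.null(ann$cds)) character(0) else unique(ann$cds$transcript_id)
  seg <- function(chrom, lo, hi) list(chrom = chrom, lo = lo, hi = hi)
  prom <- list(); utr5 <- list(); utr3 <- list(); exn <- list()
  intr <- list(); down <- list()
  for (id in tx_ids) {
    ex <- ann$exons_by_tx[[id]]
    chrom <- as.character(seqnames(ex))[1]
    plus <- as.character(strand(ex))[1] != "-"
    tss_pos <- if (plus) min(start(ex)) else max(end(ex))
    tes_pos <- if (plus) max(end(ex)) else min(start(ex))
    prom[[length(prom) + 1]] <- seg(chrom, tss_pos - promoter_bp,
                                    tss_pos + promoter_bp)
    down[[length(down) + 1]] <- if (plus)
      seg(chrom, tes_pos + 1, tes_pos + downstream_bp)
    else seg(chrom, tes_pos - downstream_bp, tes_pos - 1)
    # introns
    if (length(ex) > 1) {
      o <- order(start(ex))
      for (k in seq_len(length(ex) - 1)) {
        intr[[length(intr) + 1]] <- seg(chrom, end(ex)[o[k]] + 1,
                                        start(ex)[o[k + 1]] - 1)
      }
    }
    if (id %in% cds_tx) {
      cds <- ann$cds[ann$cds$transcript_id == id]
      lo <- min(start(cds)); hi <- max(end(cds))
      for (k in seq_along(ex)) {
        es <- start(ex)[k]; ee <- end(ex)[k]
        cs <- max(es, lo); ce <- min(ee, hi)
        if (cs <= ce) exn[[length(exn) + 1]] <- seg(chrom, cs, ce)
        if (es < lo) {
          piece <- seg(chrom, es, min(ee, lo - 1))
          if (plus) utr5[[length(utr5) + 1]] <- piece
          else utr3[[length(utr3) + 1]] <- piece
        }
        if (ee > hi) {
          piece <- seg(chrom, max(es, hi + 1), ee)
          if (plus) utr3[[length(utr3) + 1]] <- piece
          else utr5[[length(utr5) + 1]] <- piece
        }
      }
    } else {
      for (k in seq_along(ex)) {
        exn[[length(exn) + 1]] <- seg(chrom, start(ex)[k], end(ex)[k])
      }
    }
  }
  hits_any <- function(chrom, lo, hi, segs) {
    for (s in segs) {
      if (s$chrom == chrom && s$lo <= hi && s$hi >= lo && s$lo <= s$hi) {
        return(TRUE)
      }
    }
    FALSE
  }
  ordered <- list(promoter = prom, five_utr = utr5, three_utr = utr3,
                  exon = exn, intron = intr, downstream = down)
  vapply(seq_along(peaks), function(i) {
    chrom <- as.character(seqnames(peaks))[i]
    lo <- start(peaks)[i]; hi <- end(peaks)[i]
    for (nm in names(ordered)) {
      if (hits_any(chrom, lo, hi, ordered[[nm]])) return(nm)
    }
    "distal_intergenic"
  }, character(1))
}

# hypergeometric upper tail by direct combinatorial summation
hyper_tail <- function(k, n_a, n_b, N) {
  j <- seq(k, min(n_a, n_b))
  sum(choose(n_a, j) * choose(N - n_a, n_b - j)) / choose(N, n_b)
}
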