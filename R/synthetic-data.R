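#' Simulation configuration
#'
#' Defines the study conditions the generators emulate: a desk-scale genome
#' (3 chromosomes x 3 Mb) carrying 200 reference protein-coding genes, 10
#' planted intergenic multi-exon lncRNA candidates, 5 decoys per violation
#' class and 100 stable background transcripts; a 20 leukemia vs 10
#' normal-bone-marrow count cohort with negative-binomial noise and
#' direction-balanced planted fold changes (so library composition stays
#' comparable between groups); promoter DNase/H3K4me3 tracks; two jittered
#' ChIRP replicates and a chromatin-state partition; a patient cohort with
#' mutation flags, exponential survival with a planted hazard ratio of 0.63
#' for the high-expression group, and 4PL dose-response plates with one drug
#' carrying a planted sensitivity-score difference of 1.633.
#'
#' @param seed Root seed; each generator derives its own sub-seed from it so
#'   stages can be regenerated independently.
#' @param ... Overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome layout
    n_chrom = 3L, chrom_length = 3e6, slot_bp = 2e4,
    n_genes = 200L, n_candidates = 10L, n_decoys_per_class = 5L,
    n_background = 100L, monster_exon_bp = 15000L,
    # counts
    n_aml = 20L, n_nbm = 10L, nb_dispersion = 0.05,
    base_mu = 60, low_expr_mu = 0, lfc_range = c(2, 3),
    # tracks
    peak_halfwidth = c(200L, 400L),
    chirp_n_promoter = 20L, chirp_n_intron = 15L, chirp_n_exon = 10L,
    chirp_n_distal = 15L, chirp_n_noise = 15L,
    chirp_jitter = 50L, chirp_peak_width = 400L,
    state_names = c("active_tss", "enhancer", "transcription",
                    "heterochromatin", "polycomb", "quiescent"),
    state_seg_mean = 8e4,
    # cohort / survival / drugs
    n_patients = 300L, nonexpressor_fraction = 0.45,
    survival_beta = log(0.63), transplant_fraction = 0.2,
    drugs = c("arsenic_trioxide", paste0("drug_", LETTERS[2:8])),
    conc_max_uM = 15, n_doses = 8L, dose_step_log10 = 0.5,
    n_drug_replicates = 3L, drug_noise_sd = 0.5,
    planted_sdss = 1.633, dss_threshold = 10,
    # isoform usage
    iso_n_samples = 72L, iso_depth = 200,
    iso_start_mixture = c(Ex1.0 = 0.7, Ex1.1 = 0.2, Ex1.2 = 0.1),
    iso_term_mixture = c(Ex7 = 0.7, Ex10 = 0.3)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$nb_dispersion > 0, cfg$n_genes >= 1, cfg$n_candidates >= 0,
            cfg$n_decoys_per_class >= 0, cfg$n_aml >= 2, cfg$n_nbm >= 2)
  structure(cfg, class = "sim_config")
}

DECOY_CLASSES <- c("too_short", "genic", "low_expression", "no_marks",
                   "single_exon", "monster_exon", "not_DE")

# GRanges constructor pinned to the simulated chromosome set (avoids seqinfo
# mismatches when concatenating tracks built from different slot subsets)
.sim_gr <- function(chrom, start, end, chrs, strand = "*", ...) {
  GenomicRanges::GRanges(factor(chrom, levels = chrs),
                         IRanges::IRanges(start, end), strand = strand, ...)
}

# genomic position of a 1-based spliced coordinate along an exon chain
# (starts/ends in genomic order; pos counted in transcription direction)
.spliced_pos <- function(starts, ends, strand, pos) {
  if (strand == "-") { o <- order(-starts) } else { o <- order(starts) }
  s <- starts[o]; e <- ends[o]
  w <- e - s + 1L
  cum_hi <- cumsum(w); cum_lo <- cum_hi - w
  i <- which(pos <= cum_hi & pos > cum_lo)[1]
  off <- pos - cum_lo[i]
  if (strand == "-") e[i] - off + 1L else s[i] + off - 1L
}

#' Generate the reference and assembled annotations with planted truth
#'
#' Lays out multi-exon reference genes and assembled transcripts on a slot
#' grid (one entity per slot, generous inter-slot margins), guaranteeing by
#' construction that planted candidates are intergenic and each decoy class
#' violates exactly one discovery criterion: `too_short` (spliced length
#' <= 200 bp), `genic` (overlaps a reference gene), `single_exon`,
#' `monster_exon` (one exon above the long-exon bound), while `no_marks`,
#' `low_expression` and `not_DE` decoys are structurally sound and get their
#' violation from the track / count generators. Background transcripts are
#' structurally sound, supported and not differentially expressed: they
#' stand in for the bulk of an assembled transcriptome and keep library
#' composition realistic.
#'
#' @param cfg A [sim_config()].
#' @return List with `reference` and `assembled` (`gene_annotation`s),
#'   `truth` (per-transcript role table) and `layout` (slot bookkeeping used
#'   by [generate_tracks()]).
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    chrs <- paste0("chr", seq_len(cfg$n_chrom))
    n_slots_per_chrom <- floor(cfg$chrom_length / cfg$slot_bp)
    slots <- data.frame(
      chrom = rep(chrs, each = n_slots_per_chrom),
      origin = rep((seq_len(n_slots_per_chrom) - 1L) * cfg$slot_bp,
                   times = cfg$n_chrom),
      stringsAsFactors = FALSE
    )
    n_nongenic_decoys <- cfg$n_decoys_per_class * (length(DECOY_CLASSES) - 1L)
    n_entities <- cfg$n_genes + cfg$n_candidates + n_nongenic_decoys +
      cfg$n_background
    if (n_entities > nrow(slots)) {
      stop("genome too small: ", n_entities, " entities for ",
           nrow(slots), " slots; increase chrom_length or n_chrom")
    }
    slots <- slots[sample.int(nrow(slots)), ]
    rownames(slots) <- NULL

    # --- entity table: one row per transcript to be placed in its own slot
    ent <- data.frame(
      id = c(sprintf("REFG_%03d.t1", seq_len(cfg$n_genes)),
             sprintf("CAND_%02d", seq_len(cfg$n_candidates)),
             unlist(lapply(setdiff(DECOY_CLASSES, "genic"), function(cls)
               sprintf("DEC_%s_%02d", cls, seq_len(cfg$n_decoys_per_class)))),
             sprintf("BG_%03d", seq_len(cfg$n_background))),
      role = c(rep("gene", cfg$n_genes),
               rep("candidate", cfg$n_candidates),
               rep(setdiff(DECOY_CLASSES, "genic"),
                   each = cfg$n_decoys_per_class),
               rep("background", cfg$n_background)),
      stringsAsFactors = FALSE
    )
    ent$chrom <- slots$chrom[seq_len(nrow(ent))]
    ent$origin <- slots$origin[seq_len(nrow(ent))]
    ent$strand <- sample(c("+", "-"), nrow(ent), replace = TRUE)

    # exon widths / intron widths per entity (lists of integer vectors)
    draw_widths <- function(role) {
      switch(role,
        gene = list(ex = sample(120:400, sample(3:6, 1L), replace = TRUE),
                    intr = c(500L, 2000L)),
        too_short = list(ex = c(80L, 80L), intr = c(300L, 800L)),
        single_exon = list(ex = 800L, intr = c(0L, 0L)),
        monster_exon = list(ex = c(250L, cfg$monster_exon_bp),
                            intr = c(300L, 500L)),
        list(ex = sample(150:400, sample(3:6, 1L), replace = TRUE),
             intr = c(300L, 1500L))
      )
    }
    spec <- lapply(ent$role, draw_widths)
    exon_w <- lapply(spec, `[[`, "ex")
    intron_w <- lapply(seq_along(spec), function(i) {
      ne <- length(exon_w[[i]])
      if (ne < 2L) return(integer(0))
      rng <- spec[[i]]$intr
      sample(seq(rng[1], rng[2]), ne - 1L, replace = TRUE)
    })

    # flatten exon chains into one table
    n_ex <- lengths(exon_w)
    ex_start <- vector("list", nrow(ent))
    for (i in seq_len(nrow(ent))) {
      w <- exon_w[[i]]; iv <- intron_w[[i]]
      off <- cumsum(c(0L, utils::head(w, -1L) + iv))
      ex_start[[i]] <- ent$origin[i] + 3500L + off
    }
    flat <- data.frame(
      chrom = rep(ent$chrom, n_ex),
      start = unlist(ex_start),
      width = unlist(exon_w),
      strand = rep(ent$strand, n_ex),
      id = rep(ent$id, n_ex),
      role = rep(ent$role, n_ex),
      stringsAsFactors = FALSE
    )
    flat$end <- flat$start + flat$width - 1L

    is_gene <- flat$role == "gene"
    ref_exons <- .sim_gr(flat$chrom[is_gene], flat$start[is_gene],
                         flat$end[is_gene], chrs,
                         strand = flat$strand[is_gene],
                         transcript_id = flat$id[is_gene],
                         gene_id = sub("\\.t1$", "", flat$id[is_gene]),
                         biotype = "protein_coding")

    # CDS per gene: spliced interval [151, L-150] mapped to genomic
    cds_rows <- list()
    gene_rows <- which(ent$role == "gene")
    for (i in gene_rows) {
      w <- exon_w[[i]]; L <- sum(w)
      if (L <= 450L) next
      s <- ex_start[[i]]; e <- s + w - 1L
      g1 <- .spliced_pos(s, e, ent$strand[i], 151L)
      g2 <- .spliced_pos(s, e, ent$strand[i], L - 150L)
      lo <- min(g1, g2); hi <- max(g1, g2)
      cs <- pmax(s, lo); ce <- pmin(e, hi)
      keep <- cs <= ce
      cds_rows[[length(cds_rows) + 1L]] <- data.frame(
        chrom = ent$chrom[i], start = cs[keep], end = ce[keep],
        strand = ent$strand[i], id = ent$id[i], stringsAsFactors = FALSE)
    }
    cds_df <- do.call(rbind, cds_rows)
    ref_cds <- .sim_gr(cds_df$chrom, cds_df$start, cds_df$end, chrs,
                       strand = cds_df$strand, transcript_id = cds_df$id)
    reference <- gene_annotation(ref_exons, cds = ref_cds)

    # assembled = candidates, non-genic decoys, background, + genic decoys
    is_asm <- !is_gene
    asm_chrom <- flat$chrom[is_asm]; asm_start <- flat$start[is_asm]
    asm_end <- flat$end[is_asm]; asm_strand <- flat$strand[is_asm]
    asm_id <- flat$id[is_asm]
    # genic decoys overlap the first exon of a host reference gene
    host_rows <- sample(gene_rows, cfg$n_decoys_per_class)
    for (k in seq_along(host_rows)) {
      i <- host_rows[k]
      id <- sprintf("DEC_genic_%02d", k)
      s1 <- ex_start[[i]][1] + 50L
      asm_chrom <- c(asm_chrom, rep(ent$chrom[i], 2L))
      asm_start <- c(asm_start, s1, s1 + 600L)
      asm_end <- c(asm_end, s1 + 199L, s1 + 749L)
      asm_strand <- c(asm_strand, rep(sample(c("+", "-"), 1L), 2L))
      asm_id <- c(asm_id, rep(id, 2L))
    }
    assembled <- gene_annotation(.sim_gr(
      asm_chrom, asm_start, asm_end, chrs, strand = asm_strand,
      transcript_id = asm_id, gene_id = asm_id, biotype = "lincRNA"))

    truth <- data.frame(
      transcript_id = c(ent$id[ent$role != "gene"],
                        sprintf("DEC_genic_%02d",
                                seq_len(cfg$n_decoys_per_class))),
      stringsAsFactors = FALSE
    )
    role_of <- c(ent$role[ent$role != "gene"],
                 rep("genic", cfg$n_decoys_per_class))
    truth$role <- ifelse(role_of %in% c("candidate", "background"),
                         role_of, "decoy")
    truth$decoy_class <- ifelse(truth$role == "decoy", role_of, NA_character_)

    used <- nrow(ent)
    layout <- list(slots = slots, n_used = used, chrs = chrs,
                   free = slots[seq.int(used + 1L, nrow(slots)), ,
                                drop = FALSE])
    list(reference = reference, assembled = assembled,
         truth = truth, layout = layout)
  })
}

#' Generate negative-binomial transcript and exon count matrices
#'
#' Counts follow NB(mu, size = 1/dispersion). Planted candidates (and the
#' structural decoy classes, whose single violation must not be expression)
#' carry a planted |log2FC| between the leukemia-like and normal groups with
#' alternating direction, so total library mass stays balanced and CPM-scale
#' fold changes are not distorted by composition. `not_DE` decoys and
#' background transcripts have log2FC = 0; `low_expression` decoys a mean
#' far below the 0.5 RPKM gate in both groups. Exon-level counts are a
#' multinomial split of each transcript count over exon lengths, so
#' per-sample exon sums equal the transcript count exactly.
#'
#' @param cfg A [sim_config()].
#' @param assembled Assembled-transcript `gene_annotation`.
#' @param truth Truth table from [generate_reference()].
#' @return List: `counts` (transcripts x samples integer matrix),
#'   `exon_counts`, `exon_lengths` (named vector), `groups` (named character
#'   vector, `"AML"`/`"NBM"`), `truth` (with a `log2fc` column added).
#' @export
generate_counts <- function(cfg, assembled, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(assembled, "gene_annotation"))
  withr::with_seed(cfg$seed + 2L, {
    samples <- c(sprintf("AML_%02d", seq_len(cfg$n_aml)),
                 sprintf("NBM_%02d", seq_len(cfg$n_nbm)))
    groups <- setNames(rep(c("AML", "NBM"), c(cfg$n_aml, cfg$n_nbm)), samples)

    tx_ids <- truth$transcript_id
    lfc <- numeric(nrow(truth))
    plant <- truth$role == "candidate" |
      (truth$role == "decoy" &
         !truth$decoy_class %in% c("not_DE", "low_expression"))
    idx <- which(plant)
    mag <- round(stats::runif(length(idx), cfg$lfc_range[1],
                              cfg$lfc_range[2]), 3)
    sign <- rep(c(1, -1), length.out = length(idx))  # direction-balanced
    lfc[idx] <- sign * mag

    low <- truth$decoy_class %in% "low_expression"
    mu_nbm <- ifelse(low, cfg$low_expr_mu,
                     cfg$base_mu * ifelse(lfc < 0, 2^(-lfc), 1))
    mu_aml <- ifelse(low, cfg$low_expr_mu,
                     cfg$base_mu * ifelse(lfc > 0, 2^lfc, 1))

    n_tx <- length(tx_ids)
    counts <- matrix(0L, n_tx, length(samples),
                     dimnames = list(tx_ids, samples))
    size <- 1 / cfg$nb_dispersion
    for (j in seq_along(samples)) {
      mu <- if (groups[j] == "AML") mu_aml else mu_nbm
      counts[, j] <- stats::rnbinom(n_tx, mu = mu, size = size)
    }

    # exon-level split, conservative by construction
    exw <- BiocGenerics::width(assembled$exons_by_tx)
    exon_ids <- unlist(lapply(tx_ids, function(id)
      sprintf("%s:E%02d", id, seq_along(exw[[id]]))))
    exon_counts <- matrix(0L, length(exon_ids), length(samples),
                          dimnames = list(exon_ids, samples))
    row_off <- c(0L, cumsum(lengths(exw[tx_ids])))
    for (i in seq_along(tx_ids)) {
      w <- exw[[tx_ids[i]]]
      rows <- row_off[i] + seq_along(w)
      if (length(w) == 1L) {
        exon_counts[rows, ] <- counts[i, ]
      } else {
        pr <- w / sum(w)
        for (j in seq_along(samples)) {
          if (counts[i, j] > 0L) {
            exon_counts[rows, j] <- stats::rmultinom(1L, counts[i, j], pr)[, 1]
          }
        }
      }
    }
    exon_lengths <- setNames(unlist(exw[tx_ids], use.names = FALSE), exon_ids)

    truth$log2fc <- lfc
    list(counts = counts, exon_counts = exon_counts,
         exon_lengths = exon_lengths, groups = groups, truth = truth)
  })
}

#' Generate epigenomic support tracks, ChIRP replicates and chromatin states
#'
#' DNase and H3K4me3 peaks cover the TSS of every assembled transcript except
#' the `no_marks` decoys; background peaks sit in gene-free slots. ChIRP
#' consensus peaks are planted in reference-gene promoters, introns and
#' coding exons (at most one peak per gene, so the planted bound-gene set is
#' exactly recoverable) plus distal gene-free slots; the two replicates are
#' the consensus jittered by at most `chirp_jitter` bp plus replicate-private
#' noise peaks placed in mutually disjoint free slots. The chromatin-state
#' track partitions every chromosome.
#'
#' @param cfg A [sim_config()].
#' @param assembled,reference `gene_annotation`s from [generate_reference()].
#' @param truth Truth table (identifies `no_marks` decoys).
#' @param layout Slot layout from [generate_reference()].
#' @return List of `GRanges`: `dnase`, `h3k4me3`, `chirp_rep1`, `chirp_rep2`,
#'   `chirp_consensus` (with planted `category` and `gene_id`), `states`, and
#'   `chirp_genes` (character vector: the planted non-distal peak gene set).
#' @export
generate_tracks <- function(cfg, assembled, reference, truth, layout) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 3L, {
    chrs <- layout$chrs
    marked <- truth$transcript_id[!(truth$decoy_class %in% "no_marks")]
    tss_all <- tss(assembled)
    tpos <- BiocGenerics::start(tss_all)[match(marked, names(tss_all))]
    tchr <- as.character(GenomeInfoDb::seqnames(tss_all))[
      match(marked, names(tss_all))]

    mk_tss_peaks <- function() {
      hw <- cfg$peak_halfwidth
      left <- sample(seq(hw[1], hw[2]), length(tpos), replace = TRUE)
      right <- sample(seq(hw[1], hw[2]), length(tpos), replace = TRUE)
      .sim_gr(tchr, pmax(1L, tpos - left), tpos + right, chrs,
              score = round(stats::runif(length(tpos), 5, 50), 2))
    }
    free <- layout$free
    n_free <- nrow(free)
    need <- cfg$chirp_n_distal + 2L * cfg$chirp_n_noise
    if (need + 1L > n_free) {
      stop("not enough gene-free slots (", n_free,
           ") for distal/noise/background peaks (", need + 1L, ")")
    }
    slot_center <- function(rows, jitter, halfwidth = 150L) {
      p <- free$origin[rows] + cfg$slot_bp %/% 2L +
        sample(seq(-jitter, jitter), length(rows), replace = TRUE)
      .sim_gr(free$chrom[rows], p - halfwidth, p + halfwidth - 1L, chrs)
    }
    pool <- list(distal = seq_len(cfg$chirp_n_distal),
                 noise1 = cfg$chirp_n_distal + seq_len(cfg$chirp_n_noise),
                 noise2 = cfg$chirp_n_distal + cfg$chirp_n_noise +
                   seq_len(cfg$chirp_n_noise),
                 bg = seq.int(need + 1L, n_free))

    bg_peaks <- function() {
      gr <- slot_center(sample(pool$bg, min(30L, length(pool$bg))),
                        jitter = 2000L)
      gr$score <- round(stats::runif(length(gr), 2, 20), 2)
      gr
    }
    dnase <- GenomicRanges::sort(c(mk_tss_peaks(), bg_peaks()),
                                 ignore.strand = TRUE)
    h3k4me3 <- GenomicRanges::sort(c(mk_tss_peaks(), bg_peaks()),
                                   ignore.strand = TRUE)

    # --- ChIRP consensus: one peak per selected gene + distal peaks
    half <- cfg$chirp_peak_width %/% 2L
    ref_tss <- tss(reference)
    feats <- transcript_features(reference)
    promwin <- suppressWarnings(GenomicRanges::resize(
      ref_tss, width = 6001L, fix = "center"))

    introns <- feats$introns
    ok_intron <- BiocGenerics::width(introns) > cfg$chirp_peak_width + 200L &
      !suppressWarnings(IRanges::overlapsAny(introns, promwin,
                                             ignore.strand = TRUE))
    intron_tx_pool <- unique(introns$transcript_id[ok_intron])
    cexons <- feats$coding_exons
    cex_tx <- reference$cds$transcript_id
    ok_exon <- !suppressWarnings(IRanges::overlapsAny(cexons, promwin,
                                                      ignore.strand = TRUE))
    exon_tx_pool <- unique(cex_tx[ok_exon])

    all_tx <- names(ref_tss)
    pick_prom <- sample(all_tx, cfg$chirp_n_promoter)
    pick_intr <- sample(setdiff(intron_tx_pool, pick_prom), cfg$chirp_n_intron)
    pick_exon <- sample(setdiff(exon_tx_pool, c(pick_prom, pick_intr)),
                        cfg$chirp_n_exon)

    cons_chrom <- character(0); cons_center <- integer(0)
    cons_cat <- character(0); cons_gene <- character(0)
    add <- function(chrom, center, cat, gene) {
      cons_chrom <<- c(cons_chrom, chrom)
      cons_center <<- c(cons_center, as.integer(center))
      cons_cat <<- c(cons_cat, rep(cat, length(chrom)))
      cons_gene <<- c(cons_gene, gene)
    }
    add(as.character(GenomeInfoDb::seqnames(ref_tss[pick_prom])),
        BiocGenerics::start(ref_tss[pick_prom]) +
          sample(-1000:1000, length(pick_prom), replace = TRUE),
        "promoter", reference$tx[pick_prom, "gene_id"])
    first_ok_intron <- vapply(pick_intr, function(txid) {
      which(ok_intron & introns$transcript_id == txid)[1]
    }, integer(1))
    it <- introns[first_ok_intron]
    add(as.character(GenomeInfoDb::seqnames(it)),
        (BiocGenerics::start(it) + BiocGenerics::end(it)) %/% 2L,
        "intron", reference$tx[pick_intr, "gene_id"])
    first_ok_exon <- vapply(pick_exon, function(txid) {
      which(ok_exon & cex_tx == txid)[1]
    }, integer(1))
    cx <- cexons[first_ok_exon]
    add(as.character(GenomeInfoDb::seqnames(cx)),
        (BiocGenerics::start(cx) + BiocGenerics::end(cx)) %/% 2L,
        "exon", reference$tx[pick_exon, "gene_id"])
    distal <- slot_center(pool$distal, jitter = 500L)
    add(as.character(GenomeInfoDb::seqnames(distal)),
        (BiocGenerics::start(distal) + BiocGenerics::end(distal)) %/% 2L,
        "distal_intergenic", rep(NA_character_, length(distal)))

    consensus <- .sim_gr(cons_chrom, cons_center - half,
                         cons_center + half - 1L, chrs,
                         category = cons_cat, gene_id = cons_gene)
    consensus <- GenomicRanges::sort(consensus, ignore.strand = TRUE)
    names(consensus) <- sprintf("cons_%03d", seq_along(consensus))

    jitter_rep <- function(noise_rows) {
      sh <- sample(seq(-cfg$chirp_jitter, cfg$chirp_jitter),
                   length(consensus), replace = TRUE)
      rep_gr <- GenomicRanges::shift(GenomicRanges::granges(consensus), sh)
      names(rep_gr) <- NULL
      gr <- c(rep_gr, slot_center(noise_rows, jitter = 1500L))
      gr$score <- round(stats::runif(length(gr), 5, 100), 2)
      GenomicRanges::sort(gr, ignore.strand = TRUE)
    }
    chirp_rep1 <- jitter_rep(pool$noise1)
    chirp_rep2 <- jitter_rep(pool$noise2)

    # --- chromatin-state partition of each chromosome
    st_chrom <- character(0); st_start <- integer(0); st_end <- integer(0)
    for (chrom in chrs) {
      pos <- 1L
      while (pos <= cfg$chrom_length) {
        len <- max(1000L, round(stats::rexp(1L, 1 / cfg$state_seg_mean)))
        end <- min(pos + len - 1L, cfg$chrom_length)
        st_chrom <- c(st_chrom, chrom)
        st_start <- c(st_start, pos); st_end <- c(st_end, end)
        pos <- end + 1L
      }
    }
    states <- .sim_gr(st_chrom, st_start, st_end, chrs,
                      state = sample(cfg$state_names, length(st_chrom),
                                     replace = TRUE))

    list(dnase = dnase, h3k4me3 = h3k4me3,
         chirp_rep1 = chirp_rep1, chirp_rep2 = chirp_rep2,
         chirp_consensus = consensus, states = states,
         chirp_genes = sort(unique(cons_gene[!is.na(cons_gene)])))
  })
}

# closed-form area-based drug sensitivity score for exact 4PL parameters
# y(x) = bottom + (top-bottom) / (1 + 10^(hill*(x - log10(ic50)))), x = log10(c)
# (the (c/ic50)^hill parameterization; hill < 0 gives inhibition rising with
# dose)
.dss_closed_form <- function(bottom, top, ic50, hill, threshold = 10,
                             conc_min, conc_max) {
  x1 <- log10(conc_min); x2 <- log10(conc_max)
  a <- hill * log(10); m <- log10(ic50)
  log1pexp <- function(u) ifelse(u > 30, u, log1p(exp(u)))
  Fint <- function(x) x - log1pexp(a * (x - m)) / a  # antiderivative
  if (top <= bottom) return(0)
  fr <- (threshold - bottom) / (top - bottom)
  if (fr >= 1) return(0)                       # never reaches the threshold
  if (fr <= 0) { lo <- x1; hi <- x2 }          # always above the threshold
  else {
    xt <- m + log(1 / fr - 1) / a
    if (a > 0) { lo <- x1; hi <- min(x2, xt) } else {
      lo <- max(x1, xt); hi <- x2
    }
    if (lo >= hi) return(0)
  }
  area <- (bottom - threshold) * (hi - lo) +
    (top - bottom) * (Fint(hi) - Fint(lo))
  100 * max(0, area) / ((100 - threshold) * (x2 - x1))
}

#' Generate cohort metadata, survival records and dose-response plates
#'
#' Patient expression values (log2(CPM+1)) mix a point mass at zero with a
#' continuous positive component; mutation flags are enriched among
#' expressors so subgroup associations are testable. Overall-survival times
#' are exponential with hazard ratio `exp(survival_beta)` for the
#' above-median expression group (plus small age and NPM1 effects),
#' administratively censored, and a configurable fraction carries an
#' allo-HSCT transplant date for transplant censoring. Dose-response plates
#' are 4PL curves with Gaussian noise; one drug carries a planted
#' between-group sensitivity-score difference (`planted_sdss`), all others
#' none.
#'
#' @param cfg A [sim_config()].
#' @return List: `cohort` (per-patient table incl. survival columns),
#'   `plates` (long dose-response table), `drug_truth` (per drug/group true
#'   DSS from the closed-form area), `survival_beta`.
#' @export
generate_cohort_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 4L, {
    n <- cfg$n_patients
    expressed <- stats::runif(n) > cfg$nonexpressor_fraction
    expression <- ifelse(expressed,
                         round(stats::rgamma(n, shape = 1.6, scale = 1.3), 4),
                         0)
    high <- expression >= stats::median(expression)

    flag <- function(p_hi, p_lo) stats::runif(n) < ifelse(high, p_hi, p_lo)
    cohort <- data.frame(
      sample_id = sprintf("P%04d", seq_len(n)),
      expression = expression,
      NPM1 = flag(0.45, 0.20), IDH2_R140 = flag(0.18, 0.05),
      IDH2_R172 = flag(0.03, 0.03), FLT3_ITD = flag(0.30, 0.20),
      PML_RARA = flag(0.16, 0.0),
      # promyelocytic morphology concentrates among expressors
      FAB = ifelse(high,
                   sample(c("M1", "M2", "M3", "M4", "M5"), n, replace = TRUE,
                          prob = c(0.15, 0.2, 0.25, 0.2, 0.2)),
                   sample(c("M1", "M2", "M4", "M5"), n, replace = TRUE,
                          prob = c(0.28, 0.3, 0.25, 0.17))),
      risk_group = sample(c("favorable", "intermediate", "adverse"), n,
                          replace = TRUE, prob = c(0.3, 0.5, 0.2)),
      age = round(stats::rnorm(n, 60, 10), 1),
      stringsAsFactors = FALSE
    )
    lambda0 <- log(2) / 600
    lp <- cfg$survival_beta * high + 0.3 * (cohort$age - 60) / 10 -
      0.2 * cohort$NPM1
    t_event <- stats::rexp(n, rate = lambda0 * exp(lp))
    t_admin <- stats::runif(n, 100, 2500)
    cohort$os_days <- round(pmin(t_event, t_admin), 1)
    cohort$os_event <- t_event <= t_admin
    cohort$transplant_days <- ifelse(
      stats::runif(n) < cfg$transplant_fraction,
      round(stats::runif(n, 30, 800), 1), NA_real_)

    # --- dose-response plates
    concs <- cfg$conc_max_uM /
      10^(cfg$dose_step_log10 * (seq_len(cfg$n_doses) - 1L))
    cmin <- min(concs); cmax <- max(concs)
    plates <- list(); drug_truth <- list()
    for (d in seq_along(cfg$drugs)) {
      drug <- cfg$drugs[d]
      top <- stats::runif(1, 55, 95)
      ic50_wt <- 10^stats::runif(1, log10(cmin) + 0.8, log10(cmax) - 0.8)
      hill <- -stats::runif(1, 0.9, 1.8)  # inhibition rises with dose
      par_wt <- list(bottom = 0, top = top, ic50 = ic50_wt, hill = hill)
      par_ko <- par_wt
      if (d == 1L) {
        # solve the KO ic50 giving the planted DSS difference
        obj <- function(lic) {
          .dss_closed_form(0, top, 10^lic, hill, cfg$dss_threshold,
                           cmin, cmax) -
            .dss_closed_form(0, top, ic50_wt, hill, cfg$dss_threshold,
                             cmin, cmax) - cfg$planted_sdss
        }
        sol <- stats::uniroot(obj, lower = log10(cmin) - 3,
                              upper = log10(ic50_wt), tol = 1e-10)
        par_ko$ic50 <- 10^sol$root
      }
      for (grp in c("KO", "WT")) {
        par <- if (grp == "KO") par_ko else par_wt
        truey <- par$bottom + (par$top - par$bottom) /
          (1 + (concs / par$ic50)^par$hill)
        for (r in seq_len(cfg$n_drug_replicates)) {
          plates[[length(plates) + 1L]] <- data.frame(
            drug = drug, group = grp, conc_uM = concs,
            response = round(truey + stats::rnorm(length(concs), 0,
                                                  cfg$drug_noise_sd), 3),
            replicate = r, stringsAsFactors = FALSE)
        }
        drug_truth[[length(drug_truth) + 1L]] <- data.frame(
          drug = drug, group = grp,
          dss_true = .dss_closed_form(par$bottom, par$top, par$ic50,
                                      par$hill, cfg$dss_threshold,
                                      cmin, cmax),
          stringsAsFactors = FALSE)
      }
    }
    list(cohort = cohort, plates = do.call(rbind, plates),
         drug_truth = do.call(rbind, drug_truth),
         survival_beta = cfg$survival_beta)
  })
}

#' Lean survival simulator for calibration studies
#'
#' Exponential event times with log hazard ratio `beta` for a balanced binary
#' expression group, independent administrative censoring. Used for
#' null-calibration and CI-coverage replicates without regenerating a full
#' cohort.
#'
#' @param n Number of subjects.
#' @param beta Log hazard ratio of the high-expression group.
#' @param seed Optional seed.
#' @return data.frame with `time`, `event`, `group` (0/1), `age`.
#' @export
simulate_survival <- function(n, beta = log(0.63), seed = NULL) {
  run <- function() {
    group <- rep(0:1, length.out = n)
    age <- stats::rnorm(n, 60, 10)
    lambda0 <- log(2) / 600
    t_event <- stats::rexp(n, rate = lambda0 * exp(beta * group +
                                                     0.3 * (age - 60) / 10))
    t_admin <- stats::runif(n, 100, 2500)
    data.frame(time = pmin(t_event, t_admin), event = t_event <= t_admin,
               group = group, age = age)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a count matrix with optionally planted fold changes
#'
#' Two equal groups, NB counts; the first `n_de` features get fold change
#' `fc` in group A. Used for differential-expression calibration and power
#' studies.
#'
#' @param n_features,n_per_group Problem size.
#' @param n_de Number of planted differential features.
#' @param fc Linear fold change of planted features (group A over B).
#' @param mu Baseline NB mean.
#' @param dispersion NB dispersion.
#' @param seed Optional seed.
#' @return List: `counts`, `groups`, `de_features`.
#' @export
simulate_de_matrix <- function(n_features, n_per_group, n_de = 0L, fc = 4,
                               mu = 200, dispersion = 0.1, seed = NULL) {
  run <- function() {
    samples <- c(sprintf("A_%02d", seq_len(n_per_group)),
                 sprintf("B_%02d", seq_len(n_per_group)))
    groups <- setNames(rep(c("A", "B"), each = n_per_group), samples)
    mu_a <- rep(mu, n_features); mu_a[seq_len(n_de)] <- mu * fc
    counts <- matrix(0L, n_features, 2L * n_per_group,
                     dimnames = list(sprintf("f%05d", seq_len(n_features)),
                                     samples))
    for (j in seq_along(samples)) {
      counts[, j] <- stats::rnbinom(n_features,
                                    mu = if (groups[j] == "A") mu_a else mu,
                                    size = 1 / dispersion)
    }
    list(counts = counts, groups = groups,
         de_features = rownames(counts)[seq_len(n_de)])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate exon-level counts for isoform-usage analysis
#'
#' Emulates a cohort where a transcript is initiated from three alternative
#' start exons and terminated at two alternative end exons with fixed mixture
#' weights; per-exon counts are Poisson with intensity proportional to
#' (sample depth) x (mixture weight) x (exon length), so length-normalized
#' usage shares recover the mixture.
#'
#' @param cfg A [sim_config()].
#' @return List: `exon_counts` (exons x samples), `exon_info` (exon_id,
#'   length, set), `start_mixture`, `term_mixture`.
#' @export
generate_isoform_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 5L, {
    info <- data.frame(
      exon_id = c(names(cfg$iso_start_mixture), names(cfg$iso_term_mixture)),
      length = c(300L, 250L, 350L, 400L, 500L),
      set = rep(c("start", "termination"),
                c(length(cfg$iso_start_mixture),
                  length(cfg$iso_term_mixture))),
      stringsAsFactors = FALSE
    )
    n <- cfg$iso_n_samples
    samples <- sprintf("S%03d", seq_len(n))
    depth <- stats::rlnorm(n, log(cfg$iso_depth), 0.4)
    w <- c(cfg$iso_start_mixture, cfg$iso_term_mixture)
    lam <- outer(w * info$length / 1000, depth)
    counts <- matrix(stats::rpois(length(lam), lam), nrow(info), n,
                     dimnames = list(info$exon_id, samples))
    list(exon_counts = counts, exon_info = info,
         start_mixture = cfg$iso_start_mixture,
         term_mixture = cfg$iso_term_mixture)
  })
}

#' Run every generator and assemble the truth manifest
#'
#' @param cfg A [sim_config()].
#' @return List with `reference`, `assembled`, `counts`, `exon_counts`,
#'   `exon_lengths`, `groups`, `tracks`, `cohort`, `plates`, `isoform`, and
#'   `truth` (the manifest: seed, per-transcript roles and planted log2FC,
#'   survival beta, true DSS table, planted ChIRP gene set and mixtures).
#' @export
simulate_study <- function(cfg = sim_config()) {
  ref <- generate_reference(cfg)
  cnt <- generate_counts(cfg, ref$assembled, ref$truth)
  trk <- generate_tracks(cfg, ref$assembled, ref$reference, ref$truth,
                         ref$layout)
  coh <- generate_cohort_metadata(cfg)
  iso <- generate_isoform_counts(cfg)
  truth <- list(
    seed = cfg$seed,
    transcripts = cnt$truth,
    planted_candidates = cnt$truth$transcript_id[cnt$truth$role == "candidate"],
    survival_beta = coh$survival_beta,
    drug_dss = coh$drug_truth,
    chirp_genes = trk$chirp_genes,
    chirp_consensus_n = length(trk$chirp_consensus),
    start_mixture = iso$start_mixture,
    term_mixture = iso$term_mixture
  )
  list(reference = ref$reference, assembled = ref$assembled,
       counts = cnt$counts, exon_counts = cnt$exon_counts,
       exon_lengths = cnt$exon_lengths, groups = cnt$groups,
       tracks = trk, cohort = coh$cohort, plates = coh$plates,
       isoform = iso, truth = truth)
}

#' Write a simulated study to disk in standard formats
#'
#' GTF for annotations, narrowPeak for peak tracks, BED for the state
#' partition, TSV (header row) for all tables, JSON for the truth manifest.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_annotation(sim$reference, p("reference.gtf"))
  write_annotation(sim$assembled, p("assembled.gtf"))
  wt <- function(x, f, rn = "feature_id") {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- rn
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(sim$counts, "counts.tsv")
  wt(sim$exon_counts, "exon_counts.tsv")
  utils::write.table(
    data.frame(sample_id = names(sim$groups), group = sim$groups),
    p("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_peaks(sim$tracks$dnase, p("dnase.narrowPeak"), "narrowPeak")
  write_peaks(sim$tracks$h3k4me3, p("h3k4me3.narrowPeak"), "narrowPeak")
  write_peaks(sim$tracks$chirp_rep1, p("chirp_rep1.narrowPeak"), "narrowPeak")
  write_peaks(sim$tracks$chirp_rep2, p("chirp_rep2.narrowPeak"), "narrowPeak")
  write_states(sim$tracks$states, p("states.bed"))
  utils::write.table(sim$cohort, p("cohort.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$plates, p("plates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wt(sim$isoform$exon_counts, "isoform_exon_counts.tsv", rn = "exon_id")
  utils::write.table(sim$isoform$exon_info, p("exon_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
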