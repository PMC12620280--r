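test_that("replicate consensus: identity, disjointness, idempotence", {
  pk <- sort(gr("chr1", c(100, 500, 900), c(199, 650, 980)),
             ignore.strand = TRUE)
  expect_equal(granges(replicate_consensus(pk, pk)),
               granges(reduce(pk, ignore.strand = TRUE)))
  far <- gr("chr2", c(100, 500), c(150, 550))
  expect_length(replicate_consensus(pk, far), 0L)
  expect_length(replicate_consensus(pk, GRanges()), 0L)
  # min_overlap_bp is respected
  a <- gr("chr1", 100, 199)
  b <- gr("chr1", 190, 300)  # 10 bp shared
  expect_length(replicate_consensus(a, b, min_overlap_bp = 10), 1L)
  expect_length(replicate_consensus(a, b, min_overlap_bp = 11), 0L)
  # intersection merge trims to the shared interval
  got <- replicate_consensus(a, b, merge = "intersection")
  expect_equal(c(start(got), end(got)), c(190L, 199L))
  got_u <- replicate_consensus(a, b, merge = "union")
  expect_equal(c(start(got_u), end(got_u)), c(100L, 300L))
})

test_that("replicate consensus equals the all-pairs brute-force scan", {
  set.seed(13)
  for (rep in 1:20) {
    r1 <- random_peaks(40)
    r2 <- random_peaks(40)
    got <- replicate_consensus(r1, r2, merge = "union")
    want <- brute_consensus(r1, r2)
    expect_equal(as.character(seqnames(got)), as.character(seqnames(want)))
    expect_equal(start(got), start(want))
    expect_equal(end(got), end(want))
  }
})

test_that("peak annotation assigns the documented categories", {
  ref <- toy_reference()
  # gA: TSS 1000 (+). 1 kb upstream of the TSS -> promoter
  p_prom <- gr("chr1", 1, 100)  # within 3 kb of TSS 1000
  # strictly inside gA's second intron (2400..2999), > 3 kb impossible here,
  # so use gB: TSS 12799 (-), intron 10500..11999; promoter window
  # [9799, 15799] covers it -- build a far-intron case on a bigger gene
  big <- gene_annotation(
    gr("chr1", c(100000, 120000), c(100499, 120999), "+",
       transcript_id = "gBig.t1", gene_id = "gBig"))
  ann_big <- annotate_peaks(gr("chr1", 110000, 110300), big)
  expect_equal(as.character(ann_big$category), "intron")
  expect_equal(ann_big$nearest_gene, "gBig")
  got <- annotate_peaks(p_prom, ref)
  expect_equal(as.character(got$category), "promoter")
  # far from everything -> distal
  distal <- annotate_peaks(gr("chr1", 80000, 80200), ref)
  expect_equal(as.character(distal$category), "distal_intergenic")
  # downstream: just past gBig's TES (120999), outside the 3 kb TSS windows
  down <- annotate_peaks(gr("chr1", 123500, 123600), big)
  expect_equal(as.character(down$category), "downstream")
  # UTR precedence needs a gene long enough that its 3'UTR escapes every
  # promoter window
  long_gene <- gene_annotation(
    gr("chr1", c(100000, 110000), c(100499, 110999), "+",
       transcript_id = "gL.t1", gene_id = "gL"),
    cds = gr("chr1", c(100150, 110000), c(100499, 110799), "+",
             transcript_id = "gL.t1"))
  utr3 <- annotate_peaks(gr("chr1", 110850, 110900), long_gene)
  expect_equal(as.character(utr3$category), "three_utr")
  # signed TSS distance: downstream of a minus-strand TSS is negative coords
  d <- annotate_peaks(gr("chr1", 12700, 12720), ref)  # gB TSS 12799 (-)
  expect_equal(d$nearest_gene, "gB")
  expect_gt(d$distance_to_tss, 0)  # mid 12710 is downstream in tx direction
})

test_that("peak annotation partitions and matches the brute-force classifier", {
  set.seed(17)
  for (rep in 1:8) {
    ann <- random_annotation(12, genome_bp = 1e5)
    peaks <- random_peaks(25, genome_bp = 1.1e5)
    got <- annotate_peaks(peaks, ann)
    expect_equal(nrow(got), length(peaks))
    expect_equal(sum(table(got$category)), length(peaks))  # partition
    want <- brute_annotate(peaks, ann)
    expect_equal(as.character(got$category), want)
  }
  # with CDS-bearing annotation too
  ref <- toy_reference()
  peaks <- random_peaks(60, chroms = c("chr1", "chr2"), genome_bp = 2e4)
  got <- annotate_peaks(peaks, ref)
  want <- brute_annotate(peaks, ref)
  expect_equal(as.character(got$category), want)
})

test_that("state enrichment: analytic fallback and planted enrichment", {
  states <- c(gr("chr1", 1, 10000, state = "hot"),
              gr("chr1", 10001, 100000, state = "cold"))
  # all peaks in the 10% state
  pk <- gr("chr1", seq(500, 9000, by = 500), seq(500, 9000, by = 500) + 99)
  tab0 <- state_enrichment(pk, states, n_shuffles = 0)
  hot <- tab0[tab0$state == "hot", ]
  expect_equal(hot$expected, length(pk) * 0.1)
  expect_equal(hot$fold, 10)
  expect_true(is.na(hot$p))
  tab <- state_enrichment(pk, states, n_shuffles = 400, seed = 2)
  expect_equal(tab[tab$state == "hot", "fold"], 10, tolerance = 0.15)
  expect_lt(tab[tab$state == "hot", "p"], 0.02)
  # uniformly placed peaks show fold ~ 1 everywhere
  set.seed(31)
  upos <- sample(1:100000, 300)
  u <- state_enrichment(gr("chr1", upos, upos + 50), states,
                        n_shuffles = 300, seed = 3)
  expect_equal(u$fold, c(1, 1), tolerance = 0.2)
  # non-partition input errors
  gap <- c(gr("chr1", 1, 500, state = "a"), gr("chr1", 700, 1000, state = "b"))
  expect_error(state_enrichment(pk, gap, 0), "partition")
})

test_that("peaks_to_genes collapses non-distal peaks per gene", {
  annots <- data.frame(
    category = factor(c("promoter", "intron", "distal_intergenic", "exon"),
                      levels = levels(annotate_peaks(GRanges(),
                                                     toy_reference())$category)),
    nearest_gene = c("g1", "g1", "g2", "g3"))
  expect_equal(peaks_to_genes(annots), c("g1", "g3"))
  expect_equal(peaks_to_genes(annots, include_distal = TRUE),
               c("g1", "g2", "g3"))
  expect_length(peaks_to_genes(annots[0, ]), 0L)
})

test_that("hypergeometric overlap matches exhaustive combinatorics", {
  # N=10, |a|=|b|=3, k=3 -> 1/C(10,3)
  res <- set_overlap_test(letters[1:3], letters[1:3], universe_n = 10)
  expect_equal(res$p, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(res$jaccard, 1)
  # k=0 -> p=1
  expect_equal(set_overlap_test(letters[1:3], letters[4:6], 20)$p, 1)
  # all N <= 15, all (n_a, n_b, k): agreement with direct summation
  for (N in c(5, 9, 15)) {
    ids <- sprintf("m%02d", seq_len(N))
    for (n_a in 1:N) for (n_b in 1:N) {
      for (k in 0:min(n_a, n_b)) {
        if (k < n_a + n_b - N) next  # infeasible overlap for fixed margins
        a <- ids[seq_len(n_a)]
        b <- c(ids[seq_len(k)], rev(ids)[seq_len(n_b - k)])
        res <- set_overlap_test(a, b, N)
        expect_equal(res$k, k)
        expect_equal(res$p, hyper_tail(k, n_a, n_b, N), tolerance = 1e-10)
      }
    }
  }
  expect_error(set_overlap_test(letters[1:5], letters[1:2], 4), "universe")
})

test_that("overlap p is monotone decreasing in k at fixed margins", {
  N <- 40; n_a <- 12; n_b <- 9
  ids <- sprintf("g%02d", seq_len(N))
  p_seq <- vapply(0:n_b, function(k) {
    a <- ids[seq_len(n_a)]
    b <- c(ids[seq_len(k)], rev(ids)[seq_len(n_b - k)])
    set_overlap_test(a, b, N)$p
  }, numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("three-way overlap counts the seven regions", {
  counts <- three_way_overlap(c("a", "b", "c", "d"),
                              c("c", "d", "e"),
                              c("d", "e", "f"))
  expect_equal(unname(counts[c("a_only", "ab_only", "abc", "bc_only",
                               "c_only")]),
               c(2L, 1L, 1L, 1L, 1L))
  expect_equal(sum(counts), length(unique(c("a", "b", "c", "d", "e", "f"))))
})
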