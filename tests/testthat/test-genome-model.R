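test_that("annotation round-trips through GTF with exact exon chains", {
  ann <- toy_reference()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_setequal(back$tx$transcript_id, ann$tx$transcript_id)
  for (id in ann$tx$transcript_id) {
    a <- ann$exons_by_tx[[id]]; b <- back$exons_by_tx[[id]]
    expect_equal(start(b), start(a))
    expect_equal(end(b), end(a))
    expect_equal(as.character(strand(b)), as.character(strand(a)))
  }
  # CDS preserved too
  expect_equal(sort(start(back$cds)), sort(start(ann$cds)))
})

test_that("GTF dialect conversion: a 1..100 exon line loads as width-100", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\texon\t1\t100\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1";'), path)
  ann <- read_annotation(path)
  expect_equal(start(ann$exons), 1L)
  expect_equal(end(ann$exons), 100L)
  expect_equal(width(ann$exons), 100L)
})

test_that("TSS/TES follow the strand convention", {
  ex <- gr("chr1", c(100, 500), c(200, 700), "+",
           transcript_id = "p", gene_id = "p")
  ex2 <- gr("chr1", c(100, 500), c(200, 700), "-",
            transcript_id = "m", gene_id = "m")
  ann <- gene_annotation(c(ex, ex2))
  expect_equal(start(tss(ann)["p"]), 100L)
  expect_equal(start(tes(ann)["p"]), 700L)
  expect_equal(start(tss(ann)["m"]), 700L)
  expect_equal(start(tes(ann)["m"]), 100L)
  expect_equal(unname(spliced_length(ann)), c(302L, 302L))
})

test_that("annotation constructor validates exon chains", {
  bad <- gr("chr1", c(100, 150), c(200, 260), "+",
            transcript_id = "t", gene_id = "t")  # overlapping exons
  expect_error(gene_annotation(bad), "overlapping")
  two_chrom <- c(gr("chr1", 1, 10, "+", transcript_id = "t", gene_id = "t"),
                 gr("chr2", 1, 10, "+", transcript_id = "t", gene_id = "t"))
  expect_error(gene_annotation(two_chrom), "multiple chromosomes")
  expect_error(gene_annotation(gr("chr1", 1, 10)), "transcript_id")
})

test_that("BED and narrowPeak peak files load with the right coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tp1\t5\t.", bed)
  pk <- read_peaks(bed)
  expect_equal(start(pk), 11L)  # 0-based half-open -> 1-based closed
  expect_equal(end(pk), 20L)
  expect_equal(width(pk), 10L)
  expect_equal(pk$score, 5)

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t10\t20\tp1\t0\t.\t7.5\t-1\t-1\t-1",
               "chr1\t100\t250\tp2\t0\t.\t3.25\t-1\t-1\t-1"), np)
  pk2 <- read_peaks(np)
  expect_equal(pk2$score, c(7.5, 3.25))  # score from column 7
  expect_equal(start(pk2), c(11L, 101L))

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_length(read_peaks(empty), 0L)
})

test_that("narrowPeak writer round-trips coordinates and scores", {
  pk <- sort(gr("chr1", c(11, 101), c(20, 250)), ignore.strand = TRUE)
  pk$score <- c(2.5, 9)
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(pk, path, "narrowPeak")
  back <- read_peaks(path)
  expect_equal(start(back), start(pk))
  expect_equal(end(back), end(pk))
  expect_equal(back$score, pk$score)
})

test_that("interval_overlaps agrees with interval arithmetic on random pairs", {
  set.seed(42)
  n <- 1000
  a <- gr(sample(c("chr1", "chr2"), n, TRUE),
          s <- sample(1:5000, n, TRUE), s + sample(1:400, n, TRUE))
  b <- gr(sample(c("chr1", "chr2"), n, TRUE),
          s2 <- sample(1:5000, n, TRUE), s2 + sample(1:400, n, TRUE))
  for (min_bp in c(1L, 25L)) {
    expected <- as.character(seqnames(a)) == as.character(seqnames(b)) &
      (pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L) >= min_bp
    expect_equal(interval_overlaps(a, b, min_bp = min_bp), expected)
  }
  # half-open abutment in 0-based terms = adjacency in 1-based closed terms
  expect_false(interval_overlaps(gr("chr1", 11, 20), gr("chr1", 21, 30)))
  expect_true(interval_overlaps(gr("chr1", 11, 20), gr("chr1", 20, 30)))
})

test_that("classify_location matches the all-pairs brute-force scan", {
  set.seed(7)
  for (rep in 1:5) {
    qry <- random_annotation(30)
    ref <- random_annotation(20)
    for (mode in c("gene_span", "exonic")) {
      got <- classify_location(qry, ref, mode = mode)
      want <- brute_classify(qry, ref, mode = mode)
      expect_equal(got[names(want)], want)
    }
  }
})

test_that("classify_location handles span vs exonic mode and edge cases", {
  ref <- toy_reference()
  # inside gA's intron: genic by span, intergenic by exonic test
  t_intron <- gene_annotation(gr("chr1", 1300, 1600, "+",
                                 transcript_id = "ti", gene_id = "ti"))
  expect_equal(unname(classify_location(t_intron, ref, "gene_span")),
               "genic_overlap")
  expect_equal(unname(classify_location(t_intron, ref, "exonic")),
               "intergenic")
  # 1 bp overlap with an exon is genic
  t_edge <- gene_annotation(gr("chr1", 900, 1000, "+",
                               transcript_id = "te", gene_id = "te"))
  expect_equal(unname(classify_location(t_edge, ref, "exonic")),
               "genic_overlap")
  # far away -> intergenic; unknown chromosome warns and is intergenic
  t_far <- gene_annotation(gr("chr1", 50000, 50500, "+",
                              transcript_id = "tf", gene_id = "tf"))
  expect_equal(unname(classify_location(t_far, ref)), "intergenic")
  t_chr <- gene_annotation(gr("chrX", 100, 400, "+",
                              transcript_id = "tx", gene_id = "tx"))
  expect_warning(loc <- classify_location(t_chr, ref), "absent")
  expect_equal(unname(loc), "intergenic")
})

test_that("classify_location is monotone under annotation growth", {
  set.seed(11)
  qry <- random_annotation(25)
  ref_small <- random_annotation(8)
  # grow the reference by adding genes
  extra <- random_annotation(12)
  extra$exons$transcript_id <- paste0("x_", extra$exons$transcript_id)
  extra$exons$gene_id <- paste0("x_", extra$exons$gene_id)
  ref_big <- gene_annotation(c(ref_small$exons, extra$exons))
  small <- classify_location(qry, ref_small)
  big <- classify_location(qry, ref_big)
  flipped_back <- names(small)[small == "genic_overlap" &
                                 big[names(small)] == "intergenic"]
  expect_length(flipped_back, 0L)
})

test_that("transcript_features partitions exons into CDS and UTRs", {
  ann <- toy_reference()
  f <- transcript_features(ann)
  # gA (+): 5'UTR 1000..1149, 3'UTR 3250..3499
  u5 <- f$five_utr[f$five_utr$transcript_id == "gA.t1"]
  expect_equal(c(start(u5), end(u5)), c(1000L, 1149L))
  u3 <- f$three_utr[f$three_utr$transcript_id == "gA.t1"]
  expect_equal(c(start(u3), end(u3)), c(3250L, 3499L))
  # gB (-): 5'UTR is the high-coordinate side
  u5b <- f$five_utr[f$five_utr$transcript_id == "gB.t1"]
  expect_equal(c(start(u5b), end(u5b)), c(12600L, 12799L))
  # non-coding transcript exons land in noncoding_exons
  expect_equal(sum(width(f$noncoding_exons)), 300L + 400L)
  # introns: gA has two
  ia <- f$introns[f$introns$transcript_id == "gA.t1"]
  expect_equal(start(ia), c(1200L, 2400L))
  expect_equal(end(ia), c(1999L, 2999L))
})
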