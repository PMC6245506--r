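# Metric engine: FASTA parsing, the sequence/mapping/annotation/ortholog
# calculators, and the merged fifteen-parameter vector.

test_that("FASTA parsing concatenates wrapped lines and rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), fa)
  a <- read_assembly_fasta(fa, "one")
  expect_equal(unname(a$contigs["a"]), "ACGT")

  writeLines(c(">a desc", "AC", "GT", ">b", "NNA"), fa)
  a <- read_assembly_fasta(fa, "two")
  expect_equal(nchar(a$contigs), c(a = 4L, b = 3L))

  writeLines(c(">a", "AC", ">a", "GT"), fa)
  expect_error(read_assembly_fasta(fa), "a")

  writeLines(character(0), fa)
  expect_error(read_assembly_fasta(fa), "empty")
})

test_that("sequence metrics match hand-derived values", {
  lens <- c(5, 4, 3, 2, 1)
  seqs <- vapply(lens, function(L) strrep("A", L), "")
  names(seqs) <- paste0("c", seq_along(lens))
  sm <- sequence_metrics(assembly_record("x", seqs))
  expect_equal(sm$AllTransSize, 15)
  expect_equal(sm$N50, 4)   # cumsum 5,9 >= 7.5
  expect_equal(sm$N90, 2)   # cumsum reaches 14 >= 13.5
  expect_equal(sm$Ns, 0)
  expect_equal(sm$MeanGapLen, 0)

  one <- sequence_metrics(assembly_record("y", c(c1 = strrep("G", 100))))
  expect_equal(one$N50, 100)
  expect_equal(one$N90, 100)
  expect_equal(one$MeanContigLenAll, 100)

  gap <- sequence_metrics(assembly_record("z", c(c1 = "ACNNNGGNA")))
  expect_equal(gap$Ns, 4)            # runs NNN and N
  expect_equal(gap$MeanGapLen, 2.0)
})

test_that("sequence metrics agree with brute-force oracles on random assemblies", {
  set.seed(20240915)
  for (i in seq_len(1000)) {
    a <- random_assembly(sprintf("r%04d", i))
    sm <- sequence_metrics(a)
    lens <- nchar(a$contigs)
    expect_identical(sm$AllTransSize, sum(lens))
    expect_identical(sm$N50, oracle_nx(lens, 0.5))
    expect_identical(sm$N90, oracle_nx(lens, 0.9))
    ns <- oracle_nstats(a$contigs)
    expect_identical(sm$Ns, ns$ns)
    expect_equal(sm$MeanGapLen, if (ns$runs == 0) 0 else ns$ns / ns$runs)
    expect_gte(sm$N50, sm$N90)
    expect_true(all(c(sm$N50, sm$N90) %in% lens))
  }
})

test_that("splitting a contig never increases N50", {
  set.seed(7)
  for (i in 1:200) {
    a <- random_assembly(sprintf("s%03d", i), n_min = 2)
    n50 <- sequence_metrics(a)$N50
    seqs <- a$contigs
    # split a random contig with length >= 2 into two pieces
    cand <- which(nchar(seqs) >= 2)
    j <- sample(cand, 1)
    s <- seqs[[j]]
    cut <- sample(nchar(s) - 1, 1)
    seqs <- c(seqs[-j],
              setNames(c(substr(s, 1, cut), substr(s, cut + 1, nchar(s))),
                       paste0(names(seqs)[j], c("_1", "_2"))))
    n50_split <- sequence_metrics(assembly_record("split", seqs))$N50
    expect_lte(n50_split, n50)
  }
})

test_that("MeanGapLen is exactly 1 iff every N is isolated", {
  a <- assembly_record("iso", c(c1 = "ANAANA", c2 = "NAC"))
  expect_equal(sequence_metrics(a)$MeanGapLen, 1)
  b <- assembly_record("run", c(c1 = "ANNAA"))
  expect_gt(sequence_metrics(b)$MeanGapLen, 1)
})

test_that("mapping metrics follow the pair/single counting rules", {
  asm <- assembly_record("m", c(A = strrep("A", 600), B = strrep("C", 400),
                                C = strrep("G", 700)))
  aln <- data.frame(contig_id = c("A", "B"),
                    mapped_reads = c(2, 3), mapped_pairs = c(1, 0),
                    covered_bases = c(300, 200))
  mm <- mapping_metrics(asm, aln, read_mode = "paired")
  expect_equal(mm$Contigs, 1)
  expect_equal(mm$Contigs500, 1)
  expect_equal(mm$MeanContigCov, 100 * (300 / 600 + 200 / 400 + 0) / 3)
  expect_equal(mm$MeanContigLenUseful, 600)

  ms <- mapping_metrics(asm, aln, read_mode = "single")
  expect_equal(ms$Contigs, 2)
  expect_equal(ms$MeanContigLenUseful, 500)

  empty <- aln[0, ]
  me <- mapping_metrics(asm, empty, read_mode = "paired")
  expect_equal(me$Contigs, 0)
  expect_equal(me$Contigs500, 0)
  expect_equal(me$MeanContigCov, 0)

  # useful-denominator variant averages over counted contigs only
  mu <- mapping_metrics(asm, aln, read_mode = "single",
                        cov_denominator = "useful")
  expect_equal(mu$MeanContigCov, 100 * (300 / 600 + 200 / 400) / 2)

  expect_error(mapping_metrics(asm, aln), "read_mode")
  bad <- data.frame(contig_id = "Z", mapped_reads = 1, mapped_pairs = 1,
                    covered_bases = 5)
  expect_error(mapping_metrics(asm, bad, read_mode = "paired"), "Z")
})

test_that("Contigs500 uses a strict 500 nt threshold", {
  asm <- assembly_record("t", c(A = strrep("A", 500), B = strrep("C", 501)))
  aln <- data.frame(contig_id = c("A", "B"), mapped_reads = c(2, 2),
                    mapped_pairs = c(1, 1), covered_bases = c(10, 10))
  mm <- mapping_metrics(asm, aln, read_mode = "paired")
  expect_equal(mm$Contigs, 2)
  expect_equal(mm$Contigs500, 1)
})

test_that("annotation metrics count distinct proteins and two-strand contigs", {
  hits <- data.frame(
    contig_id = c("c1", "c2", "c3", "c3"),
    protein_id = c("P1", "P1", "P2", "P2"),
    strand = c("+", "-", "+", "-"),
    completeness = c("complete", "partial", "partial", "partial"))
  am <- annotation_metrics(hits)
  expect_equal(am$DiffProts, 2)
  expect_equal(am$DiffComplProts, 1)
  expect_equal(am$MissAssembl, 100 / 3)

  empty <- hits[0, ]
  ae <- annotation_metrics(empty)
  expect_equal(unlist(ae), c(DiffProts = 0, DiffComplProts = 0,
                             MissAssembl = 0))

  n <- 7
  single <- data.frame(contig_id = paste0("c", 1:n),
                       protein_id = paste0("P", 1:n), strand = "+",
                       completeness = "complete")
  as_ <- annotation_metrics(single)
  expect_equal(as_$DiffProts, n)
  expect_equal(as_$DiffComplProts, n)
  expect_equal(as_$MissAssembl, 0)

  bad <- transform(hits, strand = c("+", "*", "+", "-"))
  expect_error(annotation_metrics(bad), "strand")
})

test_that("ortholog metrics are percentages over all groups", {
  tab <- data.frame(
    ortholog_group_id = paste0("OG", 1:10),
    status = c(rep("complete_single", 5), rep("duplicated", 2),
               rep("fragmented", 2), "missing"))
  om <- ortholog_metrics(tab)
  expect_equal(unlist(om), c(ComplOrtho = 50, FragOrtho = 20,
                             DuplOrtho = 20))

  allc <- data.frame(ortholog_group_id = paste0("OG", 1:4),
                     status = "complete_single")
  expect_equal(ortholog_metrics(allc)$ComplOrtho, 100)

  allm <- data.frame(ortholog_group_id = paste0("OG", 1:4),
                     status = "missing")
  expect_equal(unlist(ortholog_metrics(allm)),
               c(ComplOrtho = 0, FragOrtho = 0, DuplOrtho = 0))

  expect_error(ortholog_metrics(tab[0, ]), "empty")
})

test_that("build_metric_vector flags missing evidence and merges blocks", {
  a <- random_assembly("bm")
  mv <- build_metric_vector(a)
  expect_s3_class(mv, "metric_vector")
  expect_length(mv, 15)
  expect_setequal(attr(mv, "missing"),
                  c("Contigs", "Contigs500", "MeanContigCov", "DiffProts",
                    "DiffComplProts", "MissAssembl", "ComplOrtho",
                    "FragOrtho", "DuplOrtho"))
  expect_equal(sum(!is.na(mv)), 6)  # 7 quantities; MeanContigLen holds the
                                    # all-contig variant when no alignment
  expect_equal(unname(mv["MeanContigLen"]), attr(mv, "mean_contig_len_all"))

  aln <- data.frame(contig_id = names(a$contigs)[1], mapped_reads = 2,
                    mapped_pairs = 1,
                    covered_bases = nchar(a$contigs[1]) %/% 2)
  hits <- data.frame(contig_id = names(a$contigs)[1], protein_id = "P1",
                     strand = "+", completeness = "complete")
  orth <- data.frame(ortholog_group_id = "OG1", status = "complete_single")
  full <- build_metric_vector(a, aln = aln, hits = hits, orthologs = orth,
                              read_mode = "paired")
  expect_length(attr(full, "missing"), 0)
  expect_true(all(!is.na(full)))
  expect_lte(full["DiffComplProts"], full["DiffProts"])
  pct <- full[c("MissAssembl", "MeanContigCov", "ComplOrtho", "FragOrtho",
                "DuplOrtho")]
  expect_true(all(pct >= 0 & pct <= 100))

  bad_aln <- transform(aln, contig_id = "nope")
  expect_error(build_metric_vector(a, aln = bad_aln, read_mode = "paired"),
               "nope")
})

test_that("SAM summarization counts primary alignments, proper pairs and breadth", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:A\tLN:600",
    "@SQ\tSN:B\tLN:400",
    "@SQ\tSN:C\tLN:700",
    # proper pair on A: covers 1-100 and 201-300
    "r1\t99\tA\t1\t60\t100M\t=\t201\t300\t*\t*",
    "r1\t147\tA\t201\t60\t100M\t=\t1\t-300\t*\t*",
    # single mapped read on B
    "r2\t0\tB\t1\t60\t50M\t*\t0\t0\t*\t*",
    # secondary alignment: excluded
    "r3\t256\tB\t100\t60\t50M\t*\t0\t0\t*\t*",
    # unmapped: excluded
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), sam)
  aln <- summarize_sam(sam)
  aln <- aln[order(aln$contig_id), ]
  expect_equal(aln$contig_id, c("A", "B"))
  expect_equal(aln$mapped_reads, c(2L, 1L))
  expect_equal(aln$mapped_pairs, c(1L, 0L))
  expect_equal(aln$covered_bases, c(200, 50))

  asm <- assembly_record("sam", c(A = strrep("A", 600), B = strrep("C", 400),
                                  C = strrep("G", 700)))
  mm <- mapping_metrics(asm, aln, read_mode = "paired")
  expect_equal(mm$Contigs, 1)
  expect_equal(mm$MeanContigCov, 100 * (200 / 600 + 50 / 400 + 0) / 3)
})

test_that("evidence table readers accept the documented dialects", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tmapped_reads\tmapped_pairs\tcovered_bases",
               "c1\t4\t2\t100"), tsv)
  expect_equal(read_alignment_summary(tsv)$covered_bases, 100)

  writeLines(c("contig_id\tprotein_id\tstrand\tcompleteness",
               "c1\tP1\t+\tcomplete"), tsv)
  expect_equal(read_protein_hits(tsv)$protein_id, "P1")

  writeLines(c("ortholog_group_id\tstatus", "OG1\tcomplete_single",
               "OG2\tmissing"), tsv)
  expect_equal(nrow(read_ortholog_status(tsv)), 2)

  # BUSCO v3 full_table dialect, duplicated groups listed once per copy
  writeLines(c("# BUSCO version is: 3.0.2",
               "# Busco id\tStatus\tContig\tStart\tEnd",
               "OG1\tComplete\tc1\t1\t50",
               "OG2\tDuplicated\tc1\t1\t50",
               "OG2\tDuplicated\tc2\t1\t50",
               "OG3\tFragmented\tc3\t1\t20",
               "OG4\tMissing"), tsv)
  busco <- read_ortholog_status(tsv)
  expect_equal(nrow(busco), 4)
  om <- ortholog_metrics(busco)
  expect_equal(unlist(om), c(ComplOrtho = 25, FragOrtho = 25,
                             DuplOrtho = 25))
})
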