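test_that("GC content excludes ambiguous bases and is strand-symmetric", {
  expect_equal(unname(gc_content(c(x = "ATGC"))), 0.5)
  expect_equal(unname(gc_content(c(x = "GGGG"))), 1.0)
  expect_equal(unname(gc_content(c(x = "ATGN"))), 1 / 3)
  expect_equal(unname(gc_content(c(x = "atgc"))), 0.5)  # case-insensitive
  expect_error(gc_content(c(x = "NNNN")), "all-N")

  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(30:300, 1), gc = runif(1, 0.3, 0.7))
    g <- unname(gc_content(c(a = s)))
    expect_equal(unname(gc_content(c(a = revcomp_chr(s)))), g)
    expect_equal(unname(gc_content(c(a = paste(rev(strsplit(s, "")[[1]]),
                                               collapse = "")))), g)
  }
})

test_that("reading frame comes from the strongest qualifying hit", {
  # identity mapping for blastx frame +1
  f <- infer_frame(hit_row(frame = 1L, bitscore = 80))
  expect_equal(f$offset, 0L)
  expect_equal(f$strand, "forward")
  expect_equal(f$source, "homology_hit")

  # no hits, or no hit above threshold -> no frame
  expect_equal(infer_frame(NULL)$source, "none")
  expect_equal(infer_frame(hit_row(bitscore = 30), min_bitscore = 50)$source,
               "none")

  # the weaker hit's frame is ignored
  f <- infer_frame(hit_table(hit_row(sseqid = "a", frame = 2L, bitscore = 90),
                             hit_row(sseqid = "b", frame = 1L, bitscore = 70)))
  expect_equal(f$offset, 1L)

  # equal bitscores: lower evalue wins, then lexicographic subject id
  f <- infer_frame(hit_table(
    hit_row(sseqid = "a", frame = 3L, bitscore = 90, evalue = 1e-10),
    hit_row(sseqid = "b", frame = 1L, bitscore = 90, evalue = 1e-30)))
  expect_equal(f$offset, 0L)
  f <- infer_frame(hit_table(
    hit_row(sseqid = "b", frame = 3L, bitscore = 90, evalue = 1e-10),
    hit_row(sseqid = "a", frame = 1L, bitscore = 90, evalue = 1e-10)))
  expect_equal(f$offset, 0L)
})

test_that("blastx frame -2 decodes as offset 1 on the reverse complement", {
  # brute-force oracle: embed a known peptide so that exactly one of the six
  # frames translates to it, then check the -2 convention finds that frame
  peptide <- "MKWVDEF"
  cod <- c(M = "ATG", K = "AAA", W = "TGG", V = "GTT", D = "GAT",
           E = "GAA", F = "TTT")
  coding <- paste(cod[strsplit(peptide, "")[[1]]], collapse = "")
  seq <- paste0(revcomp_chr(coding), "C")  # peptide now on reverse, offset 1

  translations <- lapply(c("forward", "reverse"), function(strand)
    sapply(0:2, function(off) {
      aa <- oracle_aa_composition(seq, off, strand)
      s <- if (strand == "reverse") revcomp_chr(seq) else seq
      s <- substring(s, off + 1)
      s <- substring(s, 1, (nchar(s) %/% 3) * 3)
      as.character(Biostrings::translate(Biostrings::DNAString(s),
                                         no.init.codon = TRUE))
    }))
  hits_frame <- which(translations[[2]] == peptide) - 1
  expect_equal(hits_frame, 1)  # oracle: peptide sits at reverse offset 1

  f <- infer_frame(hit_row(frame = -2L, bitscore = 80))
  expect_equal(f$offset, 1L)
  expect_equal(f$strand, "reverse")
  expect_equal(unname(aa_composition(seq, f)[c("M", "K")]),
               rep(1 / nchar(peptide), 2))
})

test_that("codon usage reads complete codons in frame", {
  fwd <- reading_frame(0, "forward")
  expect_equal(unname(codon_usage("ATGATG", fwd)["ATG"]), 1.0)
  expect_equal(sum(codon_usage("ATGATG", fwd)), 1)
  expect_equal(unname(codon_usage("ATGAAA", fwd)[c("ATG", "AAA")]),
               c(0.5, 0.5))
  # reverse strand: codons come from the reverse complement
  expect_equal(unname(codon_usage("CATCAT", reading_frame(0, "reverse"))["ATG"]),
               1.0)
  # codons containing N are skipped; trailing partial codon ignored
  expect_equal(unname(codon_usage("ATGNNNAAAGG", fwd)[c("ATG", "AAA")]),
               c(0.5, 0.5))
  # no frame -> all-zero vector
  none <- reading_frame(source = "none")
  expect_equal(sum(codon_usage("ATGATG", none)), 0)
  expect_length(codon_usage("ATGATG", none), 64)

  # RSCU variant: AAA used exclusively within the two-codon K family -> 2;
  # unbiased single-codon families (ATG/M) stay at 1
  r <- codon_usage("ATGAAAAAA", fwd, rscu = TRUE)
  expect_equal(unname(r[c("AAA", "AAG", "ATG")]), c(2, 0, 1))
})

test_that("amino-acid composition translates in frame and drops stops", {
  fwd <- reading_frame(0, "forward")
  expect_equal(unname(aa_composition("ATGAAA", fwd)[c("M", "K")]), c(0.5, 0.5))
  expect_equal(unname(aa_composition("ATGTAA", fwd)["M"]), 1.0)  # stop excluded
  expect_equal(sum(aa_composition("ATGATG", reading_frame(source = "none"))), 0)
})

test_that("composition vectors are probability vectors matching an oracle", {
  set.seed(23)
  for (i in 1:25) {
    s <- random_dna(sample(12:200, 1))
    off <- sample(0:2, 1)
    strand <- sample(c("forward", "reverse"), 1)
    frame <- reading_frame(off, strand)
    cu <- codon_usage(s, frame)
    aa <- aa_composition(s, frame)
    expect_equal(sum(cu), 1, tolerance = 1e-9)
    if (sum(aa) > 0) expect_equal(sum(aa), 1, tolerance = 1e-9)
    oracle <- oracle_aa_composition(s, off, strand)
    if (!is.null(oracle) && sum(oracle) > 0)
      expect_equal(unname(aa), unname(oracle), tolerance = 1e-12)
  }
})
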