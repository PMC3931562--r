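# mutate k random positions of a DNA string
mutate_dna <- function(s, k) {
  pos <- sample(nchar(s), k)
  chars <- strsplit(s, "")[[1]]
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

test_that("near-identical merging keeps centroids and drops contained copies", {
  set.seed(31)
  long <- random_dna(1000)
  sub_exact <- substr(long, 301, 700)            # exact 400-bp substring
  sub_mut <- mutate_dna(sub_exact, 5)            # 98.75% identity: below 99%
  other <- random_dna(500)

  # two byte-identical contigs -> one survivor
  m <- merge_near_identical(c(a = long, b = long))
  expect_equal(length(m), 1)

  # the oracle confirms the mutated substring is below the identity bar
  st <- align_stats(long, sub_mut)
  expect_lt(st$matches / 400, 0.99)

  m <- merge_near_identical(c(long = long, sub = sub_exact, mut = sub_mut,
                              other = other))
  expect_setequal(names(m), c("long", "mut", "other"))

  # output size never exceeds input; merging is idempotent on its own output
  expect_lte(length(m), 4)
  expect_equal(names(merge_near_identical(m)), names(m))
})

test_that("transcript clustering requires identity and coverage of both contigs", {
  set.seed(37)
  core <- random_dna(300)
  a <- paste0(random_dna(350), core, random_dna(350))  # core = 30% of 1000
  b <- paste0(random_dna(350), core, random_dna(350))
  cl <- cluster_transcripts(c(a = a, b = b))
  expect_equal(max(cl$cluster_id), 1)
  # representative is the longest member (tie: lexicographically first id)
  expect_equal(cl$contig_id[cl$representative], "a")

  # no alignment -> singletons
  cl <- cluster_transcripts(c(a = random_dna(400), b = random_dna(400)))
  expect_equal(max(cl$cluster_id), 2)

  # shared region covering 30% of one but only 10% of the other: both
  # coverages are required, so the pair stays apart
  short_host <- paste0(random_dna(100), core, random_dna(100))  # 60% coverage
  long_host <- paste0(random_dna(1350), core, random_dna(1350)) # 10% coverage
  expect_equal(max(cluster_transcripts(
    c(s = short_host, l = long_host))$cluster_id), 2)

  # both directions: a reverse-complement isoform still clusters
  cl <- cluster_transcripts(c(a = a, rc = revcomp_chr(b)))
  expect_equal(max(cl$cluster_id), 1)
})

test_that("clustering yields a partition independent of input order", {
  set.seed(41)
  base1 <- random_dna(600)
  base2 <- random_dna(500)
  fam <- c(f1 = base1,
           f2 = paste0(base1, random_dna(200)),
           f3 = paste0(random_dna(150), substr(base1, 1, 400)),
           g1 = base2,
           g2 = paste0(substr(base2, 101, 500), random_dna(100)),
           solo = random_dna(450))
  cl1 <- cluster_transcripts(fam)
  # partition: every contig appears exactly once
  expect_setequal(cl1$contig_id, names(fam))
  expect_equal(anyDuplicated(cl1$contig_id), 0)
  # exactly one representative per cluster
  expect_true(all(tapply(cl1$representative, cl1$cluster_id, sum) == 1))
  # input order does not matter
  for (i in 1:3) {
    perm <- sample(length(fam))
    expect_true(same_partition(partition_of(cluster_transcripts(fam[perm])),
                               partition_of(cl1)))
  }
})

test_that("greedy single-linkage agrees with a brute-force component oracle", {
  set.seed(43)
  for (rep in 1:3) {
    # random families of overlapping fragments plus unrelated singletons
    seqs <- character()
    for (f in 1:3) {
      base <- random_dna(sample(500:800, 1))
      n_frag <- sample(2:4, 1)
      for (j in seq_len(n_frag)) {
        start <- sample(1:200, 1)
        stop <- min(nchar(base), start + sample(300:600, 1))
        seqs[sprintf("f%d_%d", f, j)] <- substr(base, start, stop)
      }
    }
    for (s in 1:4) seqs[sprintf("solo%d", s)] <- random_dna(sample(300:500, 1))
    seqs <- seqs[nchar(seqs) >= 150]
    stopifnot(length(seqs) <= 20)

    link <- function(i, j)
      symbiosort:::clusterable_pair(seqs[[i]], seqs[[j]], 0.99, 0.20)
    oracle <- oracle_components(names(seqs), link)
    got <- partition_of(cluster_transcripts(seqs))
    expect_true(same_partition(got, oracle))
  }
})

test_that("accession histograms bucket per-accession contig counts", {
  expect_equal(accession_histogram(c("x", "y", "z"))$n_accessions,
               c(3, 0, 0, 0, 0, 0, 0))
  expect_equal(accession_histogram(rep("x", 4))$n_accessions[3], 1)  # 3-5

  # brute-force tally on a mixed toy map: 12 contigs over 6 accessions
  acc <- c(rep("a1", 1), rep("a2", 1), rep("a3", 2), rep("a4", 3),
           rep("a5", 4), rep("a6", 1))
  h <- accession_histogram(acc)
  per <- table(acc)
  expect_equal(h$n_accessions[h$bucket == "1"], sum(per == 1))
  expect_equal(h$n_accessions[h$bucket == "2"], sum(per == 2))
  expect_equal(h$n_accessions[h$bucket == "3-5"], sum(per >= 3 & per <= 5))
  expect_equal(sum(h$n_accessions), length(unique(acc)))
  expect_equal(accession_histogram(rep("big", 60))$n_accessions[7], 1)  # >50
})

test_that("the unigene estimate applies the annotated genes-per-contig ratio", {
  expect_equal(estimate_unigenes(100, 100, 100), 100)
  expect_equal(estimate_unigenes(22668, 7895, 5054), 22668 * 5054 / 7895)
  expect_equal(round(estimate_unigenes(22668, 7895, 5054)), 14511)
  expect_equal(round(estimate_unigenes(26219, 16373, 9386)), 15030)
  expect_error(estimate_unigenes(100, 0, 0))
  expect_error(estimate_unigenes(100, 50, 60))
})
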