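# shared fixture builders and independent oracles

# build a hit data.frame row-wise with defaults
hit_row <- function(qseqid = "q1", sseqid = "s1", species = "synthsp",
                    category = "cnidarian", bitscore = 100, evalue = 1e-20,
                    frame = 1L, qstart = 1L, qend = 100L) {
  data.frame(qseqid = qseqid, sseqid = sseqid, species = species,
             category = category, bitscore = bitscore, evalue = evalue,
             frame = frame, qstart = qstart, qend = qend,
             stringsAsFactors = FALSE)
}

hit_table <- function(...) do.call(rbind, list(...))

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# independent amino-acid composition oracle: explicit reverse complement,
# offset trim, Biostrings::translate, manual tally
oracle_aa_composition <- function(seq, offset, strand) {
  s <- if (strand == "reverse") revcomp_chr(seq) else seq
  s <- substring(s, offset + 1)
  s <- substring(s, 1, (nchar(s) %/% 3) * 3)
  if (nchar(s) == 0) return(NULL)
  aa <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(s),
                          no.init.codon = TRUE)), "")[[1]]
  aa <- aa[aa != "*"]
  aas <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))
  counts <- table(factor(aa, levels = aas))
  v <- setNames(as.numeric(counts), aas)
  if (sum(v) > 0) v / sum(v) else v
}

# brute-force connected components over an explicit pair predicate
oracle_components <- function(ids, link) {
  comp <- setNames(seq_along(ids), ids)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      if (link(ids[i], ids[j])) {
        old <- comp[ids[i]]
        comp[comp == old] <- comp[ids[j]]
      }
    }
  }
  unname(lapply(split(names(comp), comp), sort))
}

# canonical partition (list of sorted member sets) from a clustering table
partition_of <- function(clusters) {
  unname(lapply(split(clusters$contig_id, clusters$cluster_id), sort))
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, paste, character(1), collapse = "|"))
  identical(key(a), key(b))
}
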