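#' GC content of contigs
#'
#' Fraction of G+C among unambiguous bases. N bases are excluded from both
#' numerator and denominator, so the statistic is the GC fraction of the
#' determined part of the sequence. Invariant under reversal and
#' complementation.
#'
#' @param contigs A `DNAStringSet` (or named character vector) of contigs.
#' @return Named numeric vector of GC fractions in \[0, 1\].
#' @export
gc_content <- function(contigs) {
  contigs <- as_contig_set(contigs)
  f <- Biostrings::letterFrequency(contigs, letters = c("A", "C", "G", "T"))
  denom <- rowSums(f)
  if (any(denom == 0))
    stop("GC content undefined (all-N sequence): ",
         paste(names(contigs)[denom == 0], collapse = ", "))
  setNames((f[, "G"] + f[, "C"]) / denom, names(contigs))
}

#' Construct a reading frame
#'
#' @param offset Integer 0, 1 or 2: bases skipped before the first codon.
#' @param strand `"forward"` or `"reverse"` (codons read off the reverse
#'   complement).
#' @param source `"homology_hit"` when the frame was inferred from a hit,
#'   `"none"` when no frame is known (offset/strand then ignored).
#' @return A `reading_frame` list.
#' @export
reading_frame <- function(offset = 0L, strand = "forward",
                          source = "homology_hit") {
  source <- match.arg(source, c("homology_hit", "none"))
  if (source == "none")
    return(structure(list(offset = NA_integer_, strand = NA_character_,
                          source = source), class = "reading_frame"))
  if (!offset %in% 0:2) stop("frame offset must be 0, 1 or 2")
  strand <- match.arg(strand, c("forward", "reverse"))
  structure(list(offset = as.integer(offset), strand = strand,
                 source = source), class = "reading_frame")
}

#' Infer the reading frame of a contig from its homology hits
#'
#' A sufficiently strong hit (bitscore at or above `min_bitscore`) pins the
#' reading frame of a transcript. The frame of the best qualifying hit is
#' used, converting the blastx frame convention: +1..+3 map to offsets 0..2
#' on the forward strand, -1..-3 to offsets 0..2 on the reverse complement.
#' Ties on bitscore are broken by lower E-value, then lexicographic subject
#' id, so the result is deterministic.
#'
#' @param hits Hit data.frame for a single query contig (may be empty).
#' @param min_bitscore Minimum bitscore for a hit to be trusted for frame
#'   inference. Default 50 bits, a conventional "strong hit" threshold.
#' @return A [reading_frame()]; `source = "none"` when no hit qualifies.
#' @export
infer_frame <- function(hits, min_bitscore = 50) {
  if (is.null(hits) || nrow(hits) == 0)
    return(reading_frame(source = "none"))
  if (length(unique(hits$qseqid)) > 1)
    stop("infer_frame expects hits for a single query contig")
  hits <- hits[hits$bitscore >= min_bitscore, , drop = FALSE]
  if (nrow(hits) == 0) return(reading_frame(source = "none"))
  best <- hits[order(-hits$bitscore, hits$evalue, hits$sseqid), ][1, ]
  reading_frame(offset = abs(best$frame) - 1L,
                strand = if (best$frame > 0) "forward" else "reverse",
                source = "homology_hit")
}

# codons of `seq` read in `frame`; codons containing N and the trailing
# partial codon are dropped. Returns character(0) when source == "none".
frame_codons <- function(seq, frame) {
  if (frame$source == "none") return(character())
  s <- toupper(as.character(seq))
  if (frame$strand == "reverse")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s <- substring(s, frame$offset + 1L)
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0) return(character())
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  codons[!grepl("N", codons, fixed = TRUE)]
}

#' Codon-usage vector of a contig
#'
#' Fraction of each of the 64 codons among the complete codons read in the
#' given frame (after reverse complementing when the frame is on the
#' reverse strand). Codons containing N and the trailing partial codon are
#' skipped. Without a frame the vector is all zeros: codon usage is only
#' meaningful once a homology hit has pinned the frame.
#'
#' @param contig A single sequence (character or `DNAString`).
#' @param frame A [reading_frame()].
#' @param rscu If `TRUE`, return relative synonymous codon usage instead of
#'   raw fractions: each codon's frequency divided by the mean frequency of
#'   its synonyms, so 1 means no bias within the synonym family. Raw
#'   fractions (the default) are what the classifier consumes.
#' @return Named 64-vector (lexicographic codon order). Raw fractions sum
#'   to 1 when a frame is known and at least one codon is read, else all
#'   zeros.
#' @export
codon_usage <- function(contig, frame, rscu = FALSE) {
  counts <- table(factor(frame_codons(contig, frame), levels = CODONS))
  v <- setNames(as.numeric(counts), CODONS)
  if (sum(v) == 0) return(v)
  v <- v / sum(v)
  if (!rscu) return(v)
  aa <- Biostrings::GENETIC_CODE[CODONS]
  fam_mean <- stats::ave(v, aa)
  ifelse(fam_mean > 0, v / fam_mean, 0)
}

#' Amino-acid composition of a contig
#'
#' Standard-genetic-code translation of the in-frame codons; stop codons
#' are excluded from the denominator. Without a frame the vector is all
#' zeros.
#'
#' @inheritParams codon_usage
#' @return Named 20-vector (alphabetical one-letter codes) summing to 1
#'   when at least one non-stop residue is translated, else all zeros.
#' @export
aa_composition <- function(contig, frame) {
  aa <- Biostrings::GENETIC_CODE[frame_codons(contig, frame)]
  aa <- aa[aa != "*"]
  counts <- table(factor(aa, levels = AA_LETTERS))
  v <- setNames(as.numeric(counts), AA_LETTERS)
  if (sum(v) > 0) v / sum(v) else v
}

#' Compositional features of one contig
#'
#' Bundles GC content, frame-aware codon usage and amino-acid composition
#' into the compositional half of the classifier's feature vector.
#'
#' @param contig A single sequence.
#' @param frame A [reading_frame()] (typically from [infer_frame()]).
#' @return List with `gc`, `has_frame`, `codon_freq` (64), `aa_freq` (20).
#' @export
composition_features <- function(contig, frame = reading_frame(source = "none")) {
  codon <- codon_usage(contig, frame)
  list(gc = unname(gc_content(setNames(as.character(contig), "x"))),
       has_frame = frame$source == "homology_hit" && sum(codon) > 0,
       codon_freq = codon,
       aa_freq = aa_composition(contig, frame))
}
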