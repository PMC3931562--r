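#' Read contigs from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file into a `DNAStringSet`,
#' uppercasing the sequences. Only the characters A, C, G, T and N are
#' permitted; anything else is an error naming the offending contig.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-free
#'   token of each header line.
#' @export
read_contigs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_contig_set(seqs)
}

#' Coerce to a validated contig set
#'
#' Uppercases sequences and enforces the contig invariants: unique,
#' non-empty ids; length >= 1; alphabet restricted to {A,C,G,T,N}.
#'
#' @param x A named character vector or `DNAStringSet`.
#' @return A validated [Biostrings::DNAStringSet].
#' @export
as_contig_set <- function(x) {
  if (!methods::is(x, "DNAStringSet")) {
    x <- if (methods::is(x, "DNAString"))
      Biostrings::DNAStringSet(x)
    else {
      ids <- names(x)
      setNames(Biostrings::DNAStringSet(toupper(as.character(x))), ids)
    }
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("all contigs must be named")
  if (anyDuplicated(names(x)))
    stop("duplicated contig ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) < 1))
    stop("zero-length contig: ",
         paste(names(x)[Biostrings::width(x) < 1], collapse = ", "))
  bad <- Biostrings::letterFrequency(x, letters = "ACGTN") !=
    Biostrings::width(x)
  if (any(bad))
    stop("contig with characters outside {A,C,G,T,N}: ",
         paste(names(x)[bad], collapse = ", "))
  x
}

#' Write contigs to FASTA
#'
#' @param contigs A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  Biostrings::writeXStringSet(contigs, path, width = 70L)
  invisible(path)
}

# Shared TSV writer: optional "# key: value" header comments, full-precision
# numeric formatting so tables round-trip bit-exactly through read_tsv().
write_tsv <- function(df, path, header = character()) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in names(header))
    writeLines(sprintf("# %s: %s", h, header[[h]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read a homology hit table
#'
#' Reads tab-separated homology hits in an outfmt-6-like dialect with the
#' columns `qseqid`, `sseqid`, `species`, `category`, `bitscore`, `evalue`,
#' `frame`, `qstart`, `qend`. Hits with an E-value above `max_evalue` are
#' dropped on load (set `max_evalue = Inf` to keep everything).
#'
#' @param path Path to the hit TSV.
#' @param max_evalue E-value cutoff applied on load (default `1e-5`, the
#'   conventional annotation threshold).
#' @return A data.frame of hits with validated categories.
#' @export
read_hits <- function(path, max_evalue = 1e-5) {
  hits <- read_tsv(path)
  validate_hits(hits)
  hits[hits$evalue <= max_evalue, , drop = FALSE]
}

#' Write a homology hit table
#'
#' @param hits Hit data.frame (see [read_hits()] for columns).
#' @param path Output path.
#' @param header Optional named character vector written as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, header = character()) {
  validate_hits(hits)
  write_tsv(hits, path, header)
}

validate_hits <- function(hits) {
  need <- c("qseqid", "sseqid", "species", "category", "bitscore", "evalue",
            "frame", "qstart", "qend")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(hits$category), HIT_CATEGORIES)
  if (length(bad))
    stop("unknown hit categories: ", paste(bad, collapse = ", "))
  if (any(hits$qstart > hits$qend))
    stop("hit with qstart > qend for query: ",
         paste(unique(hits$qseqid[hits$qstart > hits$qend]), collapse = ", "))
  if (any(!hits$frame %in% c(-3:-1, 1:3)))
    stop("blastx frame must be in {-3..-1, 1..3}")
  invisible(hits)
}

#' Read a species-to-category map
#'
#' Two-column TSV (`species`, `category`) mapping subject species to one of
#' the eight hit categories; used when hit tables carry species but no
#' category column.
#'
#' @param path Path to the map TSV.
#' @return Named character vector: category indexed by species.
#' @export
read_species_map <- function(path) {
  m <- read_tsv(path)
  if (!all(c("species", "category") %in% names(m)))
    stop("species map needs columns 'species' and 'category'")
  bad <- setdiff(unique(m$category), HIT_CATEGORIES)
  if (length(bad))
    stop("unknown categories in species map: ", paste(bad, collapse = ", "))
  setNames(m$category, m$species)
}

#' Read a genomic read-count table
#'
#' TSV with a `contig_id` column followed by one non-negative integer
#' column per sequencing library.
#'
#' @param path Path to the count TSV.
#' @return A data.frame with rownames = contig ids and one numeric column
#'   per library.
#' @export
read_count_table <- function(path) {
  tab <- read_tsv(path)
  if (!"contig_id" %in% names(tab))
    stop("count table needs a 'contig_id' column")
  counts <- tab[setdiff(names(tab), "contig_id")]
  if (ncol(counts) < 1) stop("count table needs >= 1 library column")
  if (any(vapply(counts, function(x) any(x < 0), logical(1))))
    stop("read counts must be non-negative")
  rownames(counts) <- tab$contig_id
  counts
}
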