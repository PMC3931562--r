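#' Pairwise local alignment statistics
#'
#' Aligns two contigs locally in both orientations (the second sequence is
#' also tried as its reverse complement) with match/mismatch/gap scores of
#' +1/-2/-3 and returns the statistics of the better alignment: identity
#' over alignment columns, number of matching columns, alignment length,
#' and the fraction of each contig covered by the aligned region.
#'
#' @param a,b Sequences (character or `DNAString`).
#' @return List with `identity`, `matches`, `aligned_length`,
#'   `coverage_a`, `coverage_b`, `strand`.
#' @export
align_stats <- function(a, b) {
  a <- Biostrings::DNAString(toupper(as.character(a)))
  b <- Biostrings::DNAString(toupper(as.character(b)))
  fwd <- local_alignment(a, b)
  rev <- local_alignment(a, Biostrings::reverseComplement(b))
  best <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) fwd else rev
  strand <- if (Biostrings::score(fwd) >= Biostrings::score(rev))
    "forward" else "reverse"
  pat <- Biostrings::pattern(best)
  sub <- Biostrings::subject(best)
  cols <- nchar(as.character(pat))  # alignment columns, gaps included
  matches <- Biostrings::nmatch(best)
  span_a <- Biostrings::end(pat) - Biostrings::start(pat) + 1
  span_b <- Biostrings::end(sub) - Biostrings::start(sub) + 1
  list(identity = if (cols > 0) matches / cols else 0,
       matches = matches,
       aligned_length = cols,
       coverage_a = span_a / length(a),
       coverage_b = span_b / length(b),
       strand = strand)
}

local_alignment <- function(a, b) {
  mat <- matrix(-2, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(mat) <- 1
  mat["N", ] <- mat[, "N"] <- -2  # N never counts as a match
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 3)
}

# predicate for the near-identity merge: >= `identity` fraction of the
# shorter contig's length is matched by the best local alignment
near_identical <- function(a, b, identity = 0.99) {
  st <- align_stats(a, b)
  st$matches >= identity * min(nchar(as.character(a)), nchar(as.character(b)))
}

# predicate for isoform clustering: the alignment covers >= min_coverage of
# BOTH contigs and is >= `identity` identical over its columns
clusterable_pair <- function(a, b, identity = 0.99, min_coverage_each = 0.20) {
  st <- align_stats(a, b)
  st$aligned_length > 0 &&
    st$coverage_a >= min_coverage_each &&
    st$coverage_b >= min_coverage_each &&
    st$identity >= identity
}

# canonical processing order: descending length, then id
canonical_order <- function(contigs) {
  contigs[order(-Biostrings::width(contigs), names(contigs))]
}

#' Merge near-identical contigs
#'
#' Greedy centroid pass in descending length order: a contig is merged
#' into an existing (longer or equal) centroid when the best local
#' alignment between them matches at least `identity` of the shorter
#' contig's length — i.e. the shorter contig is essentially contained in
#' the centroid. Centroids are retained; merged contigs are dropped.
#'
#' @param contigs `DNAStringSet`.
#' @param identity Identity threshold over the shorter contig's length
#'   (default 0.99).
#' @return `DNAStringSet` of surviving centroids (descending length).
#' @export
merge_near_identical <- function(contigs, identity = 0.99) {
  contigs <- canonical_order(as_contig_set(contigs))
  keep <- character()
  for (id in names(contigs)) {
    absorbed <- FALSE
    for (cid in keep) {
      if (near_identical(contigs[[cid]], contigs[[id]], identity)) {
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) keep <- c(keep, id)
  }
  contigs[keep]
}

#' Cluster transcripts into putative genes
#'
#' Greedy single-linkage clustering of contigs that share a region at
#' least `identity` identical covering at least `min_coverage_each` of
#' BOTH contigs' total lengths — the signature of alternative transcripts
#' or very similar paralogs of one gene. Contigs are processed in
#' canonical order (descending length, then id), so the result does not
#' depend on input file order; a contig linking to several existing
#' clusters merges them (single linkage: A-B and B-C clusterable puts A, B
#' and C together even if A-C fails the pair test). The longest member of
#' each cluster (ties: lexicographically first id) is its representative.
#'
#' @param contigs `DNAStringSet`, ideally already passed through
#'   [merge_near_identical()].
#' @param identity Identity threshold over alignment columns (default
#'   0.99).
#' @param min_coverage_each Minimum aligned fraction of each contig's
#'   length (default 0.20).
#' @return Data.frame with `cluster_id`, `contig_id`, `representative`
#'   (logical), `length`.
#' @export
cluster_transcripts <- function(contigs, identity = 0.99,
                                min_coverage_each = 0.20) {
  contigs <- canonical_order(as_contig_set(contigs))
  clusters <- list()  # each: character vector of member ids
  for (id in names(contigs)) {
    linked <- which(vapply(clusters, function(members) {
      any(vapply(members, function(m) {
        clusterable_pair(contigs[[m]], contigs[[id]],
                         identity, min_coverage_each)
      }, logical(1)))
    }, logical(1)))
    if (length(linked) == 0) {
      clusters[[length(clusters) + 1L]] <- id
    } else {
      merged <- c(unlist(clusters[linked]), id)
      clusters <- clusters[-linked]
      clusters[[length(clusters) + 1L]] <- merged
    }
  }
  rows <- lapply(seq_along(clusters), function(i) {
    members <- clusters[[i]]
    w <- Biostrings::width(contigs[members])
    rep_id <- members[order(-w, members)][1]
    data.frame(contig_id = members, representative = members == rep_id,
               length = w, stringsAsFactors = FALSE)
  })
  # stable cluster numbering: by representative in canonical order
  reps <- vapply(rows, function(r) r$contig_id[r$representative], character(1))
  ord <- order(match(reps, names(contigs)))
  out <- do.call(rbind, lapply(seq_along(ord), function(k) {
    cbind(cluster_id = k, rows[[ord[k]]])
  }))
  rownames(out) <- NULL
  out
}

#' Representative contigs of a clustering
#'
#' @param contigs The `DNAStringSet` that was clustered.
#' @param clusters Output of [cluster_transcripts()].
#' @return `DNAStringSet` of one representative (longest member) per
#'   cluster.
#' @export
representative_contigs <- function(contigs, clusters) {
  as_contig_set(contigs)[clusters$contig_id[clusters$representative]]
}

#' Histogram of contigs per accession
#'
#' Buckets the number of contigs whose best annotation hit points at each
#' distinct accession: many contigs sharing one accession suggests
#' fragmented assembly or unclustered transcripts of one gene.
#'
#' @param accessions Character vector: the best-hit accession of each
#'   annotated contig (one entry per contig).
#' @return Data.frame with `bucket` (`1`, `2`, `3-5`, `6-10`, `11-25`,
#'   `26-50`, `>50`) and `n_accessions`; bucket counts sum to the number
#'   of distinct accessions.
#' @export
accession_histogram <- function(accessions) {
  per_acc <- table(accessions)
  edges <- c(1, 2, 3, 6, 11, 26, 51, Inf)
  labels <- c("1", "2", "3-5", "6-10", "11-25", "26-50", ">50")
  bucket <- cut(as.numeric(per_acc), breaks = edges, labels = labels,
                right = FALSE)
  data.frame(bucket = labels,
             n_accessions = as.integer(table(bucket)[labels]),
             stringsAsFactors = FALSE)
}

#' Worst-case unigene estimate
#'
#' Estimates the number of distinct genes behind a contig set by assuming
#' every case of several contigs annotating one accession reflects a
#' failure of those contigs to cluster, and that this failure rate is the
#' same among annotated and unannotated contigs. The annotated subset's
#' genes-per-contig ratio (distinct accessions / annotated contigs) is
#' then applied to the whole set.
#'
#' @param total_contigs Number of representative contigs in the class.
#' @param annotated_contigs Number with an annotation hit.
#' @param distinct_accessions Number of distinct accessions hit.
#' @return `total_contigs * distinct_accessions / annotated_contigs`.
#' @export
estimate_unigenes <- function(total_contigs, annotated_contigs,
                              distinct_accessions) {
  stopifnot(annotated_contigs > 0, annotated_contigs <= total_contigs,
            distinct_accessions <= annotated_contigs)
  total_contigs * distinct_accessions / annotated_contigs
}
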