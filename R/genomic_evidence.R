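#' Mean genomic read count per contig
#'
#' Arithmetic mean of the per-library genomic read-pair counts. Raw counts
#' are averaged (no library-size normalisation): the evidence question is
#' simply whether host genomic reads align at all.
#'
#' @param counts Numeric vector (one contig) or matrix/data.frame with one
#'   row per contig and one column per library.
#' @return Numeric vector of means.
#' @export
mean_read_count <- function(counts) {
  if (is.vector(counts)) {
    if (length(counts) == 0) stop("need counts from >= 1 library")
    return(mean(counts))
  }
  if (ncol(counts) == 0) stop("need counts from >= 1 library")
  rowMeans(as.matrix(counts))
}

#' Genomic-evidence flag
#'
#' A contig has genomic evidence of host origin when its mean read count
#' reaches the cutoff. The boundary is inclusive: a mean of exactly
#' `cutoff` counts as evidence. The default cutoff of 10 mean read-pairs
#' separates host contigs (typical mean counts in the hundreds) from
#' symbiont and contaminant contigs (mostly zero).
#'
#' @param mean_count Non-negative mean read counts.
#' @param cutoff Evidence threshold (default 10).
#' @return Logical vector.
#' @export
evidence_flag <- function(mean_count, cutoff = 10) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  if (any(mean_count < 0)) stop("mean counts must be non-negative")
  mean_count >= cutoff
}

#' Consensus origin assignment
#'
#' Reconciles the classifier's call with the genomic-evidence flag. Host
#' genomic reads should align to a cnidarian contig and not to a
#' non-cnidarian one; when classifier and evidence agree in that sense the
#' classifier label is confirmed, otherwise the contig is `ambiguous`.
#'
#' @param classifier_class Character vector of classifier labels
#'   (one of [TAXON_GROUPS]).
#' @param has_evidence Logical vector of genomic-evidence flags.
#' @return Character vector: the confirmed class or `"ambiguous"`.
#' @export
consensus_classify <- function(classifier_class, has_evidence) {
  stopifnot(length(classifier_class) == length(has_evidence))
  bad <- setdiff(unique(classifier_class), TAXON_GROUPS)
  if (length(bad)) stop("unknown classes: ", paste(bad, collapse = ", "))
  agree <- (classifier_class == "cnidarian") == has_evidence
  ifelse(agree, classifier_class, "ambiguous")
}

#' Build per-contig consensus records
#'
#' @param classified Data.frame with `contig_id` and `predicted` (from
#'   [classify_contigs()]).
#' @param counts Read-count matrix/data.frame (rownames = contig ids;
#'   contigs absent from the table get an all-zero row).
#' @param cutoff Evidence threshold (default 10).
#' @return Data.frame with `contig_id`, `classifier_class`, `mean_count`,
#'   `has_evidence`, `final_label`.
#' @export
consensus_records <- function(classified, counts, cutoff = 10) {
  mc <- setNames(rep(0, nrow(classified)), classified$contig_id)
  present <- intersect(classified$contig_id, rownames(counts))
  mc[present] <- mean_read_count(counts[present, , drop = FALSE])
  ev <- unname(evidence_flag(mc, cutoff))
  data.frame(contig_id = classified$contig_id,
             classifier_class = classified$predicted,
             mean_count = unname(mc), has_evidence = ev,
             final_label = consensus_classify(classified$predicted, ev),
             stringsAsFactors = FALSE)
}

#' Per-class concordance/discordance summary
#'
#' For each classifier class: the number of contigs assigned, the numbers
#' with and without genomic evidence, and the discordance (false-positive)
#' rate in percent — the fraction of calls contradicted by the evidence
#' (no evidence for cnidarian calls; evidence for non-cnidarian calls),
#' rounded half-up to one decimal. A class with no contigs gets an
#' undefined (NA) rate rather than 0.
#'
#' @param records Consensus records from [consensus_records()].
#' @return Data.frame with columns `class`, `n_classified`,
#'   `n_with_evidence`, `n_without_evidence`, `discordance_rate`.
#' @export
discordance_table <- function(records) {
  do.call(rbind, lapply(TAXON_GROUPS, function(cl) {
    idx <- records$classifier_class == cl
    n <- sum(idx)
    with_ev <- sum(records$has_evidence[idx])
    without_ev <- n - with_ev
    discordant <- if (cl == "cnidarian") without_ev else with_ev
    data.frame(class = cl, n_classified = n, n_with_evidence = with_ev,
               n_without_evidence = without_ev,
               discordance_rate = if (n == 0) NA_real_ else
                 round_half_up(100 * discordant / n, 1),
               stringsAsFactors = FALSE)
  }))
}

#' Discordance rate from printed counts
#'
#' Convenience for checking a summary table's arithmetic: the discordance
#' percentage for one class given its total and discordant counts.
#'
#' @param n_classified Total contigs the classifier assigned to the class.
#' @param n_discordant Contigs whose evidence flag contradicts the call.
#' @return Percentage rounded half-up to one decimal; NA when the class is
#'   empty.
#' @export
discordance_rate <- function(n_classified, n_discordant) {
  ifelse(n_classified == 0, NA_real_,
         round_half_up(100 * n_discordant / n_classified, 1))
}

#' Write consensus records to TSV
#'
#' @param records Consensus records.
#' @param path Output path.
#' @param header Optional named character vector of `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(records, path, header = character()) {
  write_tsv(records, path, header)
}
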