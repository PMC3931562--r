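#' Drop homology hits to training-source species
#'
#' Hits to the very species that supplied the labelled training and test
#' sequences are discarded before feature computation. Without this
#' exclusion the classifier can learn to recognise the training species
#' through their database entries and look far more accurate than it will
#' be on novel data.
#'
#' @param hits Hit data.frame.
#' @param excluded_species Character vector of species to remove.
#' @return The hits whose `species` is not excluded, original order kept.
#' @export
filter_leakage <- function(hits, excluded_species) {
  hits[!hits$species %in% excluded_species, , drop = FALSE]
}

# deterministic hit ranking: bitscore desc, then evalue asc, then subject id
rank_hits <- function(hits) {
  hits[order(-hits$bitscore, hits$evalue, hits$sseqid), , drop = FALSE]
}

one_hot_category <- function(category) {
  stopifnot(category %in% HIT_CATEGORIES)
  setNames(as.numeric(HIT_CATEGORIES == category), HIT_CATEGORIES)
}

#' Taxon scores of the top hits
#'
#' Ranks a contig's hits by bitscore (ties: lower E-value, then subject id)
#' and encodes the taxon category of each of the top `k` as a one-hot block
#' over the eight hit categories. Ranks beyond the available hits encode
#' `none_of_the_above`, so the result always has `k` blocks each summing
#' to 1.
#'
#' @param hits Hit data.frame for one query, already leakage-filtered.
#' @param k Number of ranked hits to encode (default 5).
#' @return Named numeric vector of length `8 * k` (`top1_*` ... `topk_*`).
#' @export
score_top_hits <- function(hits, k = 5) {
  cats <- rep("none_of_the_above", k)
  if (!is.null(hits) && nrow(hits) > 0) {
    top <- utils::head(rank_hits(hits)$category, k)
    cats[seq_along(top)] <- top
  }
  blocks <- lapply(seq_len(k), function(i) {
    setNames(one_hot_category(cats[i]),
             paste0("top", i, "_", HIT_CATEGORIES))
  })
  unlist(blocks)
}

#' Taxon score of the best custom-database hit
#'
#' The custom database holds the labelled sequences that went into neither
#' the training nor the test set; its single best hit is a strong,
#' leakage-safe origin signal. Encoded as one one-hot block of 8;
#' `none_of_the_above` when there is no hit.
#'
#' @param hits Hit data.frame against the custom database for one query.
#' @return Named numeric vector of length 8 (`custom_*`).
#' @export
best_customdb_hit <- function(hits) {
  cat <- "none_of_the_above"
  if (!is.null(hits) && nrow(hits) > 0)
    cat <- rank_hits(hits)$category[1]
  setNames(one_hot_category(cat), paste0("custom_", HIT_CATEGORIES))
}

#' Names of the full feature vector, in contract order
#'
#' The classifier's feature order is a stable contract:
#' `gc` (1), `has_frame` (1), codon frequencies (64), amino-acid
#' frequencies (20), top-5 hit blocks (40), custom-database block (8) —
#' 134 numbers in total.
#'
#' @return Character vector of 134 feature names.
#' @export
feature_names <- function() {
  c("gc", "has_frame",
    paste0("codon_", CODONS),
    paste0("aa_", AA_LETTERS),
    unlist(lapply(1:5, function(i) paste0("top", i, "_", HIT_CATEGORIES))),
    paste0("custom_", HIT_CATEGORIES))
}

#' Assemble one contig's feature vector
#'
#' Concatenates compositional and homology features in the fixed order
#' documented at [feature_names()].
#'
#' @param comp Output of [composition_features()].
#' @param top5 Output of [score_top_hits()] (40 numbers).
#' @param customdb Output of [best_customdb_hit()] (8 numbers).
#' @return Named numeric vector of length 134.
#' @export
assemble_feature_vector <- function(comp, top5 = score_top_hits(NULL),
                                    customdb = best_customdb_hit(NULL)) {
  v <- c(gc = comp$gc, has_frame = as.numeric(comp$has_frame),
         setNames(comp$codon_freq, paste0("codon_", names(comp$codon_freq))),
         setNames(comp$aa_freq, paste0("aa_", names(comp$aa_freq))),
         top5, customdb)
  if (!identical(names(v), feature_names()))
    stop("internal error: feature vector out of contract order")
  v
}

#' Feature matrix for a contig set
#'
#' Runs the whole per-contig feature pipeline: leakage filtering, frame
#' inference from the strongest reference-database hit, codon/amino-acid
#' composition, top-5 hit scoring and custom-database scoring.
#'
#' @param contigs `DNAStringSet` of contigs.
#' @param hits Reference-database hit data.frame (all queries), or `NULL`.
#' @param custom_hits Custom-database hit data.frame, or `NULL`.
#' @param excluded_species Species removed by [filter_leakage()].
#' @param min_bitscore Frame-inference threshold (see [infer_frame()]).
#' @return Numeric matrix, one row per contig, 134 columns in
#'   [feature_names()] order; rownames are contig ids.
#' @export
contig_features <- function(contigs, hits = NULL, custom_hits = NULL,
                            excluded_species = character(),
                            min_bitscore = 50) {
  contigs <- as_contig_set(contigs)
  if (!is.null(hits)) hits <- filter_leakage(hits, excluded_species)
  if (!is.null(custom_hits))
    custom_hits <- filter_leakage(custom_hits, excluded_species)
  hit_split <- if (is.null(hits)) list() else split(hits, hits$qseqid)
  custom_split <- if (is.null(custom_hits)) list() else
    split(custom_hits, custom_hits$qseqid)
  ids <- names(contigs)
  out <- matrix(0, nrow = length(ids), ncol = length(feature_names()),
                dimnames = list(ids, feature_names()))
  for (i in seq_along(ids)) {
    h <- hit_split[[ids[i]]]
    frame <- infer_frame(h, min_bitscore = min_bitscore)
    comp <- composition_features(contigs[[i]], frame)
    out[i, ] <- assemble_feature_vector(comp, score_top_hits(h),
                                        best_customdb_hit(custom_split[[ids[i]]]))
  }
  out
}

#' Write / read a feature table
#'
#' The TSV has a `contig_id` column followed by the 134 feature columns in
#' contract order; numerics are written at full precision so the table
#' round-trips bit-exactly.
#'
#' @param features Feature matrix from [contig_features()].
#' @param path File path.
#' @param header Optional named character vector of `# key: value` lines.
#' @return `path` (writer) or the feature matrix (reader).
#' @export
write_feature_table <- function(features, path, header = character()) {
  df <- data.frame(contig_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, header)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[setdiff(names(df), "contig_id")])
  rownames(m) <- df$contig_id
  if (!identical(colnames(m), feature_names()))
    stop("feature table columns do not match the feature contract")
  m
}
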