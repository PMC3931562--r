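#' Default synthetic taxon profiles
#'
#' Builds one compositional profile per taxon group: a target GC content
#' and a 64-vector of codon weights consistent with it. Codon weights are
#' drawn per class from a seeded uniform square (giving each class a
#' distinct codon-usage signature), stop codons are excluded, and the
#' weights are exponentially tilted in the number of G/C bases per codon
#' until the expected GC fraction matches the target. The default GC
#' targets (cnidarian 0.42, dinoflagellate 0.55, fungal 0.45, bacterial
#' 0.51) are plausible spacings chosen for benchmark separability; they
#' are synthetic settings, not biological estimates.
#'
#' @param gc_targets Named numeric vector of target GC fractions, one per
#'   class in [TAXON_GROUPS].
#' @param hit_accuracy Probability that a mock homology hit reports the
#'   true category (default 0.9).
#' @param profile_seed Seed for the per-class codon preferences; part of
#'   the profile definition, distinct from the corpus-sampling seed.
#' @return Named list of profiles, each with `class`, `gc_target`,
#'   `codon_weights` (named 64-vector, stops zero), `hit_accuracy`.
#' @export
taxon_profiles <- function(gc_targets = c(cnidarian = 0.42,
                                          dinoflagellate = 0.55,
                                          fungal = 0.45,
                                          bacterial = 0.51),
                           hit_accuracy = 0.9, profile_seed = 101) {
  if (!setequal(names(gc_targets), TAXON_GROUPS))
    stop("gc_targets must name all of: ", paste(TAXON_GROUPS, collapse = ", "))
  if (any(gc_targets <= 0 | gc_targets >= 1))
    stop("gc_targets must be in (0, 1)")
  if (hit_accuracy < 0 || hit_accuracy > 1)
    stop("hit_accuracy must be in [0, 1]")
  stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
  gc_per_codon <- vapply(strsplit(CODONS, ""), function(b)
    sum(b %in% c("G", "C")), numeric(1))
  profiles <- lapply(seq_along(TAXON_GROUPS), function(i) {
    cl <- TAXON_GROUPS[i]
    set.seed(profile_seed + i)
    u <- setNames(runif(64)^2 + 0.01, CODONS)
    u[stops] <- 0
    # tilt u by t^(#GC per codon) so the expected GC fraction hits target
    gc_of <- function(log_t) {
      w <- u * exp(log_t * gc_per_codon)
      sum(w * gc_per_codon / 3) / sum(w)
    }
    log_t <- uniroot(function(z) gc_of(z) - gc_targets[cl],
                     lower = -10, upper = 10, tol = 1e-12)$root
    w <- u * exp(log_t * gc_per_codon)
    list(class = cl, gc_target = unname(gc_targets[cl]),
         codon_weights = w / sum(w), hit_accuracy = hit_accuracy)
  })
  names(profiles) <- TAXON_GROUPS
  profiles
}

validate_profiles <- function(profiles, gc_tolerance = 0.02) {
  if (!setequal(names(profiles), TAXON_GROUPS))
    stop("profiles must cover all 4 classes")
  for (p in profiles) {
    w <- p$codon_weights
    if (length(w) != 64 || any(w < 0) || sum(w) <= 0)
      stop("invalid codon weights for class ", p$class)
    gc_per_codon <- vapply(strsplit(names(w), ""), function(b)
      sum(b %in% c("G", "C")), numeric(1))
    gc <- sum(w * gc_per_codon / 3) / sum(w)
    if (abs(gc - p$gc_target) > gc_tolerance)
      stop(sprintf("codon weights of class %s imply GC %.3f, target %.3f",
                   p$class, gc, p$gc_target))
  }
  invisible(profiles)
}

#' Generate a labelled synthetic contig corpus
#'
#' Samples coding-style sequences codon by codon from each class profile's
#' codon weights, with lengths drawn uniformly within each canonical
#' length bin (the open-ended >500 bp bin is capped at `max_length`).
#' Sequences are written 5'->3' in reading frame 0 on the forward strand.
#' The generator is a pure function of its parameters and seed:
#' regeneration with the same arguments is byte-identical.
#'
#' @param profiles Taxon profiles from [taxon_profiles()].
#' @param n_per_class_per_bin Sequences per class per bin (default 50).
#' @param seed Integer seed.
#' @param bins Length-bin table (default [length_bins()]).
#' @param max_length Upper length cap for the open-ended bin (default
#'   1500 bp).
#' @return List with `contigs` (`DNAStringSet`), `truth` (data.frame
#'   `id`, `class`, `length`, `bin`) and `seed`.
#' @export
generate_corpus <- function(profiles = taxon_profiles(),
                            n_per_class_per_bin = 50, seed = 1,
                            bins = length_bins(), max_length = 1500) {
  stopifnot(n_per_class_per_bin >= 1)
  validate_profiles(profiles)
  set.seed(seed)
  seqs <- character()
  rows <- list()
  for (cl in TAXON_GROUPS) {
    w <- profiles[[cl]]$codon_weights
    for (i in seq_len(nrow(bins))) {
      hi <- min(bins$upper[i], max_length + 1)
      lens <- floor(runif(n_per_class_per_bin, bins$lower[i], hi))
      ids <- sprintf("%s_bin%d_%04d", cl, i, seq_len(n_per_class_per_bin))
      for (j in seq_len(n_per_class_per_bin)) {
        n_codon <- ceiling(lens[j] / 3)
        s <- paste(sample(CODONS, n_codon, replace = TRUE, prob = w),
                   collapse = "")
        seqs[ids[j]] <- substr(s, 1, lens[j])
      }
      rows[[paste(cl, i)]] <- data.frame(id = ids, class = cl,
                                         length = lens, bin = bins$label[i],
                                         stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(contigs = as_contig_set(seqs), truth = truth, seed = seed)
}

class_to_category <- c(cnidarian = "cnidarian",
                       dinoflagellate = "dinoflagellate",
                       fungal = "fungus",
                       bacterial = "bacteria")

#' Generate a mock homology-hit table for a corpus
#'
#' Emulates the tabular output of a translated homology search against an
#' annotated database: each contig receives 0 to `k_max` hits (binomial
#' with per-slot probability `hit_prob`), each hit's category equals the
#' contig's true category with probability `hit_accuracy` and is a random
#' other category otherwise. Bitscores are descending within a contig;
#' frames are +1 because generated sequences are written in forward frame
#' 0.
#'
#' @param corpus Output of [generate_corpus()].
#' @param hit_accuracy Probability a hit reports the true category;
#'   default taken from the corpus profiles' setting, 0.9.
#' @param k_max Maximum hits per contig (default 5).
#' @param hit_prob Per-slot hit probability (default 0.8), so short of
#'   `k_max` hits — or none at all — is common.
#' @param seed Integer seed.
#' @return Hit data.frame in the dialect of [read_hits()].
#' @export
generate_hits <- function(corpus, hit_accuracy = 0.9, k_max = 5,
                          hit_prob = 0.8, seed = 1) {
  stopifnot(hit_accuracy >= 0, hit_accuracy <= 1, k_max >= 1)
  set.seed(seed)
  truth <- corpus$truth
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    n_hits <- rbinom(1, k_max, hit_prob)
    if (n_hits == 0) next
    true_cat <- class_to_category[[truth$class[i]]]
    correct <- runif(n_hits) < hit_accuracy
    cats <- ifelse(correct, true_cat,
                   vapply(seq_len(n_hits), function(k)
                     sample(setdiff(HIT_CATEGORIES, true_cat), 1),
                     character(1)))
    bitscore <- sort(runif(n_hits, 55, 300), decreasing = TRUE)
    out[[i]] <- data.frame(
      qseqid = truth$id[i],
      sseqid = sprintf("subj_%s_%05d", cats, sample.int(99999, n_hits)),
      species = paste0("synthsp_", cats),
      category = cats,
      bitscore = round(bitscore, 1),
      evalue = signif(10^(-bitscore / 10), 3),
      frame = 1L,
      qstart = 1L,
      qend = as.integer(truth$length[i]),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) hits <- empty_hit_table()
  rownames(hits) <- NULL
  hits
}

empty_hit_table <- function() {
  data.frame(qseqid = character(), sseqid = character(),
             species = character(), category = character(),
             bitscore = numeric(), evalue = numeric(), frame = integer(),
             qstart = integer(), qend = integer(), stringsAsFactors = FALSE)
}

#' Generate a genomic read-count table for a corpus
#'
#' Emulates alignment of host genomic DNA read-pairs to the contigs: true
#' cnidarian contigs draw negative-binomial counts with mean `host_mean`
#' in every library, non-cnidarian contigs are all-zero except for a
#' `contamination_rate` fraction that draws small positive counts
#' (mean `contam_mean`), mimicking trace host DNA carry-over.
#'
#' @param corpus Output of [generate_corpus()].
#' @param host_mean Per-library mean count for host contigs (default 200,
#'   the order of magnitude expected for a well-covered host genome).
#' @param n_libraries Number of sequencing libraries (default 6).
#' @param contamination_rate Fraction of non-host contigs with spurious
#'   counts (default 0.05).
#' @param contam_mean Per-library mean of spurious counts (default 5).
#' @param dispersion Negative-binomial size parameter (default 5).
#' @param seed Integer seed.
#' @return Data.frame of counts, rownames = contig ids, one `lib*` column
#'   per library.
#' @export
generate_read_counts <- function(corpus, host_mean = 200, n_libraries = 6,
                                 contamination_rate = 0.05, contam_mean = 5,
                                 dispersion = 5, seed = 1) {
  stopifnot(host_mean > 0, n_libraries >= 1,
            contamination_rate >= 0, contamination_rate <= 1)
  set.seed(seed)
  truth <- corpus$truth
  n <- nrow(truth)
  counts <- matrix(0L, n, n_libraries,
                   dimnames = list(truth$id,
                                   paste0("lib", seq_len(n_libraries))))
  host <- truth$class == "cnidarian"
  counts[host, ] <- rnbinom(sum(host) * n_libraries, mu = host_mean,
                            size = dispersion)
  nonhost <- which(!host)
  contam <- nonhost[runif(length(nonhost)) < contamination_rate]
  if (length(contam))
    counts[contam, ] <- rnbinom(length(contam) * n_libraries,
                                mu = contam_mean, size = 1)
  as.data.frame(counts)
}

#' Write a read-count table to TSV
#'
#' @param counts Count data.frame (rownames = contig ids).
#' @param path Output path.
#' @param header Optional named character vector of `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, header = character()) {
  df <- data.frame(contig_id = rownames(counts), counts,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, header)
}
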