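#' Configuration for an end-to-end run
#'
#' Collects every knob of the workflow in one object. With the default
#' `contigs = NULL` the run is fully synthetic: a labelled corpus, mock
#' hit tables and a genomic read-count table are generated from the seed.
#' Supplying file paths instead runs the same pipeline on user data (a
#' truth table is then required to train, or a pre-trained model can be
#' given).
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed used for every stochastic step.
#' @param n_per_class_per_bin Synthetic corpus size per class and bin
#'   (default 50).
#' @param train_fraction Fraction of each class/bin routed to training
#'   (default 0.4; an equal fraction goes to the test set and the rest to
#'   the custom-database pool).
#' @param bins Length-bin table.
#' @param min_bitscore Frame-inference bitscore threshold.
#' @param evidence_cutoff Genomic-evidence mean-count cutoff.
#' @param kernel,cost SVM settings (see [train_classifier()]).
#' @param hit_accuracy,hit_prob,host_mean,contamination_rate Synthetic
#'   generator settings (see [generate_hits()] and
#'   [generate_read_counts()]).
#' @param contigs,hits,custom_hits,counts,truth Optional input paths
#'   (FASTA / TSVs) replacing the synthetic stages.
#' @return A `symbiosort_config` list.
#' @export
run_config <- function(out_dir, seed = 1, n_per_class_per_bin = 50,
                       train_fraction = 0.4, bins = length_bins(),
                       min_bitscore = 50, evidence_cutoff = 10,
                       kernel = "radial", cost = 1, hit_accuracy = 0.9,
                       hit_prob = 0.8, host_mean = 200,
                       contamination_rate = 0.05,
                       contigs = NULL, hits = NULL, custom_hits = NULL,
                       counts = NULL, truth = NULL) {
  for (p in c(contigs, hits, custom_hits, counts, truth))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_per_class_per_bin = n_per_class_per_bin,
                 train_fraction = train_fraction, bins = bins,
                 min_bitscore = min_bitscore,
                 evidence_cutoff = evidence_cutoff, kernel = kernel,
                 cost = cost, hit_accuracy = hit_accuracy,
                 hit_prob = hit_prob, host_mean = host_mean,
                 contamination_rate = contamination_rate,
                 contigs = contigs, hits = hits, custom_hits = custom_hits,
                 counts = counts, truth = truth),
            class = "symbiosort_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full workflow
#'
#' Simulate (or ingest) contigs, hit tables and read counts; compute
#' feature vectors; build balanced train/test splits; train the four-class
#' SVM; classify every contig; reconcile with genomic evidence; and write
#' all artifacts plus a machine-readable manifest to the output directory.
#' Re-running with an identical configuration reproduces every data
#' output byte-identically.
#'
#' Outputs written: `contigs.fasta`, `hits.tsv`, `custom_hits.tsv`,
#' `counts.tsv`, `features.tsv`, `model.rds`, `classifications.tsv`,
#' `accuracy_by_bin.tsv` (when truth is known), `consensus.tsv`,
#' `discordance.tsv`, `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`truth`,
#'   `splits`, `model`, `classified`, `evaluation`, `consensus`,
#'   `discordance`, `manifest`).
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "symbiosort_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(seed = as.character(config$seed))
  out <- function(f) file.path(config$out_dir, f)
  synthetic <- is.null(config$contigs)

  inputs <- stage("inputs", {
    if (synthetic) {
      profiles <- taxon_profiles(hit_accuracy = config$hit_accuracy)
      corpus <- generate_corpus(profiles, config$n_per_class_per_bin,
                                seed = config$seed, bins = config$bins)
      hits <- generate_hits(corpus, hit_accuracy = config$hit_accuracy,
                            k_max = 5, hit_prob = config$hit_prob,
                            seed = config$seed + 1L)
      custom <- generate_hits(corpus, hit_accuracy = config$hit_accuracy,
                              k_max = 1, hit_prob = config$hit_prob,
                              seed = config$seed + 2L)
      counts <- generate_read_counts(
        corpus, host_mean = config$host_mean,
        contamination_rate = config$contamination_rate,
        seed = config$seed + 3L)
      write_contigs(corpus$contigs, out("contigs.fasta"))
      write_hits(hits, out("hits.tsv"), hdr)
      write_hits(custom, out("custom_hits.tsv"), hdr)
      write_count_table(counts, out("counts.tsv"), hdr)
      list(contigs = corpus$contigs, truth = corpus$truth, hits = hits,
           custom = custom, counts = counts)
    } else {
      contigs <- read_contigs(config$contigs)
      hits <- if (is.null(config$hits)) {
        warning("no hit table supplied; homology features fall back to ",
                "none-of-the-above")
        NULL
      } else read_hits(config$hits)
      custom <- if (is.null(config$custom_hits)) NULL else
        read_hits(config$custom_hits)
      counts <- if (is.null(config$counts)) {
        data.frame(lib1 = integer(0))
      } else read_count_table(config$counts)
      truth <- if (is.null(config$truth)) NULL else read_tsv(config$truth)
      list(contigs = contigs, truth = truth, hits = hits, custom = custom,
           counts = counts)
    }
  })

  features <- stage("features", {
    f <- contig_features(inputs$contigs, inputs$hits, inputs$custom,
                         min_bitscore = config$min_bitscore)
    write_feature_table(f, out("features.tsv"), hdr)
    f
  })

  if (is.null(inputs$truth))
    stop("stage 'split' failed: training requires a truth table")
  splits <- stage("split", {
    per_bin <- max(1L, floor(config$n_per_class_per_bin *
                               config$train_fraction))
    sizes <- if (synthetic) rep(per_bin, nrow(config$bins)) else {
      counts_per <- table(inputs$truth$class,
                          bin_of(inputs$truth$length, config$bins))
      half_min <- floor(apply(counts_per, 2, min) / 2)[config$bins$label]
      pmax(1L, half_min)
    }
    build_training_sets(inputs$truth, config$bins, sizes,
                        seed = config$seed)
  })

  model <- stage("train", {
    m <- train_classifier(features[splits$train$id, , drop = FALSE],
                          splits$train$class, kernel = config$kernel,
                          cost = config$cost, seed = config$seed)
    write_model(m, out("model.rds"))
    m
  })

  classified <- stage("classify", {
    cl <- classify_contigs(model, features)
    write_tsv(cl, out("classifications.tsv"), hdr)
    cl
  })

  evaluation <- stage("evaluate", {
    test_pred <- classified$predicted[match(splits$test$id,
                                            classified$contig_id)]
    ev <- evaluate_by_bin(test_pred, splits$test$class, splits$test$length,
                          config$bins)
    write_tsv(ev, out("accuracy_by_bin.tsv"), hdr)
    ev
  })

  consensus <- stage("consensus", {
    rec <- consensus_records(classified, inputs$counts,
                             cutoff = config$evidence_cutoff)
    write_consensus(rec, out("consensus.tsv"), hdr)
    rec
  })

  discordance <- stage("report", {
    d <- discordance_table(consensus)
    write_tsv(d, out("discordance.tsv"), hdr)
    d
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
    m <- list(
      package = "symbiosort",
      version = as.character(utils::packageVersion("symbiosort")),
      seed = config$seed,
      parameters = config[setdiff(names(config),
                                  c("out_dir", "bins"))],
      bins = config$bins,
      files = data.frame(
        file = files,
        md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
        stringsAsFactors = FALSE))
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    m
  })

  invisible(list(truth = inputs$truth, splits = splits, model = model,
                 classified = classified, evaluation = evaluation,
                 consensus = consensus, discordance = discordance,
                 manifest = manifest))
}
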