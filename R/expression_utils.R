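#' Relative expression from CT and primer efficiency
#'
#' Back-calculates a relative template amount from a qPCR critical
#' threshold: `(1 + efficiency)^(-CT)`. With a perfectly efficient primer
#' (efficiency 1, i.e. doubling each cycle) one extra cycle halves the
#' value; lower CT means more starting template.
#'
#' @param efficiency Per-cycle amplification gain in (0, 1]; 1 = perfect
#'   doubling. Typical assay values are 0.9-1.0.
#' @param ct Critical threshold cycle number (>= 0).
#' @return Positive relative expression values.
#' @export
relative_expression <- function(efficiency, ct) {
  if (any(efficiency <= 0 | efficiency > 1))
    stop("primer efficiency must be in (0, 1]")
  if (any(ct < 0)) stop("CT must be non-negative")
  (1 + efficiency)^(-ct)
}

#' Geometric-mean normalisation factor
#'
#' Per-sample normalisation factor computed as the geometric mean of the
#' relative expression values of at least two reference (housekeeping)
#' genes.
#'
#' @param reference_expressions Numeric vector (>= 2 strictly positive
#'   values).
#' @return The geometric mean.
#' @export
normalization_factor <- function(reference_expressions) {
  if (length(reference_expressions) < 2)
    stop("need >= 2 reference genes")
  if (any(reference_expressions <= 0))
    stop("reference expression values must be strictly positive")
  exp(mean(log(reference_expressions)))
}

#' Log2 fold-change between conditions
#'
#' `log2(symbiotic / aposymbiotic)` of normalised relative expression
#' values; positive values mean higher expression in the symbiotic state.
#'
#' @param sym_norm_expr,apo_norm_expr Strictly positive normalised
#'   expression values.
#' @return Log2 fold-changes.
#' @export
log2_fold_change <- function(sym_norm_expr, apo_norm_expr) {
  if (any(sym_norm_expr <= 0) || any(apo_norm_expr <= 0))
    stop("expression values must be strictly positive")
  log2(sym_norm_expr / apo_norm_expr)
}

#' Full qPCR quantification workflow
#'
#' From a long-format measurement table, averages technical replicates on
#' the CT scale (each cycle is a log2 step, so averaging CTs is a
#' geometric mean of template amounts), converts to relative expression,
#' normalises each condition by the geometric mean of the declared
#' reference genes, and reports the log2 fold-change of each gene in the
#' symbiotic relative to the aposymbiotic condition.
#'
#' @param measurements Data.frame with columns `gene`, `condition`
#'   (`"symbiotic"` / `"aposymbiotic"`), `replicate`, `ct`, `efficiency`.
#' @param reference_genes Character vector (>= 2) of reference gene ids
#'   present in the table.
#' @return Data.frame with `gene`, `expr_symbiotic`, `expr_aposymbiotic`
#'   (normalised relative expression) and `log2_fc`.
#' @export
qpcr_expression <- function(measurements, reference_genes) {
  need <- c("gene", "condition", "replicate", "ct", "efficiency")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("qPCR table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(measurements$condition),
                 c("symbiotic", "aposymbiotic"))
  if (length(bad)) stop("unknown conditions: ", paste(bad, collapse = ", "))
  if (length(reference_genes) < 2)
    stop("need >= 2 reference genes")
  if (!all(reference_genes %in% measurements$gene))
    stop("reference genes absent from the table: ",
         paste(setdiff(reference_genes, measurements$gene), collapse = ", "))

  agg <- stats::aggregate(ct ~ gene + condition + efficiency,
                          data = measurements, FUN = mean)
  agg$expr <- relative_expression(agg$efficiency, agg$ct)

  per_cond <- lapply(c("symbiotic", "aposymbiotic"), function(cond) {
    sub <- agg[agg$condition == cond, , drop = FALSE]
    nf <- normalization_factor(sub$expr[sub$gene %in% reference_genes])
    setNames(sub$expr / nf, sub$gene)
  })
  names(per_cond) <- c("symbiotic", "aposymbiotic")

  genes <- sort(intersect(names(per_cond$symbiotic),
                          names(per_cond$aposymbiotic)))
  data.frame(gene = genes,
             expr_symbiotic = unname(per_cond$symbiotic[genes]),
             expr_aposymbiotic = unname(per_cond$aposymbiotic[genes]),
             log2_fc = log2_fold_change(per_cond$symbiotic[genes],
                                        per_cond$aposymbiotic[genes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a qPCR measurement table
#'
#' TSV with columns `gene`, `condition`, `replicate`, `ct`, `efficiency`.
#'
#' @param path Path to the TSV.
#' @return Data.frame of measurements.
#' @export
read_qpcr_table <- function(path) {
  tab <- read_tsv(path)
  need <- c("gene", "condition", "replicate", "ct", "efficiency")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("qPCR table missing columns: ", paste(miss, collapse = ", "))
  tab
}
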