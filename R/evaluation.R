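# BEELINE-protocol evaluation: candidate universe, average precision, AUPRC
# ratio, early precision (ratio), AUROC. Ties are handled as blocks: all
# candidates sharing a score are processed together, which realizes the
# "unique predictions" form of the discretized precision-recall sum.

#' Enumerate the candidate edge universe
#'
#' All ordered (TF, gene) pairs for every TF and every gene — including a
#' TF paired with itself, matching the benchmark convention (e.g. 410 TFs x
#' 1,410 genes = 578,100 candidate edges).
#'
#' @param gene_names Character vector of genes in the expression data.
#' @param tf_names Character vector of regulator-eligible genes (must be a
#'   subset of `gene_names`).
#' @return Tibble with columns `regulator` and `target`.
#' @export
candidate_universe <- function(gene_names, tf_names) {
  gene_names <- as.character(gene_names)
  tf_names <- unique(as.character(tf_names))
  if (length(tf_names) == 0) stop("TF set is empty", call. = FALSE)
  missing <- setdiff(tf_names, gene_names)
  if (length(missing) > 0) {
    stop("TFs absent from gene set: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  tidyr::expand_grid(regulator = tf_names, target = gene_names)
}

check_score_set <- function(scores, labels, need_negative = FALSE) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  labels <- as.logical(labels)
  if (!any(labels)) stop("no positive labels", call. = FALSE)
  if (need_negative && all(labels)) stop("no negative labels", call. = FALSE)
  labels
}

# per-block cumulative counts, descending score
score_blocks <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  ends <- cumsum(rle(s)$lengths)
  cum_tp <- cumsum(l)[ends]
  list(tp = diff(c(0, cum_tp)), size = diff(c(0, ends)),
       cum_tp = cum_tp, cum_n = ends)
}

#' Average precision (area under the precision-recall curve)
#'
#' The discretized, non-interpolated sum `AP = sum P_k (R_k - R_{k-1})`
#' over unique score levels, candidates sorted by decreasing score and tied
#' scores processed as one block (precision and recall evaluated after the
#' whole block).
#'
#' @param scores Numeric prediction scores, higher = more confident.
#' @param labels Logical (or 0/1) true labels; at least one positive.
#' @return Average precision in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- check_score_set(scores, labels)
  bl <- score_blocks(scores, labels)
  pos <- sum(labels)
  prec <- bl$cum_tp / bl$cum_n
  rec <- bl$cum_tp / pos
  sum(prec * diff(c(0, rec)))
}

#' AUPRC ratio
#'
#' Average precision divided by the expected average precision of a random
#' predictor, which equals the positive-class fraction. A value of 1 means
#' chance performance.
#'
#' @inheritParams auprc
#' @return Nonnegative ratio.
#' @export
auprc_ratio <- function(scores, labels) {
  labels <- check_score_set(scores, labels)
  auprc(scores, labels) / (sum(labels) / length(labels))
}

#' Early precision and early precision ratio
#'
#' Early precision (EP) is the fraction of true positives among the top-k
#' candidates, where k is the number of positives. If the k-th position
#' falls inside a tied block, the block contributes its positives pro rata.
#' The ratio (EPR) divides EP by the positive-class fraction (the edge
#' density of the ground-truth network).
#'
#' @inheritParams auprc
#' @return `early_precision()`: EP in \[0, 1\]; `early_precision_ratio()`:
#'   nonnegative ratio.
#' @export
early_precision <- function(scores, labels) {
  labels <- check_score_set(scores, labels)
  k <- sum(labels)
  bl <- score_blocks(scores, labels)
  full <- which(bl$cum_n <= k)
  tp <- if (length(full)) bl$cum_tp[max(full)] else 0
  taken <- if (length(full)) bl$cum_n[max(full)] else 0
  if (taken < k) {
    nxt <- if (length(full)) max(full) + 1L else 1L
    tp <- tp + (k - taken) / bl$size[nxt] * bl$tp[nxt]
  }
  tp / k
}

#' @rdname early_precision
#' @export
early_precision_ratio <- function(scores, labels) {
  labels <- check_score_set(scores, labels)
  early_precision(scores, labels) / (sum(labels) / length(labels))
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a uniformly random
#' positive outscores a uniformly random negative, ties counted one half.
#'
#' @inheritParams auprc
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_score_set(scores, labels, need_negative = TRUE)
  pos <- sum(labels); neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Evaluate an inferred network against a ground truth
#'
#' Builds the candidate universe from the truth's TF list and the network's
#' genes, scores each candidate by the absolute inferred weight, labels it
#' by membership in the ground-truth edge set, and computes all metrics.
#' Ground-truth edges whose endpoints are absent from the network's gene
#' set are dropped before k is computed; predicted edges outside the
#' candidate universe are ignored. Gene matching is case-folded.
#'
#' @param network An [adjacency_matrix()], `dazzle_fit`, `dazzle_ensemble`,
#'   or a tibble of scored edges (`regulator`, `target`, and `weight` or
#'   `score`).
#' @param truth A `grn_truth` (see [ground_truth()]) or a list with
#'   `edges` (data frame of regulator/target) and `tf_names`.
#' @return One-row tibble: `auprc`, `auprc_ratio`, `early_precision`,
#'   `early_precision_ratio`, `auroc`, `n_candidates`, `n_positives`.
#' @export
evaluate_grn <- function(network, truth) {
  if (inherits(network, c("dazzle_fit", "dazzle_ensemble"))) {
    network <- get_adjacency(network)
  }
  if (is.matrix(network)) {
    A <- unclass(network)
    genes <- tolower(rownames(A))
    scores_lookup <- function(reg, tgt) {
      abs(A[cbind(match(reg, genes), match(tgt, genes))])
    }
  } else {
    ed <- tibble::as_tibble(network)
    sc <- if ("score" %in% names(ed)) ed$score else abs(ed$weight)
    key <- paste(tolower(ed$regulator), tolower(ed$target), sep = "\r")
    genes <- unique(c(tolower(ed$regulator), tolower(ed$target)))
    scores_lookup <- function(reg, tgt) {
      v <- sc[match(paste(reg, tgt, sep = "\r"), key)]
      v[is.na(v)] <- 0
      v
    }
  }
  tfs <- intersect(tolower(truth$tf_names), genes)
  if (length(tfs) == 0) {
    stop("no ground-truth TF appears in the network's gene set", call. = FALSE)
  }
  uni <- candidate_universe(genes, tfs)
  te <- truth$edges
  truth_key <- paste(tolower(te$regulator), tolower(te$target), sep = "\r")
  truth_key <- truth_key[tolower(te$regulator) %in% genes &
                           tolower(te$target) %in% genes]
  labels <- paste(uni$regulator, uni$target, sep = "\r") %in% truth_key
  scores <- scores_lookup(uni$regulator, uni$target)
  tibble::tibble(
    auprc = auprc(scores, labels),
    auprc_ratio = auprc_ratio(scores, labels),
    early_precision = early_precision(scores, labels),
    early_precision_ratio = early_precision_ratio(scores, labels),
    auroc = auroc(scores, labels),
    n_candidates = nrow(uni),
    n_positives = sum(labels)
  )
}
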