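# Shared fixtures and independent oracles used across test files.

# small raw-count matrix with named genes/cells
tiny_counts <- function() {
  expression_matrix(
    matrix(c(1, 0, 2,
             0, 0, 5), nrow = 2, byrow = TRUE),
    gene_names = c("g1", "g2", "g3"),
    cell_ids = c("c1", "c2")
  )
}

# brute-force average precision: walk unique score levels in descending
# order, recompute precision/recall after each whole tied block
oracle_auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  lv <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels)
  ap <- 0
  prev_recall <- 0
  for (s in lv) {
    taken <- scores >= s
    precision <- sum(labels[taken]) / sum(taken)
    recall <- sum(labels[taken]) / pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# exhaustive positive x negative pair enumeration
oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  p <- scores[labels]
  n <- scores[!labels]
  tot <- 0
  for (a in p) for (b in n) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(p) * length(n))
}

# early precision with pro-rata tie handling, by direct enumeration
oracle_early_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  k <- sum(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- 0; taken <- 0; i <- 1
  while (taken < k && i <= length(s)) {
    block <- which(s == s[i])
    bsize <- length(block)
    btp <- sum(l[block])
    if (taken + bsize <= k) {
      tp <- tp + btp
      taken <- taken + bsize
    } else {
      tp <- tp + (k - taken) / bsize * btp
      taken <- k
    }
    i <- max(block) + 1
  }
  tp / k
}

# a small trained-free adjacency with known structure
toy_adjacency <- function() {
  A <- matrix(0, 4, 4, dimnames = rep(list(paste0("g", 1:4)), 2))
  A["g1", "g2"] <- 0.5
  A["g1", "g3"] <- -0.3
  A["g2", "g3"] <- 0.2
  adjacency_matrix(A)
}
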