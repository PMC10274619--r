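# UPGMA (size-weighted average linkage) clustering of elevation bands,
# with deterministic tie-breaking, tree cutting and Newick export.

#' UPGMA clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with unweighted pair-group average linkage:
#' repeatedly merge the two clusters with minimum average dissimilarity,
#' updating \eqn{d(A \cup B, C) = (n_A d(A,C) + n_B d(B,C)) / (n_A + n_B)}.
#' When several pairs tie for the minimum, the pair whose (smallest-leaf,
#' smallest-leaf) label pair sorts lexicographically first is merged, so
#' results are deterministic across platforms. Merge heights are the raw
#' merge dissimilarities (halving to ultrametric branch lengths happens
#' only at Newick export).
#'
#' @param D A `beta_matrix`, `dist`, or symmetric numeric matrix with
#'   labels; must be NaN-free.
#' @return An `elev_dendrogram`: `labels`, an [stats::hclust]-style
#'   `merge` matrix, `height` vector, and `order`.
#' @export
upgma_tree <- function(D) {
  M <- if (inherits(D, "beta_matrix")) D$D else as.matrix(D)
  if (is.null(rownames(M))) rownames(M) <- colnames(M) <- seq_len(nrow(M))
  n <- nrow(M)
  if (n < 2L) stop("upgma_tree needs at least 2 items")
  if (anyNA(M) || any(!is.finite(M))) stop("dissimilarity matrix contains NA/NaN")
  if (max(abs(M - t(M))) > 1e-12) stop("dissimilarity matrix is not symmetric")
  labels <- rownames(M)

  # active cluster bookkeeping: node id (negative = leaf, positive = merge),
  # size, and the lexicographically smallest member label (tie-break key)
  active <- seq_len(n)
  node <- -seq_len(n)
  size <- rep(1L, n)
  key <- labels
  d <- M
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- d[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    m <- min(sub)
    cand <- which(sub <= m + 1e-15, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      # lexicographically smallest (sorted label pair) wins
      keys <- t(apply(cand, 1L, function(p) {
        sort(c(key[active[p[1]]], key[active[p[2]]]))
      }))
      pick <- order(keys[, 1], keys[, 2])[1]
    } else {
      pick <- 1L
    }
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    # child with the lexicographically smaller member label goes left
    merge[step, ] <- if (key[i] <= key[j]) c(node[i], node[j])
                     else c(node[j], node[i])
    height[step] <- d[i, j]
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      dn <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- dn
      d[others, i] <- dn
    }
    size[i] <- size[i] + size[j]
    node[i] <- step
    key[i] <- min(key[i], key[j])
    active <- setdiff(active, j)
  }

  ord <- .leaf_order(merge, n)
  structure(list(labels = labels, merge = merge, height = height,
                 order = ord, method = "upgma"),
            class = "elev_dendrogram")
}

.leaf_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' @export
print.elev_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram: ", length(x$labels), " leaves, merge heights ",
      round(min(x$height), 3), "..", round(max(x$height), 3), "\n", sep = "")
  invisible(x)
}

#' Convert to a base-R hclust object
#' @param x An `elev_dendrogram`.
#' @param ... Unused.
#' @return An [stats::hclust] object (method `"average"`).
#' @export
as.hclust.elev_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "beta_cc"),
            class = "hclust")
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` highest merges; ties in merge height are resolved
#' by merge order (earlier merges are kept intact).
#'
#' @param t An `elev_dendrogram`.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return Named integer vector: leaf label -> group id (groups numbered
#'   by first appearance in leaf-label order).
#' @export
cut_tree <- function(t, k) {
  n <- length(t$labels)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  stats::cutree(as.hclust.elev_dendrogram(t), k = k)
}

#' Cophenetic distances of a dendrogram
#' @param t An `elev_dendrogram`.
#' @return A [stats::dist] of cophenetic (merge-height) distances.
#' @export
cophenetic_distances <- function(t) {
  stats::cophenetic(as.hclust.elev_dendrogram(t))
}

.newick_quote <- function(lab) {
  if (grepl("[ ()\\[\\]:;,']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

#' Export a dendrogram as a Newick string
#'
#' Produces a rooted ultrametric Newick tree in which each leaf-to-node
#' path length equals half the node's merge height, so cophenetic
#' distances on the exported tree equal the original merge heights.
#'
#' @param t An `elev_dendrogram`.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(t, digits = 10) {
  fmt <- function(x) sprintf("%.*g", digits, x)
  # depth of a node = merge height / 2; leaf depth = 0
  node_str <- function(node, parent_depth) {
    if (node < 0L) {
      lab <- .newick_quote(t$labels[-node])
      return(paste0(lab, ":", fmt(parent_depth)))
    }
    depth <- t$height[node] / 2
    kids <- c(node_str(t$merge[node, 1], depth),
              node_str(t$merge[node, 2], depth))
    paste0("(", paste(kids, collapse = ","), "):",
           fmt(parent_depth - depth))
  }
  root <- nrow(t$merge)
  depth <- t$height[root] / 2
  kids <- c(node_str(t$merge[root, 1], depth),
            node_str(t$merge[root, 2], depth))
  paste0("(", paste(kids, collapse = ","), ");")
}

#' Write the merge table as TSV
#'
#' @param t An `elev_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merge_table <- function(t, path) {
  sizes <- integer(nrow(t$merge))
  sz <- function(node) if (node < 0L) 1L else sizes[node]
  for (i in seq_len(nrow(t$merge))) {
    sizes[i] <- sz(t$merge[i, 1]) + sz(t$merge[i, 2])
  }
  tab <- data.frame(left = t$merge[, 1], right = t$merge[, 2],
                    height = t$height, size = sizes)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
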