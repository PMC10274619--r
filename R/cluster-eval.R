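# Number-of-groups selection by the gap statistic (dissimilarity form,
# range-shuffle reference null) and per-group support by clusterwise
# Jaccard bootstrap over species resampling.

#' Pooled within-group dispersion of a partition
#'
#' The dissimilarity-based dispersion used by the gap statistic:
#' \deqn{W = \sum_r \frac{1}{2 n_r} \sum_{i,j \in r} D_{ij}}
#' where the inner sum runs over all ordered pairs within group `r`.
#' Singleton groups contribute zero.
#'
#' @param D A `beta_matrix` or symmetric dissimilarity matrix.
#' @param membership Named group vector covering all labels of `D`.
#' @return Nonnegative scalar dispersion.
#' @export
within_dispersion <- function(D, membership) {
  M <- if (inherits(D, "beta_matrix")) D$D else as.matrix(D)
  labs <- rownames(M)
  if (!all(labs %in% names(membership))) {
    stop("membership does not cover all labels")
  }
  g <- membership[labs]
  W <- 0
  for (grp in unique(g)) {
    idx <- which(g == grp)
    if (length(idx) > 1L) {
      W <- W + sum(M[idx, idx]) / (2 * length(idx))
    }
  }
  W
}

# log W with a floor so degenerate (zero-dispersion) partitions stay finite
.log_w <- function(w) log(max(w, .Machine$double.eps))

# dispersion curve for k = 1..k_max from one band matrix
.dispersion_curve <- function(occ, k_max) {
  bm <- beta_matrix(occ)
  tr <- upgma_tree(bm)
  vapply(seq_len(k_max), function(k) {
    .log_w(within_dispersion(bm, cut_tree(tr, k)))
  }, numeric(1))
}

# reference matrix under the chosen null.
# "shift": bounded range shuffle -- each species keeps its observed
#   occupancy pattern (breadth, cohesion, number of occupied bands), the
#   pattern is randomly reflected and slid to a uniform random position
#   along the gradient; destroys the cross-species alignment of range
#   edges (the zonation signal) while preserving range cohesion.
# "prevalence"/"uniform": independent Bernoulli per cell with per-species
#   marginal prevalence (or p = 0.5); destroys cohesion as well.
# Empty rows/columns in a draw get one presence planted so pairwise
# dissimilarity stays defined and dimensions stay fixed.
.reference_matrix <- function(occ,
                              null = c("shift", "prevalence", "uniform")) {
  null <- match.arg(null)
  nb <- nrow(occ); ns <- ncol(occ)
  if (null == "shift") {
    ref <- occ
    ref[] <- 0L
    for (j in seq_len(ns)) {
      idx <- which(occ[, j] == 1L)
      pat <- idx - min(idx)
      if (stats::runif(1) < 0.5) pat <- max(pat) - rev(pat)
      start <- sample.int(nb - max(pat), 1L)
      ref[start + pat, j] <- 1L
    }
  } else {
    p <- if (null == "prevalence") colMeans(occ) else rep(0.5, ns)
    ref <- matrix(stats::rbinom(nb * ns, 1L, rep(p, each = nb)), nb, ns,
                  dimnames = dimnames(occ))
    for (jj in which(colSums(ref) == 0L)) ref[sample.int(nb, 1L), jj] <- 1L
  }
  for (ii in which(rowSums(ref) == 0L)) ref[ii, sample.int(ns, 1L)] <- 1L
  ref
}

#' Select the number of elevational groups by the gap statistic
#'
#' For each candidate `k` the observed bands are clustered (UPGMA on total
#' beta) and the log within-group dispersion recorded; `B_ref` reference
#' band matrices are drawn from a null model that destroys elevational
#' structure, and put through the identical pipeline. The default null is
#' a bounded range shuffle: every species keeps its observed occupancy
#' pattern (breadth, cohesion) but the pattern is randomly reflected and
#' slid to a uniform random position along the band axis, so only the
#' cross-species alignment of ranges -- the zonation signal -- is
#' destroyed. Bernoulli nulls that also destroy range cohesion are
#' available as options. Then `gap(k)` is the mean reference log-dispersion minus the
#' observed one, with simulation error
#' `s_k = sd(log W*) * sqrt(1 + 1/B_ref)`. The default selection rule is
#' the one-standard-error rule: the smallest `k` with
#' `gap(k) >= gap(k+1) - s_(k+1)`; `k_selected = 1` means no elevational
#' groups are detected.
#'
#' @param M A `band_matrix`.
#' @param k_max Largest group count examined (default
#'   `min(10, n bands - 1)`).
#' @param B_ref Number of reference datasets.
#' @param seed Integer seed; the whole computation is reproducible
#'   bit-for-bit given (inputs, seed, B_ref).
#' @param null Reference null: `"shift"` (bounded range shuffle,
#'   default), `"prevalence"` (independent Bernoulli with per-species
#'   marginal prevalence) or `"uniform"` (Bernoulli p = 0.5).
#' @param rule `"1se"` (default) or `"globalmax"`.
#' @return A `gap_result`: `k_selected`, `gap`, `s_k`, `logW`,
#'   `logW_ref_mean`, plus bookkeeping (`k_max`, `B_ref`, `seed`, `rule`,
#'   `null`).
#' @export
gap_select_k <- function(M, k_max = NULL, B_ref = 1000L, seed = 1L,
                         null = c("shift", "prevalence", "uniform"),
                         rule = c("1se", "globalmax")) {
  null <- match.arg(null); rule <- match.arg(rule)
  occ <- M$occupancy
  nb <- nrow(occ)
  if (nb < 2L) stop("gap_select_k needs at least 2 bands")
  if (is.null(k_max)) k_max <- min(10L, nb - 1L)
  if (k_max >= nb) stop("k_max must be smaller than the number of bands")
  set.seed(seed)
  logW <- .dispersion_curve(occ, k_max)
  logW_ref <- matrix(NA_real_, B_ref, k_max)
  for (b in seq_len(B_ref)) {
    logW_ref[b, ] <- .dispersion_curve(.reference_matrix(occ, null), k_max)
  }
  gap <- colMeans(logW_ref) - logW
  s_k <- apply(logW_ref, 2, stats::sd) * sqrt(1 + 1 / B_ref)
  k_selected <- if (rule == "globalmax") {
    which.max(gap)
  } else {
    sel <- k_max
    for (k in seq_len(k_max - 1L)) {
      if (gap[k] >= gap[k + 1L] - s_k[k + 1L]) { sel <- k; break }
    }
    sel
  }
  structure(list(k_selected = as.integer(k_selected), gap = gap, s_k = s_k,
                 logW = logW, logW_ref_mean = colMeans(logW_ref),
                 k_max = as.integer(k_max), B_ref = as.integer(B_ref),
                 seed = as.integer(seed), rule = rule, null = null),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat("Gap statistic (", x$null, " null, B_ref = ", x$B_ref, "): ",
      "k_selected = ", x$k_selected,
      if (x$k_selected == 1L) " (no groups detected)", "\n", sep = "")
  print(data.frame(k = seq_len(x$k_max), gap = round(x$gap, 4),
                   s_k = round(x$s_k, 4)), row.names = FALSE)
  invisible(x)
}

.jaccard_sets <- function(A, B) {
  u <- length(union(A, B))
  if (u == 0L) return(NA_real_)
  length(intersect(A, B)) / u
}

#' Bootstrap (clusterwise Jaccard) support for elevational groups
#'
#' Quantifies the stability of each of the `k` groups obtained from the
#' UPGMA tree: in each replicate the species pool is resampled with
#' replacement, bands left empty are dropped, the dissimilarity matrix,
#' tree and k-group cut are recomputed, and each original group is scored
#' by its best Jaccard match (on band memberships, ignoring bands missing
#' from the replicate) among the replicate's groups. `J_b` for a group is
#' its mean best-match Jaccard over replicates. `k = 1` gives `J_b = 1`
#' by construction.
#'
#' @param M A `band_matrix`.
#' @param t The UPGMA `elev_dendrogram` of `M`'s beta matrix, or `NULL`
#'   to compute it.
#' @param k Number of groups to evaluate.
#' @param B_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A `cluster_support`: `groups` (band-label list per group),
#'   `J_b` (per-group mean support), `k`, `B_boot`, `n_skipped`, `seed`.
#'   Replicates where fewer than 2 bands or fewer than `k` bands survive
#'   are skipped and counted; more than 50% skipped is an error.
#' @export
bootstrap_support <- function(M, t = NULL, k, B_boot = 1000L, seed = 1L) {
  occ <- M$occupancy
  if (is.null(t)) t <- upgma_tree(beta_matrix(occ))
  if (k < 1L) stop("k must be >= 1")
  memb <- cut_tree(t, k)
  groups <- split(names(memb), memb)
  if (k == 1L) {
    return(structure(list(groups = groups, J_b = stats::setNames(1, "1"),
                          k = 1L, B_boot = as.integer(B_boot),
                          n_skipped = 0L, seed = as.integer(seed)),
                     class = "cluster_support"))
  }
  set.seed(seed)
  ns <- ncol(occ)
  acc <- matrix(NA_real_, B_boot, length(groups))
  n_skipped <- 0L
  for (b in seq_len(B_boot)) {
    cols <- sample.int(ns, ns, replace = TRUE)
    boot <- occ[, cols, drop = FALSE]
    keep <- rowSums(boot) > 0L
    if (sum(keep) < 2L || sum(keep) < k) { n_skipped <- n_skipped + 1L; next }
    boot <- boot[keep, , drop = FALSE]
    bt <- upgma_tree(beta_matrix(boot))
    bmemb <- cut_tree(bt, k)
    bgroups <- split(names(bmemb), bmemb)
    present <- rownames(boot)
    for (g in seq_along(groups)) {
      orig <- intersect(groups[[g]], present)
      if (length(orig) == 0L) { acc[b, g] <- 0; next }
      acc[b, g] <- max(vapply(bgroups, .jaccard_sets, numeric(1), A = orig))
    }
  }
  if (n_skipped > B_boot / 2) {
    stop("more than half of bootstrap replicates degenerate (", n_skipped,
         "/", B_boot, ")")
  }
  J_b <- colMeans(acc, na.rm = TRUE)
  names(J_b) <- names(groups)
  structure(list(groups = groups, J_b = J_b, k = as.integer(k),
                 B_boot = as.integer(B_boot), n_skipped = n_skipped,
                 seed = as.integer(seed)),
            class = "cluster_support")
}

#' @export
print.cluster_support <- function(x, ...) {
  cat("Bootstrap cluster support (B =", x$B_boot, "):\n")
  for (g in seq_along(x$groups)) {
    cat("  group ", names(x$groups)[g], " [",
        paste(x$groups[[g]], collapse = ", "), "]  J_b = ",
        round(x$J_b[g], 3), "\n", sep = "")
  }
  invisible(x)
}
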