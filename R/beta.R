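# Jaccard-family beta-diversity partition: total dissimilarity (beta_cc)
# split into species turnover and richness-difference components.

#' Beta-diversity components for one pair of bands
#'
#' For two presence-absence vectors with `a` shared species, `b` species
#' unique to the first band and `c` unique to the second, the total
#' Jaccard-family dissimilarity is
#' \deqn{\beta_{cc} = (b + c) / (a + b + c)}
#' partitioned additively into species turnover
#' \deqn{\beta_{-3} = 2 \min(b, c) / (a + b + c)}
#' and richness difference
#' \deqn{\beta_{rich} = |b - c| / (a + b + c).}
#' The identity `beta_cc == beta_turn + beta_rich` holds exactly.
#'
#' @param x,y Binary (0/1 or logical) species incidence vectors of equal
#'   length; at least one must be non-empty.
#' @return A `beta_components` list: `a`, `b`, `c`, `beta_cc`,
#'   `beta_turn`, `beta_rich`.
#' @export
beta_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- as.logical(x); y <- as.logical(y)
  a <- sum(x & y)
  b <- sum(x & !y)
  cc <- sum(!x & y)
  if (a + b + cc == 0L) {
    stop("beta_pair undefined: both bands are empty")
  }
  n <- a + b + cc
  structure(list(a = a, b = b, c = cc,
                 beta_cc = (b + cc) / n,
                 beta_turn = 2 * min(b, cc) / n,
                 beta_rich = abs(b - cc) / n),
            class = "beta_components")
}

#' Pairwise beta-diversity matrix over elevation bands
#'
#' Computes `beta_cc` (and its turnover / richness-difference parts) for
#' every pair of bands in a band matrix, by exact set-bit arithmetic.
#'
#' @param M A `band_matrix` (or a plain binary matrix with row names).
#' @return A `beta_matrix` object: `labels`, symmetric zero-diagonal `D`
#'   (total beta), and component matrices `turn` and `rich`.
#' @export
beta_matrix <- function(M) {
  occ <- if (inherits(M, "band_matrix")) M$occupancy else as.matrix(M)
  if (nrow(occ) < 2L) stop("beta_matrix needs at least 2 bands")
  storage.mode(occ) <- "double"
  A <- tcrossprod(occ)                      # shared species counts
  s <- rowSums(occ)
  B <- matrix(s, nrow(occ), nrow(occ)) - A  # unique to row band
  C <- t(B)
  tot <- A + B + C
  if (any(tot == 0)) stop("beta_matrix undefined: a pair of empty bands")
  D <- (B + C) / tot
  Turn <- 2 * pmin(B, C) / tot
  Rich <- abs(B - C) / tot
  diag(D) <- 0; diag(Turn) <- 0; diag(Rich) <- 0
  labs <- rownames(occ)
  dimnames(D) <- dimnames(Turn) <- dimnames(Rich) <- list(labs, labs)
  structure(list(labels = labs, D = D, turn = Turn, rich = Rich),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("Beta dissimilarity matrix (total beta, Jaccard family): ",
      length(x$labels), " bands\n", sep = "")
  print(round(x$D, 3))
  invisible(x)
}

#' Convert a beta matrix to a `dist` object
#' @param m A `beta_matrix`.
#' @return A [stats::dist] of the total-beta values.
#' @export
as.dist.beta_matrix <- function(m, ...) stats::as.dist(m$D)

#' Serialize a beta matrix
#'
#' Writes the square total-beta matrix as TSV and, optionally, a
#' long-format component table (`band_i`, `band_j`, `beta_cc`,
#' `beta_turn`, `beta_rich`).
#'
#' @param bm A `beta_matrix`.
#' @param path Output TSV path.
#' @param components If `TRUE`, also write `<path>.components.tsv`.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path, components = FALSE) {
  utils::write.table(bm$D, path, sep = "\t", quote = FALSE, col.names = NA)
  if (components) {
    idx <- which(upper.tri(bm$D), arr.ind = TRUE)
    long <- data.frame(band_i = bm$labels[idx[, 1]],
                       band_j = bm$labels[idx[, 2]],
                       beta_cc = bm$D[idx],
                       beta_turn = bm$turn[idx],
                       beta_rich = bm$rich[idx])
    utils::write.table(long, paste0(path, ".components.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
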