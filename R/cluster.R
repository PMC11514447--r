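#' @title Consensus positional clustering
#' @name consensus_clustering
#' @description
#' Repeated k-means with correlation distance and component-wise median
#' centres, run over many rounds with random initial centres; rounds are
#' aligned to a reference round and a gene is assigned only when it falls
#' in the same aligned cluster in at least a configurable fraction of
#' rounds (the "occurrence").
NULL

# one k-means round: correlation distance (1 - Pearson), median centres.
# x: row-normalized matrix; xs: row-standardized (NA rows = constant).
.kmeans_round <- function(x, xs, k, max_iter) {
  n <- nrow(x); p <- ncol(x)
  nonconst <- !is.na(xs[, 1L])
  pool <- if (sum(nonconst) >= k) which(nonconst) else seq_len(n)
  centers <- x[sample(pool, k), , drop = FALSE]
  assign_prev <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    cs <- t(apply(centers, 1L, function(cc) {
      s <- stats::sd(cc)
      if (is.na(s) || s == 0) rep(NA_real_, p) else (cc - mean(cc)) / s
    }))
    D <- matrix(2, n, k)  # 1 - cor in [0, 2]
    ok_c <- !is.na(cs[, 1L])
    if (any(ok_c) && any(nonconst))
      D[nonconst, ok_c] <- 1 - (xs[nonconst, , drop = FALSE] %*%
                                  t(cs[ok_c, , drop = FALSE])) / (p - 1)
    # Euclidean fallback where Pearson is undefined (constant gene or centre)
    if (any(!nonconst) || any(!ok_c)) {
      for (j in which(!ok_c))
        D[, j] <- sqrt(rowSums((x - matrix(centers[j, ], n, p, byrow = TRUE))^2))
      if (any(!nonconst))
        for (j in which(ok_c))
          D[!nonconst, j] <- sqrt(rowSums((x[!nonconst, , drop = FALSE] -
            matrix(centers[j, ], sum(!nonconst), p, byrow = TRUE))^2))
    }
    assign <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) == 0L) {
        worst <- which.max(D[cbind(seq_len(n), assign)])
        centers[j, ] <- x[worst, ]
        assign[worst] <- j
      } else {
        centers[j, ] <- apply(x[members, , drop = FALSE], 2L, stats::median)
      }
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  list(assign = assign, centers = centers)
}

# greedy alignment of round centres to reference centres by highest
# correlation first; returns perm such that round cluster j maps to
# reference cluster perm[j]
.align_centers <- function(centers, ref) {
  k <- nrow(ref)
  sim <- matrix(-Inf, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    sa <- stats::sd(centers[a, ]); sb <- stats::sd(ref[b, ])
    sim[a, b] <- if (is.na(sa) || sa == 0 || is.na(sb) || sb == 0)
      -sqrt(sum((centers[a, ] - ref[b, ])^2)) else
        stats::cor(centers[a, ], ref[b, ])
  }
  perm <- integer(k)
  used_a <- logical(k); used_b <- logical(k)
  for (step in seq_len(k)) {
    sim2 <- sim
    sim2[used_a, ] <- -Inf; sim2[, used_b] <- -Inf
    best <- arrayInd(which.max(sim2), dim(sim2))
    perm[best[1L]] <- best[2L]
    used_a[best[1L]] <- TRUE; used_b[best[2L]] <- TRUE
  }
  perm
}

#' Consensus clustering of five-region occupancy
#'
#' Runs k-means (`k` clusters, 1 - Pearson correlation distance,
#' component-wise median centres, random initial centres) for `rounds`
#' rounds on row-normalized occupancy, aligns every round to the first by
#' greedy centre matching, and assigns each gene to its modal aligned
#' cluster only when the modal frequency ("occurrence") reaches
#' `occurrence_min`; otherwise the gene is `unassigned`. Consensus
#' clusters are labelled by the region of their centre's maximal
#' component.
#'
#' @param occupancy genes x 5 matrix (e.g. [occupancy_matrix()]), rows
#'   named by gene.
#' @param k clusters per round.
#' @param rounds number of rounds.
#' @param occurrence_min minimum modal frequency for assignment.
#' @param seed integer seed.
#' @param max_iter k-means iteration cap per round.
#' @return list with `assignments` (data frame `gene_id`, `cluster`,
#'   `label`, `occurrence`, `constant`), `centers` (consensus k x 5
#'   matrix) and `cluster_labels`.
#' @export
consensus_cluster <- function(occupancy, k = 5L, rounds = 200L,
                              occurrence_min = 0.70, seed = 1L,
                              max_iter = 100L) {
  occupancy <- as.matrix(occupancy)
  n <- nrow(occupancy)
  if (n < k) stop("need at least k = ", k, " genes, got ", n)
  # canonical internal order (by gene id) so results are exactly invariant
  # to the order genes are supplied in
  orig_names <- rownames(occupancy) %||% as.character(seq_len(n))
  ord_in <- order(orig_names)
  occupancy <- occupancy[ord_in, , drop = FALSE]
  rs <- rowSums(occupancy)
  x <- occupancy / ifelse(rs > 0, rs, 1)
  sds <- apply(x, 1L, stats::sd)
  constant <- is.na(sds) | sds == 0
  if (any(constant))
    message(sum(constant), " constant-occupancy gene(s): Euclidean fallback")
  xs <- (x - rowMeans(x)) / sds
  xs[constant, ] <- NA_real_

  votes <- matrix(0L, n, k)
  ref <- NULL
  center_sum <- matrix(0, k, ncol(x))
  center_n <- 0L
  all_centers <- array(0, c(rounds, k, ncol(x)))
  for (r in seq_len(rounds)) {
    set.seed(derive_seed(seed, paste0("cluster/", r)))
    fit <- .kmeans_round(x, xs, k, max_iter)
    if (is.null(ref)) {
      ref <- fit$centers
      perm <- seq_len(k)
    } else {
      perm <- .align_centers(fit$centers, ref)
    }
    aligned <- perm[fit$assign]
    votes[cbind(seq_len(n), aligned)] <- votes[cbind(seq_len(n), aligned)] + 1L
    all_centers[r, perm, ] <- fit$centers
  }
  consensus_centers <- apply(all_centers, c(2L, 3L), stats::median)
  colnames(consensus_centers) <- REGION_LABELS
  cluster_labels <- REGION_LABELS[max.col(consensus_centers, "first")]

  modal <- max.col(votes, ties.method = "first")
  occurrence <- votes[cbind(seq_len(n), modal)] / rounds
  label <- ifelse(occurrence >= occurrence_min, cluster_labels[modal],
                  "unassigned")
  assignments <- data.frame(
    gene_id = orig_names[ord_in],
    cluster = ifelse(occurrence >= occurrence_min, modal, NA_integer_),
    label = label, occurrence = occurrence, constant = constant,
    stringsAsFactors = FALSE)
  # report in the caller's original row order
  assignments <- assignments[match(orig_names, assignments$gene_id), ]
  rownames(assignments) <- NULL
  list(assignments = assignments, centers = consensus_centers,
       cluster_labels = cluster_labels)
}
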