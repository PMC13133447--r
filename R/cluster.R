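#' Channel adjacency graph from electrode positions
#'
#' Two channels are neighbors iff their Euclidean distance is at most
#' `radius` (default 0.04 m, i.e. a 4 cm channel neighborhood).
#'
#' @param positions channels x 3 matrix of electrode coordinates in meters
#'   (rownames = labels).
#' @param radius neighborhood radius in meters.
#' @return object of class `adjacency_graph` with `labels` and `pairs`
#'   (2-column matrix of neighbor index pairs, `i < j`).
#' @export
build_adjacency <- function(positions, radius = 0.04) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) stop("need at least 2 channels", call. = FALSE)
  if (any(!is.finite(positions))) {
    bad <- rownames(positions)[apply(!is.finite(positions), 1L, any)]
    stop("missing positions for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(stats::dist(positions))
  pairs <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  colnames(pairs) <- c("i", "j")
  structure(list(labels = rownames(positions) %||%
                   paste0("ch", seq_len(nrow(positions))),
                 pairs = pairs, radius = radius,
                 n_channels = nrow(positions)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d channels, %d edges (radius %.3g m)\n",
              x$n_channels, nrow(x$pairs), x$radius))
  invisible(x)
}

# connected components of supra-threshold (channel x time) cells under
# temporal contiguity + spatial adjacency; returns integer label matrix
# (0 = sub-threshold) and the number of clusters
label_clusters <- function(mask, pairs) {
  nc <- nrow(mask); nt <- ncol(mask)
  lin <- function(c, t) (t - 1L) * nc + c
  e_from <- integer(0); e_to <- integer(0)
  if (nt > 1L) {
    tm <- mask[, -nt, drop = FALSE] & mask[, -1L, drop = FALSE]
    w <- which(tm, arr.ind = TRUE)
    if (nrow(w)) {
      e_from <- c(e_from, lin(w[, 1L], w[, 2L]))
      e_to <- c(e_to, lin(w[, 1L], w[, 2L] + 1L))
    }
  }
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      both <- which(mask[pairs[k, 1L], ] & mask[pairs[k, 2L], ])
      if (length(both)) {
        e_from <- c(e_from, lin(pairs[k, 1L], both))
        e_to <- c(e_to, lin(pairs[k, 2L], both))
      }
    }
  }
  cells <- which(mask)
  labels <- matrix(0L, nc, nt)
  if (!length(cells)) return(list(labels = labels, n = 0L))
  parent <- seq_along(cells)
  idx_of <- integer(nc * nt)
  idx_of[cells] <- seq_along(cells)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(e_from)) for (k in seq_along(e_from)) {
    a <- find(idx_of[e_from[k]]); b <- find(idx_of[e_to[k]])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(cells), find, integer(1))
  comp <- match(roots, unique(roots))
  labels[cells] <- comp
  list(labels = labels, n = max(comp))
}

# cluster masses (sum of t) for positive and negative clusters of a t-map
cluster_masses <- function(tmap, thr, pairs) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > thr
    lab <- label_clusters(mask, pairs)
    if (lab$n > 0L) {
      for (k in seq_len(lab$n)) {
        cells <- which(lab$labels == k)
        out[[length(out) + 1L]] <-
          list(cells = cells, mass = sum(tmap[cells]), sign = sgn)
      }
    }
  }
  out
}

max_abs_mass <- function(tmap, thr, pairs) {
  cl <- cluster_masses(tmap, thr, pairs)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
}

# pointwise paired t statistics under sign flips: signs is n-vector of +-1
flip_t <- function(D, SS, signs) {
  n <- nrow(D)
  m <- drop(signs %*% D) / n
  v <- (SS - n * m^2) / (n - 1)
  m / sqrt(pmax(v, .Machine$double.eps) / n)
}

welch_t_map <- function(XA, XB) {
  na <- nrow(XA); nb <- nrow(XB)
  ma <- colMeans(XA); mb <- colMeans(XB)
  va <- (colSums(XA^2) - na * ma^2) / (na - 1)
  vb <- (colSums(XB^2) - nb * mb^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(pmax(se2, .Machine$double.eps))
  df <- se2^2 / pmax(va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)),
                     .Machine$double.eps)
  list(t = t, df = df)
}

#' Spatiotemporal cluster-based permutation test
#'
#' Compares two sets of per-subject channel x time waveforms with
#' family-wise error control: pointwise t-tests (paired, or Welch for
#' independent groups), clustering of supra-threshold points that are
#' contiguous in time or spatial neighbors under the adjacency graph
#' (positive and negative clusters formed separately from the signed t
#' map), cluster mass = sum of t within the cluster, and a Monte Carlo
#' null distribution of the maximum absolute cluster mass from sign flips
#' (paired) or group-label shuffles (independent). Corrected p-values are
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param A,B numeric arrays, subjects x channels x time. Paired designs
#'   need the same subjects (and order) in both.
#' @param design `"paired"` or `"independent"`.
#' @param adjacency an [build_adjacency()] graph (or `NULL` for
#'   temporal-only clustering).
#' @param cluster_alpha cluster-forming alpha for the pointwise two-sided
#'   t threshold.
#' @param n_perm number of permutations.
#' @param seed RNG seed; identical seeds give identical p-values.
#' @param times optional time axis (ms) for reporting.
#' @return object of class `cluster_result`: list of clusters (channel and
#'   time indices, mass, corrected p), the observed t map, the threshold,
#'   and the null distribution.
#' @export
cluster_perm_test <- function(A, B, design = c("paired", "independent"),
                              adjacency = NULL, cluster_alpha = 0.05,
                              n_perm = 1000, seed = 1, times = NULL) {
  design <- match.arg(design)
  stopifnot(length(dim(A)) == 3L, length(dim(B)) == 3L)
  if (any(dim(A)[2:3] != dim(B)[2:3]))
    stop("A and B must share channels and time axis", call. = FALSE)
  if (dim(A)[3] < 2L) stop("need at least 2 time samples", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations")
  nc <- dim(A)[2L]; nt <- dim(A)[3L]
  pairs <- if (is.null(adjacency)) NULL else adjacency$pairs
  if (!is.null(adjacency) && adjacency$n_channels != nc)
    stop("adjacency channel count mismatch", call. = FALSE)

  flat <- function(X) matrix(X, nrow = dim(X)[1L])   # subjects x (ch*time)

  set.seed(seed)
  if (design == "paired") {
    if (dim(A)[1L] != dim(B)[1L])
      stop("paired design needs matched subjects", call. = FALSE)
    n <- dim(A)[1L]
    D <- flat(A) - flat(B)
    SS <- colSums(D^2)
    t_obs <- flip_t(D, SS, rep(1, n))
    thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
    tmap <- matrix(t_obs, nc, nt)
    null_max <- vapply(seq_len(n_perm), function(p) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      max_abs_mass(matrix(flip_t(D, SS, s), nc, nt), thr, pairs)
    }, numeric(1))
  } else {
    na <- dim(A)[1L]; nb <- dim(B)[1L]
    X <- rbind(flat(A), flat(B))
    obs <- welch_t_map(X[seq_len(na), , drop = FALSE],
                       X[na + seq_len(nb), , drop = FALSE])
    thr_vec <- stats::qt(1 - cluster_alpha / 2, df = obs$df)
    # clustering uses the pointwise threshold map: normalize t by its own
    # critical value so a single unit threshold applies
    tmap <- matrix(obs$t / thr_vec, nc, nt)
    thr <- 1
    null_max <- vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(na + nb)
      pt <- welch_t_map(X[idx[seq_len(na)], , drop = FALSE],
                        X[idx[na + seq_len(nb)], , drop = FALSE])
      max_abs_mass(matrix(pt$t / stats::qt(1 - cluster_alpha / 2, pt$df),
                          nc, nt), thr, pairs)
    }, numeric(1))
  }

  clusters <- cluster_masses(tmap, thr, pairs)
  clusters <- lapply(clusters, function(cl) {
    ch <- ((cl$cells - 1L) %% nc) + 1L
    tt <- ((cl$cells - 1L) %/% nc) + 1L
    p <- (1 + sum(null_max >= abs(cl$mass))) / (n_perm + 1)
    list(channels = sort(unique(ch)), time_idx = sort(unique(tt)),
         cells = cbind(channel = ch, time = tt),
         mass = cl$mass, sign = cl$sign, p = p,
         time_span = if (!is.null(times)) range(times[tt]) else range(tt))
  })
  ord <- order(vapply(clusters, function(cl) -abs(cl$mass), numeric(1)))
  structure(list(clusters = clusters[ord], tmap = tmap, threshold = thr,
                 null_max = null_max, cluster_alpha = cluster_alpha,
                 n_perm = n_perm, design = design, times = times),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s design, %d clusters, %d permutations\n",
              x$design, length(x$clusters), x$n_perm))
  for (cl in x$clusters[seq_len(min(5L, length(x$clusters)))])
    cat(sprintf("  %s cluster: %d channels, mass %.1f, p = %.4g\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$channels), cl$mass, cl$p))
  invisible(x)
}

#' Smallest corrected p-value of a cluster result (1 if no clusters)
#' @param x a `cluster_result`.
#' @export
min_cluster_p <- function(x) {
  if (!length(x$clusters)) return(1)
  min(vapply(x$clusters, `[[`, numeric(1), "p"))
}

#' Serialize a cluster result
#'
#' JSON members (channel labels + time ms) and a TSV summary table
#' (cluster id, span, channel count, mass, corrected p).
#'
#' @param x a `cluster_result`.
#' @param labels channel labels.
#' @param json_path,tsv_path output paths (`NULL` to skip).
#' @export
write_cluster_result <- function(x, labels, json_path = NULL, tsv_path = NULL) {
  summ <- data.frame(
    cluster = seq_along(x$clusters),
    sign = vapply(x$clusters, function(cl)
      if (cl$sign > 0) "positive" else "negative", character(1)),
    span_lo = vapply(x$clusters, function(cl) cl$time_span[1], numeric(1)),
    span_hi = vapply(x$clusters, function(cl) cl$time_span[2], numeric(1)),
    n_channels = vapply(x$clusters, function(cl)
      length(cl$channels), integer(1)),
    mass = vapply(x$clusters, `[[`, numeric(1), "mass"),
    p = vapply(x$clusters, `[[`, numeric(1), "p"))
  if (!is.null(tsv_path))
    utils::write.table(summ, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    js <- lapply(x$clusters, function(cl) list(
      channels = labels[cl$channels],
      time = if (!is.null(x$times)) x$times[cl$time_idx] else cl$time_idx,
      mass = cl$mass, p = cl$p))
    jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summ)
}
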