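# adjacency graphs, cluster formation, permutation inference

test_that("adjacency edges follow Euclidean distance exactly", {
  pos <- rbind(a = c(0, 0, 0), b = c(0.03, 0, 0),
               c = c(0.03, 0.03, 0), d = c(0, 0.03, 0))
  adj0 <- build_adjacency(pos, 0)
  expect_equal(nrow(adj0$pairs), 0)
  adj <- build_adjacency(pos, 0.04)
  # square of side 3 cm: 4 side edges, no diagonals (4.24 cm)
  expect_equal(nrow(adj$pairs), 4)
  got <- apply(adj$pairs, 1, function(p)
    paste(sort(adj$labels[p]), collapse = "-"))
  expect_setequal(got, c("a-b", "b-c", "c-d", "a-d"))
  two <- build_adjacency(rbind(x = c(0, 0, 0), y = c(0.03, 0, 0)), 0.04)
  expect_equal(nrow(two$pairs), 1)
  bad <- pos; bad[2, 1] <- NA
  expect_error(build_adjacency(bad, 0.04), "b")
  expect_error(build_adjacency(pos[1, , drop = FALSE], 0.04), "2 channels")
})

test_that("cluster labeling agrees with igraph connected components", {
  skip_if_not_installed("igraph")
  set.seed(21)
  pos <- speechTRF:::grid_positions(9, 0.03, 3)
  adj <- build_adjacency(pos, 0.04)
  for (rep in 1:20) {
    mask <- matrix(runif(9 * 30) < 0.3, 9, 30)
    lab <- speechTRF:::label_clusters(mask, adj$pairs)
    # oracle via igraph on the same supra-threshold cells
    cells <- which(mask)
    if (!length(cells)) { expect_equal(lab$n, 0); next }
    ids <- seq_along(cells)
    cell_ch <- ((cells - 1) %% 9) + 1
    cell_t <- ((cells - 1) %/% 9) + 1
    edges <- NULL
    for (i in ids) for (j in ids) if (i < j) {
      same_ch_adj_t <- cell_ch[i] == cell_ch[j] &&
        abs(cell_t[i] - cell_t[j]) == 1
      same_t_nb_ch <- cell_t[i] == cell_t[j] &&
        any((adj$pairs[, 1] == cell_ch[i] & adj$pairs[, 2] == cell_ch[j]) |
            (adj$pairs[, 1] == cell_ch[j] & adj$pairs[, 2] == cell_ch[i]))
      if (same_ch_adj_t || same_t_nb_ch) edges <- rbind(edges, c(i, j))
    }
    g <- igraph::graph_from_edgelist(if (is.null(edges))
      matrix(integer(0), 0, 2) else edges, directed = FALSE)
    g <- igraph::add_vertices(g, length(ids) - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    ours <- lab$labels[cells]
    # same partition up to relabeling
    expect_equal(length(unique(ours)), comp |> unique() |> length())
    expect_true(all(tapply(comp, ours, function(v) length(unique(v))) == 1))
  }
})

test_that("identical inputs produce no clusters", {
  set.seed(22)
  A <- array(rnorm(8 * 4 * 30), c(8, 4, 30))
  adj <- build_adjacency(speechTRF:::grid_positions(4, 0.03, 2), 0.04)
  res <- suppressWarnings(
    cluster_perm_test(A, A, "paired", adj, n_perm = 120, seed = 1))
  expect_equal(length(res$clusters), 0)
  expect_equal(min_cluster_p(res), 1)
})

test_that("a planted spatiotemporal effect is detected", {
  set.seed(23)
  n_sub <- 20; n_ch <- 8; n_t <- 100
  adj <- build_adjacency(speechTRF:::grid_positions(n_ch, 0.03, 4), 0.04)
  A <- array(rnorm(n_sub * n_ch * n_t), c(n_sub, n_ch, n_t))
  B <- array(rnorm(n_sub * n_ch * n_t), c(n_sub, n_ch, n_t))
  A[, 1:4, 41:60] <- A[, 1:4, 41:60] + 1       # 1 SD, 4 channels, 20 samples
  res <- cluster_perm_test(A, B, "paired", adj, n_perm = 200, seed = 3)
  expect_gt(length(res$clusters), 0)
  top <- res$clusters[[1]]
  expect_lt(top$p, 0.05)
  expect_true(any(top$channels %in% 1:4))
  expect_true(any(top$time_idx %in% 41:60))
  expect_gte(min(vapply(res$clusters, `[[`, numeric(1), "p")),
             1 / (200 + 1))
})

test_that("independent-groups design uses Welch tests and label shuffles", {
  set.seed(24)
  adj <- build_adjacency(speechTRF:::grid_positions(6, 0.03, 3), 0.04)
  A <- array(rnorm(12 * 6 * 60), c(12, 6, 60))
  B <- array(rnorm(10 * 6 * 60, sd = 2), c(10, 6, 60))
  A[, 1:2, 20:40] <- A[, 1:2, 20:40] + 2.5
  res <- cluster_perm_test(A, B, "independent", adj, n_perm = 200, seed = 5)
  expect_gt(length(res$clusters), 0)
  expect_lt(res$clusters[[1]]$p, 0.05)
  expect_error(cluster_perm_test(A, array(0, c(10, 6, 59)), "independent",
                                 adj), "share")
})

test_that("p-values are invariant to graph-preserving channel relabeling", {
  set.seed(25)
  n_ch <- 6
  pos <- speechTRF:::grid_positions(n_ch, 0.03, 3)
  adj <- build_adjacency(pos, 0.04)
  A <- array(rnorm(10 * n_ch * 40), c(10, n_ch, 40))
  B <- array(rnorm(10 * n_ch * 40), c(10, n_ch, 40))
  A[, 3:4, 10:25] <- A[, 3:4, 10:25] + 1.2
  perm <- c(4, 5, 6, 1, 2, 3)     # relabel; permute positions identically
  adj_p <- build_adjacency(pos[perm, ], 0.04)
  r1 <- cluster_perm_test(A, B, "paired", adj, n_perm = 150, seed = 9)
  r2 <- cluster_perm_test(A[, perm, , drop = FALSE],
                          B[, perm, , drop = FALSE],
                          "paired", adj_p, n_perm = 150, seed = 9)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "p"),
               vapply(r2$clusters, `[[`, numeric(1), "p"))
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "mass"),
               vapply(r2$clusters, `[[`, numeric(1), "mass"))
})

test_that("identical seeds reproduce identical results; small n_perm warns", {
  set.seed(26)
  A <- array(rnorm(8 * 4 * 30), c(8, 4, 30))
  B <- array(rnorm(8 * 4 * 30), c(8, 4, 30))
  adj <- build_adjacency(speechTRF:::grid_positions(4, 0.03, 2), 0.04)
  r1 <- cluster_perm_test(A, B, "paired", adj, n_perm = 150, seed = 7)
  r2 <- cluster_perm_test(A, B, "paired", adj, n_perm = 150, seed = 7)
  expect_identical(r1$null_max, r2$null_max)
  expect_warning(cluster_perm_test(A, B, "paired", adj, n_perm = 50,
                                   seed = 1), "100")
  expect_error(cluster_perm_test(A[1:4, , ], B, "paired", adj,
                                 n_perm = 150), "matched")
})

test_that("doubling permutations moves p by at most Monte-Carlo error", {
  set.seed(27)
  A <- array(rnorm(12 * 4 * 40), c(12, 4, 40))
  B <- array(rnorm(12 * 4 * 40), c(12, 4, 40))
  A[, 1:2, 10:20] <- A[, 1:2, 10:20] + 0.9
  adj <- build_adjacency(speechTRF:::grid_positions(4, 0.03, 2), 0.04)
  p1 <- min_cluster_p(cluster_perm_test(A, B, "paired", adj,
                                        n_perm = 400, seed = 11))
  p2 <- min_cluster_p(cluster_perm_test(A, B, "paired", adj,
                                        n_perm = 800, seed = 11))
  se <- sqrt(p1 * (1 - p1) / 400)
  expect_lt(abs(p1 - p2), 2 * se + 1e-3)
})

test_that("cluster results serialize to JSON and TSV", {
  set.seed(28)
  A <- array(rnorm(10 * 4 * 30), c(10, 4, 30))
  B <- array(rnorm(10 * 4 * 30), c(10, 4, 30))
  A[, 1:2, 5:15] <- A[, 1:2, 5:15] + 1.5
  adj <- build_adjacency(speechTRF:::grid_positions(4, 0.03, 2), 0.04)
  res <- cluster_perm_test(A, B, "paired", adj, n_perm = 150, seed = 2,
                           times = seq(0, 116, by = 4))
  td <- withr::local_tempdir()
  summ <- write_cluster_result(res, paste0("ch", 1:4),
                               json_path = file.path(td, "cl.json"),
                               tsv_path = file.path(td, "cl.tsv"))
  expect_true(file.exists(file.path(td, "cl.json")))
  back <- jsonlite::read_json(file.path(td, "cl.json"),
                              simplifyVector = TRUE)
  expect_equal(nrow(summ), length(res$clusters))
  expect_equal(summ$p, vapply(res$clusters, `[[`, numeric(1), "p"))
})
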