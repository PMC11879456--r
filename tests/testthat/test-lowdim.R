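# Low-dimensional representation: collection fitting, scaling, embedding,
# clustering, summaries and condition shifts.

# small, fast collection shared by several tests
make_small_collection <- function(seed = 1, n_per_class = 3) {
  sim_collection(n_per_class = n_per_class,
                 times = seq(0, 10, length.out = 15),
                 noise_sd = 0.01, seed = seed)
}

test_that("collection fitting returns one coherent row per course", {
  coll <- make_small_collection()
  cf <- fit_collection(coll, n_starts = 4, seed = 1)
  expect_identical(nrow(cf$param_matrix), length(coll$courses))
  expect_identical(rownames(cf$param_matrix), coll$metadata$id)
  expect_identical(colnames(cf$param_matrix),
                   c("A", "B", "alpha", "beta", "gamma", "tau", "b",
                     "sign_sus", "sign_trans"))
  # each row is that course's best fit
  for (i in c(1, 4)) {
    f <- cf$fits[[i]]
    expect_equal(unname(cf$param_matrix[i, "A"]), unname(f$best[["A"]]))
  }
})

test_that("duplicated courses give identical parameter rows", {
  coll <- make_small_collection()
  tab <- coll$courses[[1]]$table
  dup <- list(courses = list(list(id = "a", table = tab),
                             list(id = "b", table = tab)),
              metadata = data.frame(id = c("a", "b")))
  cf <- fit_collection(dup, n_starts = 4, seed = 3)
  expect_identical(cf$param_matrix["a", ], cf$param_matrix["b", ])
})

test_that("standardization centres, scales and log-transforms rates", {
  m <- cbind(A = c(1, 2, 3, 4), alpha = c(0.01, 0.1, 1, 10),
             sign_sus = c(1, 1, 1, 1))
  s <- scale_param_matrix(m)
  expect_equal(unname(colMeans(s)), c(0, 0, 0))
  expect_equal(unname(apply(s[, 1:2], 2, sd)), c(1, 1))
  # rates standardized on log scale: equal spacing in the decades
  expect_equal(diff(s[, "alpha"]), rep(diff(s[, "alpha"])[1], 3))
  # constant columns become zeros, not NaN
  expect_identical(unname(s[, "sign_sus"]), rep(0, 4))
})

test_that("embedding is deterministic and preserves coincidence", {
  set.seed(10)
  base <- matrix(rnorm(8 * 4), 8, 4)
  m <- rbind(base, base[1, , drop = FALSE])  # duplicate row
  rownames(m) <- paste0("r", 1:9)
  for (method in c("nmds", "pca")) {
    co1 <- embed_params(m, seed = 5, method = method)
    co2 <- embed_params(m, seed = 5, method = method)
    expect_identical(co1, co2)
    expect_true(all(is.finite(co1)))
    expect_identical(dim(co1), c(9L, 2L))
    # duplicated input rows map to (near-)coincident points
    expect_lt(sqrt(sum((co1["r9", ] - co1["r1", ])^2)),
              1e-6 * max(dist(co1)))
  }
  expect_error(embed_params(m[1:3, ]), "at least 4")
})

test_that("well-separated classes stay separated in the embedding", {
  # two synthetic blobs in parameter space
  set.seed(77)
  blob1 <- matrix(rnorm(10 * 5, 0, 0.1), 10, 5)
  blob2 <- matrix(rnorm(10 * 5, 3, 0.1), 10, 5)
  m <- rbind(blob1, blob2)
  rownames(m) <- paste0("c", 1:20)
  co <- embed_params(m, seed = 1)
  km <- {
    set.seed(1)
    kmeans(co, 2, nstart = 10)
  }
  truthlab <- rep(1:2, each = 10)
  agree <- max(mean(km$cluster == truthlab), mean(km$cluster == 3 - truthlab))
  expect_identical(agree, 1)
})

test_that("k-means clustering selects k by silhouette on blobs", {
  set.seed(31)
  m <- rbind(matrix(rnorm(12 * 3, 0, 0.2), 12, 3),
             matrix(rnorm(12 * 3, 4, 0.2), 12, 3))
  cl <- cluster_params(m, seed = 2)
  expect_identical(cl$k, 2L)
  expect_identical(length(unique(cl$labels[1:12])), 1L)
  expect_identical(length(unique(cl$labels[13:24])), 1L)
  expect_false(cl$labels[1] == cl$labels[13])
  expect_gt(cl$silhouette, 0.5)

  # permuting rows gives the same partition up to label names
  perm <- sample(24)
  cl2 <- cluster_params(m[perm, ], seed = 2)
  expect_identical(length(unique(cl2$labels[perm <= 12])), 1L)
  expect_false(cl2$labels[which(perm == 1)] == cl2$labels[which(perm == 13)])

  expect_identical(cluster_params(m, k = 1)$labels, rep(1L, 24))
  expect_error(cluster_params(m[1, , drop = FALSE]), "at least 2")
})

test_that("cluster summaries bracket the median and handle edge cases", {
  m <- cbind(p1 = c(1, 2, 3, 10), p2 = c(4, 4, 4, 8))
  s <- summarize_clusters(m, c(1, 1, 1, 2))
  s1 <- s[s$cluster == 1 & s$parameter == "p1", ]
  expect_identical(s1$median, 2)
  expect_identical(s1$q25, 1.5)  # type-7 linear interpolation
  expect_identical(s1$q75, 2.5)
  # single-member cluster: all three quantiles equal the row
  s2 <- s[s$cluster == 2 & s$parameter == "p1", ]
  expect_true(all(unlist(s2[c("q25", "median", "q75")]) == 10))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
})

test_that("cluster dynamics are min-max scaled into [0, 1]", {
  coll <- make_small_collection()
  cf <- fit_collection(coll, n_starts = 4, seed = 1)
  dyn <- cluster_dynamics(cf, rep(1L, length(cf$fits)), n_grid = 20)
  expect_true(all(dyn$y_scaled >= 0 & dyn$y_scaled <= 1))
  for (id in unique(dyn$id)[1:2]) {
    sub <- dyn[dyn$id == id, ]
    rng <- range(sub$y)
    expect_equal(sub$y_scaled, (sub$y - rng[1]) / diff(rng))
  }
})

test_that("the full pipeline is deterministic end-to-end", {
  coll <- make_small_collection(seed = 8, n_per_class = 2)
  e1 <- low_dim_rtf(coll, n_starts = 4, k = 2, seed = 5)
  e2 <- low_dim_rtf(coll, n_starts = 4, k = 2, seed = 5)
  expect_identical(e1$param_matrix, e2$param_matrix)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$labels, e2$labels)
  expect_true(all(e1$labels %in% seq_len(e1$k)))
  expect_true(all(table(e1$labels) > 0))
})

test_that("condition shifts rank pairs and report unmatched ids", {
  coords <- rbind(a1 = c(0, 0), a2 = c(0, 0),
                  b1 = c(1, 1), b2 = c(4, 5))
  emb <- list(coords = coords)
  pairing <- data.frame(id1 = c("a1", "b1", "zz"),
                        id2 = c("a2", "b2", "b2"))
  cs <- condition_shift(emb, pairing)
  expect_identical(nrow(cs), 2L)
  expect_identical(cs$id1, c("b1", "a1"))  # sorted by decreasing distance
  expect_identical(cs$distance, c(5, 0))
  expect_identical(attr(cs, "unmatched"), "zz")
  expect_identical(cs$dx[1], 3)

  empty <- condition_shift(emb, data.frame(id1 = character(),
                                           id2 = character()))
  expect_identical(nrow(empty), 0L)
})
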