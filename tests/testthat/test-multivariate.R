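# PCA with supplementary individuals, dimension description, and
# hierarchical clustering on principal components.

test_that("supplementary rows never affect the fitted structure", {
  pm <- toy_pm(n_active = 12, n_sup = 3)
  active_only <- parameter_matrix(
    as.data.frame(pm)[pm$role == "active", , drop = FALSE])
  f_with <- fit_pca_with_supplementary(pm)
  f_without <- fit_pca_with_supplementary(active_only)
  expect_identical(f_with$eigenvalues, f_without$eigenvalues)
  expect_identical(f_with$loadings, f_without$loadings)
  expect_identical(f_with$coords_active, f_without$coords_active)
  expect_identical(f_with$means, f_without$means)
  expect_identical(f_with$sds, f_without$sds)
})

test_that("a supplementary row equal to an active row gets identical coordinates", {
  pm <- toy_pm(n_active = 10, n_sup = 1)
  df <- as.data.frame(pm)
  df[df$role == "supplementary", -(1:2)] <- df[1, -(1:2)]
  f <- fit_pca_with_supplementary(parameter_matrix(df))
  expect_equal(unname(f$coords_supplementary[1, ]),
               unname(f$coords_active[1, ]), tolerance = 1e-12)
})

test_that("two perfectly correlated parameters give eigenvalues {2, 0}", {
  set.seed(3)
  v <- rnorm(8)
  df <- data.frame(assembly_id = paste0("a", 1:8), role = "active",
                   p1 = v, p2 = 3 * v + 1)
  f <- fit_pca_with_supplementary(parameter_matrix(df), n_components = 2)
  expect_equal(f$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(f$explained_variance_pct[1], 100, tolerance = 1e-12)
})

test_that("eigen-identities hold against an independent SVD oracle", {
  set.seed(11)
  n <- 10; p <- 15
  X <- matrix(rnorm(n * p), n)
  df <- data.frame(assembly_id = sprintf("a%02d", 1:n), role = "active", X)
  names(df) <- c("assembly_id", "role", sprintf("p%02d", 1:p))
  f <- fit_pca_with_supplementary(parameter_matrix(df), n_components = p)
  expect_equal(sum(f$eigenvalues), p, tolerance = 1e-9)
  # population variance of the coordinates on dim k equals eigenvalue k
  co <- f$coords_active
  popvar <- apply(co, 2, function(v) sum((v - mean(v))^2) / n)
  expect_equal(unname(popvar), unname(f$eigenvalues), tolerance = 1e-9)
  orc <- oracle_pca(X)
  expect_equal(sort(f$eigenvalues, decreasing = TRUE),
               sort(c(orc$eigenvalues, rep(0, p - n)), decreasing = TRUE),
               tolerance = 1e-9)
  # coordinates agree up to the sign convention
  k <- sum(orc$eigenvalues > 1e-9)
  for (j in seq_len(k))
    expect_equal(abs(unname(co[, j])), abs(unname(orc$coords[, j])),
                 tolerance = 1e-8)
  # full space is an isometry of the standardized data
  expect_equal(as.matrix(dist(co)), as.matrix(dist(orc$Z)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("eigenvector signs are fixed largest-loading-positive", {
  pm <- toy_pm()
  f <- fit_pca_with_supplementary(pm)
  for (j in seq_along(f$eigenvalues)) {
    v <- f$loadings[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
})

test_that("degenerate inputs are hard errors", {
  df <- data.frame(assembly_id = paste0("a", 1:5), role = "active",
                   p1 = rnorm(5), p2 = 1)
  expect_error(fit_pca_with_supplementary(parameter_matrix(df)), "p2")
  df2 <- data.frame(assembly_id = paste0("a", 1:2), role = "active",
                    p1 = 1:2, p2 = 2:1)
  expect_error(parameter_matrix(df2), "3 active")
})

test_that("dimension description recovers exact correlations and filters by P", {
  pm <- toy_pm(n_active = 15, n_sup = 0, p = 4)
  f <- fit_pca_with_supplementary(pm)
  df <- as.data.frame(pm)
  # parameter proportional to the dim-1 coordinates, and its negation:
  # the model is held fixed, only the described values change
  df$p1 <- 2 * f$coords_active[, 1] + 5
  df$p2 <- -f$coords_active[, 1]
  dd <- describe_dimensions(f, parameter_matrix(df))
  expect_equal(dd$R[dd$parameter == "p1" & dd$dimension == 1], 1,
               tolerance = 1e-12)
  expect_equal(dd$R[dd$parameter == "p2" & dd$dimension == 1], -1,
               tolerance = 1e-12)
  expect_true(dd$retained[dd$parameter == "p1" & dd$dimension == 1])
  expect_true(dd$retained[dd$parameter == "p2" & dd$dimension == 1])
  expect_true(all(dd$retained == (dd$P <= 0.05)))
  expect_true(all(abs(dd$R) <= 1 + 1e-12))
})

test_that("null (permuted) parameters are retained at about the alpha rate", {
  set.seed(2024)
  pm <- toy_pm(n_active = 30, n_sup = 0, p = 15)
  f <- fit_pca_with_supplementary(pm, n_components = 3)
  n_sim <- 300
  retained <- logical(0)
  df <- as.data.frame(pm)
  for (s in seq_len(n_sim)) {
    dfp <- df
    for (p in attr(pm, "params")) dfp[[p]] <- sample(dfp[[p]])
    dd <- describe_dimensions(f, parameter_matrix(dfp), alpha = 0.05)
    retained <- c(retained, dd$retained)
  }
  frac <- mean(retained)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("Ward clustering agrees with a brute-force agglomeration oracle", {
  set.seed(99)
  for (trial in 1:40) {
    n <- sample(7:12, 1)
    co <- matrix(rnorm(n * 3), n)
    df <- data.frame(assembly_id = sprintf("x%02d", 1:n), role = "active",
                     p1 = co[, 1], p2 = co[, 2], p3 = co[, 3])
    f <- fit_pca_with_supplementary(parameter_matrix(df), n_components = 3)
    cl <- cluster_assemblies(f, q_range = c(2, n - 1))
    coords <- f$coords_active[, 1:f$n_retained, drop = FALSE]
    oracle <- oracle_ward_partitions(coords)
    # merge-by-merge: partition into q clusters must match the oracle's
    for (q in seq.int(n - 1, 2)) {
      got <- canonical_labels(unname(cutree(cl$tree, q)))
      want <- oracle[[n - q]]
      expect_identical(got, want)
    }
    # merge heights non-decreasing
    expect_true(all(diff(cl$tree$height) >= -1e-9))
  }
})

test_that("the inertia-gain ratio picks the evident number of clusters", {
  set.seed(5)
  # two well-separated blobs
  co <- rbind(matrix(rnorm(10 * 2, 0, 0.3), ncol = 2),
              matrix(rnorm(10 * 2, 10, 0.3), ncol = 2))
  df <- data.frame(assembly_id = sprintf("b%02d", 1:20), role = "active",
                   p1 = co[, 1], p2 = co[, 2], p3 = rnorm(20, sd = 0.2))
  f <- fit_pca_with_supplementary(parameter_matrix(df), n_components = 3)
  cl <- cluster_assemblies(f)
  expect_equal(cl$q, 2)
  truth <- rep(1:2, each = 10)
  expect_equal(ari(cl$labels, truth), 1)

  # duplicating every point leaves the chosen q unchanged
  df2 <- rbind(df, transform(df, assembly_id = paste0(assembly_id, "_b")))
  f2 <- fit_pca_with_supplementary(parameter_matrix(df2), n_components = 3)
  cl2 <- cluster_assemblies(f2)
  expect_equal(cl2$q, cl$q)
})

test_that("three collinear equidistant points split into adjacent pair + endpoint", {
  df <- data.frame(assembly_id = c("p1", "p2", "p3"), role = "active",
                   p1 = c(0, 1, 2))
  f <- fit_pca_with_supplementary(parameter_matrix(df), n_components = 1)
  cl <- cluster_assemblies(f, q_range = c(2, 2))
  expect_equal(cl$q, 2)
  # the middle point is clustered with one endpoint, never alone
  expect_true(cl$labels["p2"] %in%
                c(cl$labels["p1"], cl$labels["p3"]))
})

test_that("clustering rejects degenerate inputs and clips q_range", {
  df <- data.frame(assembly_id = paste0("a", 1:4), role = "active",
                   p1 = c(1, 1, 1, 2))
  f <- fit_pca_with_supplementary(parameter_matrix(
    data.frame(assembly_id = paste0("a", 1:4), role = "active",
               p1 = rnorm(4), p2 = rnorm(4))), n_components = 2)
  expect_warning(cluster_assemblies(f, q_range = c(2, 10)), "clipped")
  same <- data.frame(assembly_id = paste0("s", 1:4), role = "active",
                     p1 = rnorm(4))
  fs <- fit_pca_with_supplementary(parameter_matrix(same))
  # make all retained coordinates identical via a zero-variance trick is
  # impossible post-standardization; instead test the guard directly
  fs$coords_active[] <- 1
  expect_error(cluster_assemblies(fs), "identical")
})

test_that("Newick export writes a tree over all clustered individuals", {
  pm <- toy_pm(n_active = 8, n_sup = 2)
  f <- fit_pca_with_supplementary(pm)
  cl <- cluster_assemblies(f, include_supplementary = TRUE)
  nwk <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, nwk)
  tr <- ape::read.tree(nwk)
  expect_setequal(tr$tip.label, pm$assembly_id)
})
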