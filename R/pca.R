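## Standardized (correlation) PCA with supplementary individuals, dimension
## description by significance-filtered correlations, and hierarchical
## clustering on the retained principal components.

#' Construct / validate a parameter matrix
#'
#' A parameter matrix is a `data.frame` with one row per individual
#' (assembly or reference transcriptome), a `role` column marking each row
#' `active` or `supplementary`, an `assembly_id` column, and one numeric
#' column per evaluation parameter. Active rows drive the PCA; supplementary
#' rows (the reference transcriptomes) are projected afterwards and never
#' influence the component structure.
#'
#' @param x `data.frame` with columns `assembly_id`, `role` and parameter
#'   columns (default: the fifteen canonical parameters; any numeric subset
#'   with >= 1 column is accepted via `params`).
#' @param params Character vector naming the parameter columns to use;
#'   default: all columns other than `assembly_id`/`role`.
#' @return The validated `data.frame` with class `"parameter_matrix"`
#'   prepended; attribute `"params"` holds the parameter column names.
#' @export
parameter_matrix <- function(x, params = NULL) {
  if (!is.data.frame(x)) txstop("'x' must be a data.frame")
  if (!all(c("assembly_id", "role") %in% names(x)))
    txstop("parameter matrix needs 'assembly_id' and 'role' columns")
  x$assembly_id <- as.character(x$assembly_id)
  x$role <- as.character(x$role)
  if (!all(x$role %in% c("active", "supplementary")))
    txstop("'role' must be 'active' or 'supplementary'")
  if (anyDuplicated(x$assembly_id))
    txstop("duplicated assembly_id in parameter matrix")
  params <- params %||% setdiff(names(x), c("assembly_id", "role"))
  if (!length(params)) txstop("no parameter columns")
  miss <- setdiff(params, names(x))
  if (length(miss))
    txstop("parameter column(s) absent: ", paste(miss, collapse = ", "))
  for (p in params) {
    if (!is.numeric(x[[p]]))
      txstop("parameter column '", p, "' is not numeric")
    if (anyNA(x[[p]]))
      txstop("missing values in parameter '", p,
             "'; restrict 'params' or supply the evidence")
  }
  if (sum(x$role == "active") < 3L)
    txstop("need at least 3 active rows")
  structure(x, params = params,
            class = c("parameter_matrix", class(x)))
}

#' Read / write a parameter matrix TSV
#'
#' Tab-separated with header `assembly_id  role  <param> ...`.
#'
#' @param path File path.
#' @return [parameter_matrix()] for the reader; invisibly `path` for the
#'   writer.
#' @export
read_parameter_matrix <- function(path) {
  parameter_matrix(utils::read.delim(path, stringsAsFactors = FALSE,
                                     check.names = FALSE))
}

#' @rdname read_parameter_matrix
#' @param pm A [parameter_matrix()].
#' @export
write_parameter_matrix <- function(pm, path) {
  utils::write.table(as.data.frame(pm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Standardized PCA with supplementary individuals
#'
#' Centers and scales every parameter with the mean and population
#' (1/n) standard deviation of the ACTIVE rows only, eigendecomposes the
#' active correlation matrix, and projects both active and supplementary
#' rows onto the eigenvectors. Supplementary rows are standardized with the
#' active constants and projected with the same eigenvectors, so they never
#' affect the component structure. Each eigenvector's sign is fixed so that
#' its largest-magnitude loading is positive. By default the first three
#' components are retained; `var_threshold` instead retains the smallest
#' number of components whose cumulative explained variance reaches the
#' given percentage.
#'
#' @param pm A [parameter_matrix()] (or coercible `data.frame`).
#' @param n_components Number of components to retain (default 3; capped
#'   at the rank of the correlation matrix).
#' @param var_threshold Optional percentage (e.g. 85) overriding
#'   `n_components`.
#' @param sd_type `"population"` (default, 1/n) or `"sample"` (1/(n-1))
#'   standard deviation for the scaling step.
#' @return Object of class `"pca_supp"`: means, sds, eigenvalues,
#'   loadings (unit-norm eigenvectors, parameters x dimensions),
#'   coords_active, coords_supplementary, explained_variance_pct,
#'   n_retained, params.
#' @export
fit_pca_with_supplementary <- function(pm, n_components = 3,
                                       var_threshold = NULL,
                                       sd_type = c("population", "sample")) {
  if (!inherits(pm, "parameter_matrix")) pm <- parameter_matrix(pm)
  sd_type <- match.arg(sd_type)
  params <- attr(pm, "params")
  act <- pm$role == "active"
  Xa <- as.matrix(as.data.frame(pm)[act, params, drop = FALSE])
  rownames(Xa) <- pm$assembly_id[act]
  n <- nrow(Xa)
  if (n < 3L) txstop("need at least 3 active rows")
  means <- colMeans(Xa)
  sds <- apply(Xa, 2, function(v) {
    s2 <- sum((v - mean(v))^2)
    sqrt(s2 / if (sd_type == "population") length(v) else (length(v) - 1L))
  })
  zero <- names(sds)[sds <= 0 | !is.finite(sds)]
  if (length(zero))
    txstop("zero-variance parameter(s) among active rows: ",
           paste(zero, collapse = ", "))
  Za <- sweep(sweep(Xa, 2, means), 2, sds, "/")
  R <- crossprod(Za) / if (sd_type == "population") n else (n - 1L)
  eig <- eigen(R, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  dimnames(vectors) <- list(params, paste0("Dim", seq_along(values)))
  rank <- sum(values > length(params) * max(values) * 1e-12)
  if (!is.null(var_threshold)) {
    expl <- 100 * cumsum(values) / sum(values)
    n_retained <- min(which(expl >= var_threshold - 1e-12), rank)
  } else {
    n_retained <- min(n_components, rank)
  }
  coords_active <- Za %*% vectors
  sup <- pm$role == "supplementary"
  coords_sup <- NULL
  if (any(sup)) {
    Xs <- as.matrix(as.data.frame(pm)[sup, params, drop = FALSE])
    rownames(Xs) <- pm$assembly_id[sup]
    Zs <- sweep(sweep(Xs, 2, means), 2, sds, "/")
    coords_sup <- Zs %*% vectors
  }
  structure(list(
    means = means, sds = sds, sd_type = sd_type,
    eigenvalues = values, loadings = vectors,
    coords_active = coords_active, coords_supplementary = coords_sup,
    explained_variance_pct = 100 * values / sum(values),
    n_retained = as.integer(n_retained), params = params,
    n_active = n
  ), class = "pca_supp")
}

#' @export
print.pca_supp <- function(x, ...) {
  cat("Standardized PCA:", x$n_active, "active individuals,",
      if (is.null(x$coords_supplementary)) 0
      else nrow(x$coords_supplementary),
      "supplementary,", length(x$params), "parameters\n")
  k <- x$n_retained
  cat(sprintf("Retained %d dimension(s), %.1f%% of variance\n", k,
              sum(x$explained_variance_pct[seq_len(k)])))
  invisible(x)
}

## retained-dimension coordinates for active (+ optionally supplementary)
retained_coords <- function(model, include_supplementary = FALSE) {
  k <- seq_len(model$n_retained)
  co <- model$coords_active[, k, drop = FALSE]
  if (include_supplementary && !is.null(model$coords_supplementary))
    co <- rbind(co, model$coords_supplementary[, k, drop = FALSE])
  co
}

#' Describe PCA dimensions by parameter correlations
#'
#' Pearson correlation between each parameter's active values and the
#' active individuals' coordinates on each retained dimension, with a
#' two-sided significance from the t statistic on n-2 degrees of freedom.
#' Pairs with `P > alpha` are flagged not retained (no multiplicity
#' adjustment, by design).
#'
#' @param model A fitted [fit_pca_with_supplementary()] model.
#' @param pm The parameter matrix the model was fitted on.
#' @param alpha Significance threshold (default 0.05).
#' @return `data.frame` with columns `parameter`, `dimension`, `R`, `P`,
#'   `retained`.
#' @export
describe_dimensions <- function(model, pm, alpha = 0.05) {
  stopifnot(inherits(model, "pca_supp"))
  if (!inherits(pm, "parameter_matrix")) pm <- parameter_matrix(pm)
  act <- pm$role == "active"
  n <- sum(act)
  if (n < 3L) txstop("need at least 3 active rows")
  out <- list()
  for (d in seq_len(model$n_retained)) {
    coord <- model$coords_active[, d]
    for (p in model$params) {
      ct <- stats::cor.test(as.data.frame(pm)[act, p], coord,
                            method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, dimension = d,
        R = unname(ct$estimate), P = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$retained <- res$P <= alpha
  res
}

## total within-cluster inertia of a labelled point set
within_inertia <- function(coords, labels) {
  sum(vapply(split(seq_len(nrow(coords)), labels), function(ix) {
    cc <- coords[ix, , drop = FALSE]
    ctr <- colMeans(cc)
    sum(sweep(cc, 2, ctr)^2)
  }, numeric(1)))
}

#' Hierarchical clustering on principal components
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances over
#' the retained PCA coordinates. The number of clusters q is chosen within
#' `q_range` to maximize the inertia-gain ratio Delta(q)/Delta(q+1), where
#' Delta(q) = W(q-1) - W(q) and W is the total within-cluster inertia of
#' the partition into q clusters: the partition just before the largest
#' relative drop in between-cluster gain. Supplementary individuals are
#' clustered jointly with the assemblies by default.
#'
#' @param model A fitted [fit_pca_with_supplementary()] model.
#' @param include_supplementary Cluster the supplementary individuals
#'   together with the active ones (default `TRUE`).
#' @param q_range Integer vector `c(min, max)` of candidate cluster
#'   counts; default `c(2, min(10, n - 1))`. Degenerate ranges are clipped
#'   with a warning.
#' @return Object of class `"cluster_partition"`: `labels` (named integer
#'   vector), `q`, `tree` (the `hclust` object), `within` (inertia per
#'   candidate partition size), `ratio` (the selection criterion per q).
#' @export
cluster_assemblies <- function(model, include_supplementary = TRUE,
                               q_range = NULL) {
  stopifnot(inherits(model, "pca_supp"))
  co <- retained_coords(model, include_supplementary)
  n <- nrow(co)
  if (n < 3L) txstop("need at least 3 individuals to cluster")
  if (all(apply(co, 2, function(v) diff(range(v)) == 0)))
    txstop("all points identical: total inertia is zero")
  q_range <- as.integer(q_range %||% c(2L, min(10L, n - 1L)))
  if (length(q_range) != 2L || q_range[1] > q_range[2])
    txstop("'q_range' must be c(min, max) with min <= max")
  clipped <- pmin(pmax(q_range, 2L), n - 1L)
  if (!identical(clipped, q_range)) {
    warning("q_range clipped to feasible values [",
            clipped[1], ", ", clipped[2], "]")
    q_range <- clipped
  }
  d <- stats::dist(co, method = "euclidean")
  tree <- stats::hclust(d, method = "ward.D2")
  qs <- seq.int(q_range[1] - 1L, min(q_range[2] + 1L, n))
  W <- vapply(qs, function(q)
    within_inertia(co, stats::cutree(tree, k = q)), numeric(1))
  names(W) <- qs
  Wq <- function(q) W[[as.character(q)]]
  cand <- seq.int(q_range[1], q_range[2])
  eps <- 1e-12 * Wq(qs[1])
  ratio <- vapply(cand, function(q) {
    d1 <- Wq(q - 1L) - Wq(q)
    d2 <- if (q + 1L <= max(qs)) Wq(q) - Wq(q + 1L) else NA_real_
    if (is.na(d2)) return(NA_real_)
    if (d2 <= eps) return(if (d1 <= eps) 1 else Inf)
    d1 / d2
  }, numeric(1))
  names(ratio) <- cand
  best <- cand[which.max(ratio)]
  labels <- stats::cutree(tree, k = best)
  structure(list(labels = labels, q = best, tree = tree, within = W,
                 ratio = ratio, q_range = q_range,
                 include_supplementary = include_supplementary),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("Hierarchical clustering on principal components:",
      length(x$labels), "individuals in", x$q, "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Export a cluster dendrogram as Newick
#'
#' @param partition A [cluster_assemblies()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram_newick <- function(partition, path) {
  stopifnot(inherits(partition, "cluster_partition"))
  phy <- ape::as.phylo(partition$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
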