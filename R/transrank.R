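#' Reference-anchored evaluation and ranking of assemblies
#'
#' The central fit: given a parameter matrix whose active rows are the
#' candidate assemblies and whose supplementary rows are reference
#' transcriptomes, fits a standardized PCA on the active rows, projects
#' the references into the same space as supplementary individuals,
#' describes each retained dimension by significance-filtered parameter
#' correlations, clusters the individuals by Ward hierarchical clustering
#' on the retained components, and ranks every assembly by its mean
#' Euclidean distance (MD) to the references. MD close to 0 means the
#' assembly's evaluation parameters resemble the references' — the better
#' the assembly.
#'
#' @param x A [parameter_matrix()] (or coercible `data.frame` with
#'   `assembly_id`, `role` and parameter columns).
#' @param references Character vector of supplementary row ids to rank
#'   against; default all supplementary rows.
#' @param n_components Retained PCA dimensions (default 3).
#' @param var_threshold Optional explained-variance percentage overriding
#'   `n_components` (see [fit_pca_with_supplementary()]).
#' @param alpha Significance threshold for the dimension description
#'   (default 0.05).
#' @param q_range Candidate cluster-count range, `c(min, max)`; default
#'   `c(2, min(10, n - 1))`.
#' @param include_supplementary Cluster the references together with the
#'   assemblies (default `TRUE`).
#' @param sd_type Standardization convention, `"population"` (default) or
#'   `"sample"`.
#' @return An object of class `"transrank"`: list with `pm`, `pca`,
#'   `dimensions`, `clusters`, `ranking`, `references`, `alpha`, `call`.
#'   Methods: `print`, `summary`, `coef` (loadings), `predict` (project
#'   new metric rows and compute their MD), `plot` (map of individuals on
#'   the first two dimensions), `screeplot`.
#' @seealso [build_metric_vector()] to compute parameter rows from FASTA
#'   and evidence tables; [run_evaluation()] for the file-driven pipeline.
#' @export
#' @examples
#' pm <- make_parameter_matrix(n_active = 24, n_supplementary = 2,
#'                             n_clusters = 3, separation = 8, seed = 42)
#' fit <- transrank(pm)
#' fit
#' head(fit$ranking)
transrank <- function(x, references = NULL, n_components = 3,
                      var_threshold = NULL, alpha = 0.05, q_range = NULL,
                      include_supplementary = TRUE,
                      sd_type = "population") {
  pm <- if (inherits(x, "parameter_matrix")) x else parameter_matrix(x)
  sup_ids <- pm$assembly_id[pm$role == "supplementary"]
  references <- references %||% sup_ids
  if (length(references) == 0L)
    txstop("no reference (supplementary) rows to rank against")
  unknown <- setdiff(references, sup_ids)
  if (length(unknown))
    txstop("reference id(s) not among supplementary rows: ",
           paste(unknown, collapse = ", "))
  pca <- fit_pca_with_supplementary(pm, n_components = n_components,
                                    var_threshold = var_threshold,
                                    sd_type = sd_type)
  dims <- describe_dimensions(pca, pm, alpha = alpha)
  clusters <- cluster_assemblies(pca,
                                 include_supplementary = include_supplementary,
                                 q_range = q_range)
  ranking <- rank_by_mean_distance(pca, reference_ids = references,
                                   clusters = clusters)
  ## flag references that sit far from every assembly (candidate outliers
  ## that would distort the distance scale); purely informational
  ref_means <- colMeans(as.matrix(
    as.data.frame(ranking)[, paste0("dist_", references), drop = FALSE]))
  distorting <- names(ref_means)[ref_means > 3 * min(ref_means)]
  structure(list(pm = pm, pca = pca, dimensions = dims,
                 clusters = clusters, ranking = ranking,
                 references = references, alpha = alpha,
                 distorting_references = sub("^dist_", "", distorting),
                 call = match.call()),
            class = "transrank")
}

#' @export
print.transrank <- function(x, ...) {
  cat("Reference-anchored assembly ranking\n")
  cat(sprintf("  %d assemblies, %d reference(s); %d/%d parameters\n",
              nrow(x$ranking), length(x$references),
              length(x$pca$params), length(x$pca$params)))
  k <- x$pca$n_retained
  cat(sprintf("  %d retained dimension(s) explain %.1f%% of the variance\n",
              k, sum(x$pca$explained_variance_pct[seq_len(k)])))
  cat(sprintf("  %d clusters (Ward on principal components)\n",
              x$clusters$q))
  if (length(x$distorting_references))
    cat("  note: possibly distorting reference(s): ",
        paste(x$distorting_references, collapse = ", "), "\n", sep = "")
  cat("\nTop assemblies by Mean Distance (MD, lower is better):\n")
  print(utils::head(as.data.frame(x$ranking)[, c("assembly_id", "MD",
                                                 "rank", "cluster")], 5L),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.transrank <- function(object, ...) {
  structure(list(fit = object), class = "summary.transrank")
}

#' @export
print.summary.transrank <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nExplained variance per dimension (%):\n")
  print(round(f$pca$explained_variance_pct[seq_len(f$pca$n_retained)], 2))
  cat("\nSignificant parameter-dimension correlations (P <=",
      f$alpha, "):\n")
  keep <- f$dimensions[f$dimensions$retained, c("parameter", "dimension",
                                                "R", "P")]
  keep <- keep[order(keep$dimension, -abs(keep$R)), ]
  print(keep, row.names = FALSE, digits = 3)
  cat("\nCluster sizes:\n")
  print(table(cluster = f$clusters$labels))
  invisible(x)
}

#' @export
coef.transrank <- function(object, ...) {
  object$pca$loadings[, seq_len(object$pca$n_retained), drop = FALSE]
}

#' Project new individuals into a fitted evaluation space
#'
#' Standardizes new parameter rows with the fit's active-row constants,
#' projects them onto the retained components, and computes their distance
#' to each reference and their MD — without refitting anything.
#'
#' @param object A [transrank()] fit.
#' @param newdata `data.frame` with the fit's parameter columns (and
#'   optionally `assembly_id`).
#' @param ... Unused.
#' @return `data.frame` with the retained coordinates, per-reference
#'   distances and `MD` of every new row.
#' @export
predict.transrank <- function(object, newdata, ...) {
  pca <- object$pca
  miss <- setdiff(pca$params, names(newdata))
  if (length(miss))
    txstop("newdata lacks parameter column(s): ",
           paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, pca$params, drop = FALSE])
  Z <- sweep(sweep(X, 2, pca$means), 2, pca$sds, "/")
  k <- seq_len(pca$n_retained)
  co <- (Z %*% pca$loadings)[, k, drop = FALSE]
  refs <- pca$coords_supplementary[object$references, k, drop = FALSE]
  D <- sapply(seq_len(nrow(refs)), function(j)
    sqrt(rowSums(sweep(co, 2, refs[j, ])^2)))
  D <- matrix(D, nrow = nrow(co))
  colnames(D) <- paste0("dist_", object$references)
  ids <- if ("assembly_id" %in% names(newdata)) newdata$assembly_id
         else sprintf("new%03d", seq_len(nrow(co)))
  out <- data.frame(assembly_id = ids, co, D, MD = rowMeans(D),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' @export
plot.transrank <- function(x, dims = c(1, 2), ...) {
  pca <- x$pca
  if (pca$n_retained < 2L)
    txstop("need at least two retained dimensions to plot")
  co <- pca$coords_active[, dims, drop = FALSE]
  sup <- pca$coords_supplementary[, dims, drop = FALSE]
  lab <- x$clusters$labels[rownames(co)]
  cols <- (lab %% 8) + 1
  xlab <- sprintf("Dim %d (%.1f%%)", dims[1],
                  pca$explained_variance_pct[dims[1]])
  ylab <- sprintf("Dim %d (%.1f%%)", dims[2],
                  pca$explained_variance_pct[dims[2]])
  rng <- apply(rbind(co, sup), 2, range)
  graphics::plot(co, col = cols, pch = 19, xlab = xlab, ylab = ylab,
                 xlim = rng[, 1], ylim = rng[, 2],
                 main = "Assemblies and references in PCA space", ...)
  graphics::points(sup, pch = 17, cex = 1.5)
  graphics::text(sup, labels = rownames(sup), pos = 3, cex = 0.8)
  graphics::legend("topright", bty = "n",
                   legend = c(paste("cluster", sort(unique(lab))),
                              "reference"),
                   pch = c(rep(19, length(unique(lab))), 17),
                   col = c(sort(unique((lab %% 8) + 1)), 1))
  invisible(x)
}

#' @export
screeplot.transrank <- function(x, ...) {
  graphics::barplot(x$pca$explained_variance_pct,
                    names.arg = seq_along(x$pca$eigenvalues),
                    xlab = "Dimension", ylab = "Explained variance (%)",
                    ...)
  invisible(x)
}
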