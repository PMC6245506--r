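## Mean-distance ranking of assemblies against reference transcriptomes in
## the retained principal-component space.

#' Rank assemblies by mean Euclidean distance to the references
#'
#' For every active assembly, computes the Euclidean distance in the
#' retained PCA space to each selected reference transcriptome
#' (supplementary individual) and the Mean Distance (MD), the unweighted
#' arithmetic mean of those distances. Assemblies are ranked by ascending
#' MD (the closer an assembly's parameters are to the references, the
#' closer MD is to 0); ties are broken lexicographically by assembly id.
#'
#' @param model A fitted [fit_pca_with_supplementary()] model with at
#'   least one supplementary individual.
#' @param reference_ids Which supplementary individuals to rank against;
#'   default all of them. Restricting the set (e.g. dropping a distorting
#'   reference) changes only MD, never the per-reference columns.
#' @param dims `"retained"` (default) to use the retained dimensions, or
#'   `"all"` to use every dimension.
#' @param clusters Optional [cluster_assemblies()] partition whose labels
#'   are joined onto the table.
#' @return `data.frame` of class `"ranking_table"`, ordered by rank, with
#'   columns `assembly_id`, one `dist_<ref>` column per reference, `MD`,
#'   `rank` and (when `clusters` is given) `cluster`.
#' @export
rank_by_mean_distance <- function(model, reference_ids = NULL,
                                  dims = c("retained", "all"),
                                  clusters = NULL) {
  stopifnot(inherits(model, "pca_supp"))
  dims <- match.arg(dims)
  sup <- model$coords_supplementary
  if (is.null(sup) || nrow(sup) == 0L)
    txstop("model has no supplementary individuals to rank against")
  reference_ids <- reference_ids %||% rownames(sup)
  if (length(reference_ids) == 0L)
    txstop("empty reference list")
  unknown <- setdiff(reference_ids, rownames(sup))
  if (length(unknown))
    txstop("unknown reference id(s): ", paste(unknown, collapse = ", "))
  k <- if (dims == "retained") seq_len(model$n_retained)
       else seq_along(model$eigenvalues)
  A <- model$coords_active[, k, drop = FALSE]
  R <- sup[reference_ids, k, drop = FALSE]
  D <- sapply(seq_len(nrow(R)), function(j)
    sqrt(rowSums(sweep(A, 2, R[j, ])^2)))
  D <- matrix(D, nrow = nrow(A),
              dimnames = list(rownames(A), paste0("dist_", reference_ids)))
  md <- rowMeans(D)
  out <- data.frame(assembly_id = rownames(A), D, MD = md,
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  ord <- order(out$MD, out$assembly_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(clusters)) {
    stopifnot(inherits(clusters, "cluster_partition"))
    out$cluster <- unname(clusters$labels[out$assembly_id])
  }
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Write a ranking table
#'
#' Emits the ranking as TSV (`assembly_id  dist_<ref>...  MD  rank
#' [cluster]`) and, optionally, JSON.
#'
#' @param ranking A [rank_by_mean_distance()] table.
#' @param path Output path without extension.
#' @param json Also write `<path>.json` (default `TRUE`).
#' @return Invisibly, the TSV path.
#' @export
write_ranking <- function(ranking, path, json = TRUE) {
  stopifnot(inherits(ranking, "ranking_table"))
  tsv <- paste0(path, ".tsv")
  utils::write.table(as.data.frame(ranking), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (json)
    jsonlite::write_json(as.data.frame(ranking), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  invisible(tsv)
}
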