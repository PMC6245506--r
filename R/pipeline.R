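## One-call pipeline: from FASTA + evidence tables (or a precomputed
## parameter table) to the fitted ranking, with artifacts on disk.

#' Run the full evaluation pipeline
#'
#' Builds the parameter matrix — either loading a precomputed table or
#' computing the fifteen parameters per assembly from FASTA plus evidence
#' tables — then fits [transrank()] and optionally writes every artifact
#' (parameter matrix, PCA model JSON, dimension description TSV, cluster
#' TSV, dendrogram Newick, ranking TSV/JSON) under `out_dir`.
#'
#' @param config A list (see Details) or path to a `key = value` text
#'   file. Recognized keys: `params` (path to a parameter-matrix TSV,
#'   exclusive with `assemblies`), `assemblies` and `references` (named
#'   lists; each entry a list with `fasta` and optional `sam`,
#'   `aln_summary`, `proteins`, `orthologs` paths), `read_mode`,
#'   `cov_denominator`, `param_subset`, `n_components`, `var_threshold`,
#'   `alpha`, `q_range`, `include_supplementary`, `sd_type`, `out_dir`.
#' @return The [transrank()] fit, invisibly carrying attribute
#'   `"artifacts"` (paths written) when `out_dir` was set.
#' @export
run_evaluation <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  has_refs <- !is.null(config$references) && length(config$references) > 0
  if (!is.null(config$params)) {
    pm <- if (is.character(config$params)) read_parameter_matrix(config$params)
          else parameter_matrix(config$params)
    if (!any(pm$role == "supplementary"))
      txstop("parameter table has no supplementary (reference) rows")
  } else {
    if (is.null(config$assemblies) || length(config$assemblies) < 3L)
      txstop("need at least 3 assemblies (or a precomputed 'params' table)")
    if (!has_refs)
      txstop("config lists no references; ranking is impossible")
    rows <- c(
      lapply(config$assemblies, evaluate_one, config = config),
      lapply(config$references, evaluate_one, config = config)
    )
    ids <- c(names(config$assemblies), names(config$references))
    role <- rep(c("active", "supplementary"),
                c(length(config$assemblies), length(config$references)))
    df <- data.frame(assembly_id = ids, role = role,
                     do.call(rbind, lapply(rows, as.numeric)),
                     stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- c("assembly_id", "role", TX_PARAMS)
    keep <- config$param_subset
    if (is.null(keep)) {
      complete <- colSums(is.na(df[TX_PARAMS])) == 0L
      act <- df$role == "active"
      varying <- vapply(TX_PARAMS, function(p)
        complete[[p]] && stats::var(df[[p]][act]) > 0, logical(1))
      keep <- TX_PARAMS[varying]
      dropped <- TX_PARAMS[complete & !varying]
      if (length(dropped))
        message("dropping constant parameter(s) among assemblies: ",
                paste(dropped, collapse = ", "))
    }
    pm <- parameter_matrix(df[, c("assembly_id", "role", keep)],
                           params = keep)
  }
  fit <- transrank(pm,
                   references = config$reference_ids %||% NULL,
                   n_components = config$n_components %||% 3,
                   var_threshold = config$var_threshold %||% NULL,
                   alpha = config$alpha %||% 0.05,
                   q_range = config$q_range %||% NULL,
                   include_supplementary =
                     config$include_supplementary %||% TRUE,
                   sd_type = config$sd_type %||% "population")
  if (!is.null(config$out_dir))
    attr(fit, "artifacts") <- write_artifacts(fit, config$out_dir)
  fit
}

evaluate_one <- function(entry, config) {
  asm <- read_assembly_fasta(entry$fasta)
  aln <- NULL
  if (!is.null(entry$sam)) aln <- summarize_sam(entry$sam)
  if (!is.null(entry$aln_summary)) aln <- read_alignment_summary(entry$aln_summary)
  hits <- if (!is.null(entry$proteins)) read_protein_hits(entry$proteins)
  orth <- if (!is.null(entry$orthologs)) read_ortholog_status(entry$orthologs)
  build_metric_vector(asm, aln = aln, hits = hits, orthologs = orth,
                      read_mode = config$read_mode %||% "paired",
                      cov_denominator = config$cov_denominator %||% "all")
}

#' Read a plain key = value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                 ln))[[1]]
    if (length(kv) != 3L) txstop("cannot parse config line: ", ln)
    val <- trimws(strsplit(kv[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (identical(val, "TRUE")) val <- TRUE
    if (identical(val, "FALSE")) val <- FALSE
    out[[kv[2]]] <- val
  }
  out
}

write_artifacts <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$params <- file.path(out_dir, "parameter_matrix.tsv")
  write_parameter_matrix(fit$pm, paths$params)
  paths$model <- file.path(out_dir, "pca_model.json")
  pca <- fit$pca
  jsonlite::write_json(list(
    params = pca$params, means = as.list(pca$means),
    sds = as.list(pca$sds), sd_type = pca$sd_type,
    eigenvalues = pca$eigenvalues,
    explained_variance_pct = pca$explained_variance_pct,
    n_retained = pca$n_retained,
    loadings = as.data.frame(pca$loadings),
    coords_active = cbind(assembly_id = rownames(pca$coords_active),
                          as.data.frame(pca$coords_active)),
    coords_supplementary = if (!is.null(pca$coords_supplementary))
      cbind(assembly_id = rownames(pca$coords_supplementary),
            as.data.frame(pca$coords_supplementary))
  ), paths$model, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    pretty = TRUE)
  paths$dimensions <- file.path(out_dir, "dimension_description.tsv")
  utils::write.table(fit$dimensions, paths$dimensions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$clusters <- file.path(out_dir, "clusters.tsv")
  utils::write.table(
    data.frame(assembly_id = names(fit$clusters$labels),
               cluster = unname(fit$clusters$labels)),
    paths$clusters, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$dendrogram <- file.path(out_dir, "dendrogram.nwk")
  write_dendrogram_newick(fit$clusters, paths$dendrogram)
  paths$ranking <- write_ranking(fit$ranking,
                                 file.path(out_dir, "ranking"))
  paths
}
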