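## Self-contained report: a JSON bundle plus a static HTML page rendered
## from the bundle alone (no server, no external assets).

#' Percent-of-maximum heatmap table
#'
#' Per-parameter (column-wise) normalization of the raw values of all
#' individuals, assemblies and references alike: each cell is
#' 100 * value / max(column). Lower-better parameters are deliberately not
#' inverted — the trend arrow is reported beside each parameter instead.
#'
#' @param pm A [parameter_matrix()].
#' @return Numeric matrix (individuals x parameters) of percentages; each
#'   column with a positive maximum contains at least one 100.
#' @export
percent_of_max <- function(pm) {
  if (!inherits(pm, "parameter_matrix")) pm <- parameter_matrix(pm)
  params <- attr(pm, "params")
  X <- as.matrix(as.data.frame(pm)[, params, drop = FALSE])
  rownames(X) <- pm$assembly_id
  apply(X, 2, function(v) {
    m <- max(v)
    if (m == 0) rep(0, length(v)) else 100 * v / m
  })
}

#' Render the evaluation report
#'
#' Writes `report.json` — a self-contained bundle with (1) the
#' percent-of-max heatmap across assemblies and references with trend
#' annotations, (2) the ranking table sorted by ascending MD, (3) the
#' cluster-membership table, (4) parameter weight tables (significant
#' correlations only) for the first two PCA dimensions, (5) per-parameter
#' raw values for histograms — and `report.html` rendered purely from that
#' JSON via [render_report_html()].
#'
#' @param fit A [transrank()] fit.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `json` and `html` paths.
#' @export
render_report <- function(fit, out_dir) {
  stopifnot(inherits(fit, "transrank"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pm <- fit$pm
  params <- attr(pm, "params")
  hm <- percent_of_max(pm)
  dims12 <- fit$dimensions[fit$dimensions$retained &
                             fit$dimensions$dimension <= 2, ]
  raw <- as.data.frame(pm)[, c("assembly_id", "role", params)]
  bundle <- list(
    meta = list(
      tool = "transrank",
      version = as.character(utils::packageVersion("transrank")),
      n_assemblies = sum(pm$role == "active"),
      n_references = sum(pm$role == "supplementary"),
      alpha = fit$alpha,
      p_adjustment = "none",
      trend_note = paste("Trends annotate the expected direction of each",
                         "parameter in a good transcriptome; the printed",
                         "trend for FragOrtho is 'higher_better' although",
                         "high fragmentation is usually a defect."),
      distorting_references = fit$distorting_references
    ),
    trends = as.list(TX_TRENDS[params[params %in% names(TX_TRENDS)]]),
    heatmap = list(
      individuals = rownames(hm),
      role = pm$role,
      parameters = colnames(hm),
      percent_of_max = as.data.frame(hm)
    ),
    ranking = as.data.frame(fit$ranking),
    clusters = data.frame(assembly_id = names(fit$clusters$labels),
                          cluster = unname(fit$clusters$labels)),
    dimension_weights = dims12,
    explained_variance_pct = fit$pca$explained_variance_pct,
    histograms = raw
  )
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  html_path <- render_report_html(json_path,
                                  file.path(out_dir, "report.html"))
  invisible(list(json = json_path, html = html_path))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, digits = 3) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "g") else
      html_escape(as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- apply(cells, 1, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table>", head, paste(body, collapse = ""), "</table>")
}

#' Render the HTML report from the JSON bundle alone
#'
#' @param json_path Path to a `report.json` written by [render_report()].
#' @param html_path Output HTML path.
#' @return `html_path`, invisibly.
#' @export
render_report_html <- function(json_path, html_path) {
  b <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  trend_arrow <- function(p) {
    tr <- b$trends[[p]]
    if (is.null(tr)) "" else if (tr == "higher_better") " (+)" else " (-)"
  }
  hm <- as.data.frame(b$heatmap$percent_of_max)
  names(hm) <- paste0(names(hm), vapply(names(hm), trend_arrow, ""))
  hm <- cbind(individual = b$heatmap$individuals, role = b$heatmap$role, hm)
  sections <- c(
    "<h1>Assembly evaluation report</h1>",
    sprintf("<p>%d assemblies ranked against %d reference transcriptome(s).</p>",
            b$meta$n_assemblies, b$meta$n_references),
    sprintf("<p class='note'>%s</p>", html_escape(b$meta$trend_note)),
    "<h2>Ranking (Mean Distance to references, ascending)</h2>",
    html_table(as.data.frame(b$ranking)),
    "<h2>Clusters</h2>",
    html_table(as.data.frame(b$clusters)),
    "<h2>Evaluation parameters, percent of maximum</h2>",
    html_table(hm, digits = 4),
    sprintf("<h2>Dimension weights (significant at P &le; %s)</h2>",
            b$meta$alpha),
    html_table(as.data.frame(b$dimension_weights)),
    "<h2>Raw parameter values</h2>",
    html_table(as.data.frame(b$histograms), digits = 6)
  )
  if (length(b$meta$distorting_references))
    sections <- c(sections,
                  sprintf("<p class='note'>Possibly distorting reference(s): %s</p>",
                          html_escape(paste(b$meta$distorting_references,
                                            collapse = ", "))))
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Assembly evaluation report</title>",
            "<style>body{font-family:sans-serif;margin:2em}",
            "table{border-collapse:collapse;margin:1em 0}",
            "td,th{border:1px solid #999;padding:2px 6px;font-size:12px}",
            ".note{color:#555;font-style:italic}</style></head><body>",
            sections, "</body></html>")
  writeLines(html, html_path)
  invisible(html_path)
}
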