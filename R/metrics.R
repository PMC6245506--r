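## Metric calculators. Each returns a partial set of the fifteen evaluation
## parameters; build_metric_vector() merges them into one row.

#' Sequence-derived assembly statistics
#'
#' Computes the parameters that need only the contig sequences:
#' `AllTransSize` (total length), `N50`/`N90` (length of the contig at which
#' the descending-length cumulative sum first reaches 50%/90% of the total),
#' `Ns` (count of N letters, case-insensitive; other ambiguity codes are
#' ignored) and `MeanGapLen` (total Ns divided by the number of maximal runs
#' of consecutive Ns; a value of 1 means every indetermination is isolated,
#' larger values indicate real gaps; 0 when there are no Ns).
#'
#' @param assembly An [assembly_record()]; must be non-empty.
#' @return A named list with `AllTransSize`, `N50`, `N90`, `Ns`,
#'   `MeanGapLen`, `MeanContigLenAll` (mean length over all contigs) and
#'   `n_contigs`.
#' @export
#' @examples
#' a <- assembly_record("toy", c(a = "ACNNNGGNA"))
#' sequence_metrics(a)  # Ns = 4, two N-runs, MeanGapLen = 2
sequence_metrics <- function(assembly) {
  stopifnot(inherits(assembly, "assembly_record"))
  seqs <- assembly$contigs
  len <- nchar(seqs)
  total <- sum(len)
  sorted <- sort(len, decreasing = TRUE)
  cs <- cumsum(as.numeric(sorted))
  nx <- function(frac) unname(sorted[which(cs >= frac * total)[1L]])
  runs <- gregexpr("[Nn]+", seqs)
  run_count <- vapply(runs, function(m)
    if (m[1L] == -1L) 0L else length(m), integer(1))
  run_total <- vapply(runs, function(m)
    if (m[1L] == -1L) 0L else sum(attr(m, "match.length")), integer(1))
  n_total <- sum(run_total)
  n_runs <- sum(run_count)
  list(
    AllTransSize = total,
    N50 = nx(0.5),
    N90 = nx(0.9),
    Ns = n_total,
    MeanGapLen = if (n_runs == 0L) 0 else n_total / n_runs,
    MeanContigLenAll = mean(len),
    n_contigs = length(seqs)
  )
}

#' Read-mapping derived assembly statistics
#'
#' `Contigs` counts contigs supported by at least one properly mapped read
#' pair (paired mode) or at least one mapped read (single mode);
#' `Contigs500` is the same count restricted to contigs strictly longer
#' than 500 nt. `MeanContigCov` is the per-contig breadth of coverage
#' (percentage of contig positions covered by at least one read) averaged,
#' by default, over all contigs of the assembly (contigs without alignments
#' contribute 0); `cov_denominator = "useful"` averages over the contigs
#' counted by `Contigs` instead. `MeanContigLenUseful` is the mean length
#' of the contigs counted by `Contigs`.
#'
#' @param assembly An [assembly_record()].
#' @param aln An alignment summary `data.frame` with columns `contig_id`,
#'   `mapped_reads`, `mapped_pairs`, `covered_bases` (one row per contig
#'   with evidence; contigs absent from the table count as unmapped). See
#'   [read_alignment_summary()] and [summarize_sam()].
#' @param read_mode `"paired"` or `"single"`; no default, missing is an
#'   error because the two modes count different evidence.
#' @param cov_denominator `"all"` (default) or `"useful"`.
#' @return Named list with `Contigs`, `Contigs500`, `MeanContigCov` and
#'   `MeanContigLenUseful`.
#' @export
mapping_metrics <- function(assembly, aln, read_mode,
                            cov_denominator = c("all", "useful")) {
  stopifnot(inherits(assembly, "assembly_record"))
  if (missing(read_mode) || is.null(read_mode))
    txstop("'read_mode' must be given as \"paired\" or \"single\"")
  read_mode <- match.arg(read_mode, c("paired", "single"))
  cov_denominator <- match.arg(cov_denominator)
  aln <- validate_alignment_summary(aln)
  len <- nchar(assembly$contigs)
  unknown <- setdiff(aln$contig_id, names(len))
  if (length(unknown))
    txstop("alignment summary names contig(s) absent from assembly '",
           assembly$assembly_id, "': ", paste(unknown, collapse = ", "))
  bad_cov <- aln$covered_bases > len[aln$contig_id]
  if (any(bad_cov))
    txstop("covered_bases exceeds contig length for: ",
           paste(aln$contig_id[bad_cov], collapse = ", "))
  useful <- if (read_mode == "paired") aln$contig_id[aln$mapped_pairs >= 1L]
            else aln$contig_id[aln$mapped_reads >= 1L]
  cov_pct <- setNames(numeric(length(len)), names(len))
  cov_pct[aln$contig_id] <- 100 * aln$covered_bases / len[aln$contig_id]
  mean_cov <- if (cov_denominator == "all") {
    if (length(len)) mean(cov_pct) else 0
  } else {
    if (length(useful)) mean(cov_pct[useful]) else 0
  }
  list(
    Contigs = length(useful),
    Contigs500 = sum(len[useful] > 500L),
    MeanContigCov = mean_cov,
    MeanContigLenUseful = if (length(useful)) mean(len[useful]) else 0
  )
}

validate_alignment_summary <- function(aln) {
  need <- c("contig_id", "mapped_reads", "mapped_pairs", "covered_bases")
  if (!is.data.frame(aln) || !all(need %in% names(aln)))
    txstop("alignment summary needs columns: ", paste(need, collapse = ", "))
  aln$contig_id <- as.character(aln$contig_id)
  for (cc in need[-1]) {
    v <- aln[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      txstop("alignment summary column '", cc, "' must be non-negative numeric")
  }
  if (anyDuplicated(aln$contig_id))
    txstop("alignment summary has duplicated contig ids")
  aln
}

#' Protein-annotation derived assembly statistics
#'
#' `DiffProts` is the number of distinct proteins hit anywhere in the
#' assembly; `DiffComplProts` restricts to proteins with at least one hit
#' flagged complete. `MissAssembl` is the percentage of annotated contigs
#' whose hits fall on both strands (a putative mis-assembly/chimera signal);
#' the denominator is the set of contigs with at least one hit, 0 when no
#' contig is annotated.
#'
#' @param hits `data.frame` with columns `contig_id`, `protein_id`,
#'   `strand` (`+`/`-`), `completeness` (`complete`/`partial`). May have
#'   zero rows.
#' @return Named list with `DiffProts`, `DiffComplProts`, `MissAssembl`.
#' @export
annotation_metrics <- function(hits) {
  hits <- validate_protein_hits(hits)
  if (nrow(hits) == 0L)
    return(list(DiffProts = 0L, DiffComplProts = 0L, MissAssembl = 0))
  diff_prots <- length(unique(hits$protein_id))
  compl <- unique(hits$protein_id[hits$completeness == "complete"])
  strands <- split(hits$strand, hits$contig_id)
  both <- sum(vapply(strands, function(s) all(c("+", "-") %in% s), logical(1)))
  list(
    DiffProts = diff_prots,
    DiffComplProts = length(compl),
    MissAssembl = 100 * both / length(strands)
  )
}

validate_protein_hits <- function(hits) {
  need <- c("contig_id", "protein_id", "strand", "completeness")
  if (!is.data.frame(hits) || !all(need %in% names(hits)))
    txstop("protein hit table needs columns: ", paste(need, collapse = ", "))
  for (cc in need) hits[[cc]] <- as.character(hits[[cc]])
  bad <- setdiff(unique(hits$strand), c("+", "-"))
  if (length(bad))
    txstop("malformed strand value(s): ", paste(bad, collapse = ", "))
  badc <- setdiff(unique(hits$completeness), c("complete", "partial"))
  if (length(badc))
    txstop("malformed completeness value(s): ", paste(badc, collapse = ", "))
  hits
}

#' Ortholog-completeness statistics
#'
#' Percentage of benchmark single-copy ortholog groups recovered complete in
#' a single contig (`ComplOrtho`), fragmented across contigs (`FragOrtho`),
#' or duplicated in several contigs (`DuplOrtho`). Missing groups count only
#' in the denominator.
#'
#' @param orthologs `data.frame` with columns `ortholog_group_id` and
#'   `status` in `complete_single`, `duplicated`, `fragmented`, `missing`;
#'   one row per group; must be non-empty (the percentages are undefined
#'   otherwise).
#' @return Named list with `ComplOrtho`, `FragOrtho`, `DuplOrtho`.
#' @export
ortholog_metrics <- function(orthologs) {
  orthologs <- validate_ortholog_status(orthologs)
  if (nrow(orthologs) == 0L)
    txstop("ortholog status table is empty; percentages are undefined")
  n <- nrow(orthologs)
  pct <- function(st) 100 * sum(orthologs$status == st) / n
  list(
    ComplOrtho = pct("complete_single"),
    FragOrtho = pct("fragmented"),
    DuplOrtho = pct("duplicated")
  )
}

validate_ortholog_status <- function(orthologs) {
  need <- c("ortholog_group_id", "status")
  if (!is.data.frame(orthologs) || !all(need %in% names(orthologs)))
    txstop("ortholog table needs columns: ", paste(need, collapse = ", "))
  orthologs$ortholog_group_id <- as.character(orthologs$ortholog_group_id)
  orthologs$status <- as.character(orthologs$status)
  ok <- c("complete_single", "duplicated", "fragmented", "missing")
  bad <- setdiff(unique(orthologs$status), ok)
  if (length(bad))
    txstop("unknown ortholog status value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(orthologs$ortholog_group_id))
    txstop("duplicated ortholog group id(s)")
  orthologs
}

#' Assemble the full fifteen-parameter metric vector for one assembly
#'
#' Sequence statistics are always computed; mapping, annotation and
#' ortholog blocks are computed only when their evidence is supplied, and
#' the corresponding fields are `NA` (flagged missing) otherwise.
#' `MeanContigLen` is the mean over "useful" contigs (those counted by
#' `Contigs`) when alignment evidence is available, and the mean over all
#' contigs otherwise; the all-contig value is always kept in the
#' `"mean_contig_len_all"` attribute.
#'
#' @inheritParams mapping_metrics
#' @param hits Optional protein hit table (see [annotation_metrics()]).
#' @param orthologs Optional ortholog status table (see
#'   [ortholog_metrics()]).
#' @param read_mode Required when `aln` is given.
#' @return A named numeric vector of class `"metric_vector"` with the
#'   fifteen parameters in canonical order; attributes `assembly_id`,
#'   `missing` (names of unpopulated fields), `trends` and
#'   `mean_contig_len_all`.
#' @export
build_metric_vector <- function(assembly, aln = NULL, hits = NULL,
                                orthologs = NULL, read_mode = NULL,
                                cov_denominator = "all") {
  sq <- sequence_metrics(assembly)
  mv <- setNames(rep(NA_real_, length(TX_PARAMS)), TX_PARAMS)
  mv[c("AllTransSize", "N50", "N90", "Ns", "MeanGapLen")] <-
    unlist(sq[c("AllTransSize", "N50", "N90", "Ns", "MeanGapLen")])
  mv["MeanContigLen"] <- sq$MeanContigLenAll
  if (!is.null(aln)) {
    mp <- mapping_metrics(assembly, aln, read_mode = read_mode,
                          cov_denominator = cov_denominator)
    mv[c("Contigs", "Contigs500", "MeanContigCov")] <-
      unlist(mp[c("Contigs", "Contigs500", "MeanContigCov")])
    mv["MeanContigLen"] <- mp$MeanContigLenUseful
  }
  if (!is.null(hits))
    mv[c("DiffProts", "DiffComplProts", "MissAssembl")] <-
      unlist(annotation_metrics(hits))
  if (!is.null(orthologs))
    mv[c("ComplOrtho", "FragOrtho", "DuplOrtho")] <-
      unlist(ortholog_metrics(orthologs))
  structure(mv,
            assembly_id = assembly$assembly_id,
            missing = names(mv)[is.na(mv)],
            trends = TX_TRENDS,
            mean_contig_len_all = sq$MeanContigLenAll,
            class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, ...) {
  cat("Evaluation parameters for assembly '", attr(x, "assembly_id"), "'\n",
      sep = "")
  df <- data.frame(value = as.numeric(x),
                   trend = ifelse(TX_TRENDS == "higher_better", "(+)", "(-)"),
                   row.names = TX_PARAMS)
  print(df, ...)
  miss <- attr(x, "missing")
  if (length(miss))
    cat("missing evidence for:", paste(miss, collapse = ", "), "\n")
  invisible(x)
}
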