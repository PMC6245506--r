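## Readers and writers for the evidence tables and result files.

#' Read a per-contig alignment summary table
#'
#' Tab-separated with header `contig_id  mapped_reads  mapped_pairs
#' covered_bases`. `covered_bases` is the number of distinct contig
#' positions overlapped by at least one aligned read segment.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` usable as the `aln` argument of
#'   [mapping_metrics()].
#' @export
read_alignment_summary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_alignment_summary(df)
}

#' Summarize a SAM file into per-contig alignment evidence
#'
#' Only primary, mapped alignment lines contribute (secondary,
#' supplementary and unmapped records are excluded). A read pair counts
#' when both mates map to the same contig with the proper-pair flag set
#' (counted once, on the first mate). Coverage breadth is the number of
#' contig positions covered by at least one aligned segment.
#'
#' @param path Path to a SAM (or BAM) file with `@SQ` header lines.
#' @return Alignment summary `data.frame` (one row per contig with at
#'   least one primary alignment) with columns `contig_id`,
#'   `mapped_reads`, `mapped_pairs`, `covered_bases`.
#' @export
summarize_sam <- function(path) {
  if (!file.exists(path)) txstop("SAM file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("flag", "mrnm"), flag = flag)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  rn <- as.character(GenomicAlignments::seqnames(gal))
  reads <- table(rn)
  fl <- S4Vectors::mcols(gal)$flag
  mrnm <- as.character(S4Vectors::mcols(gal)$mrnm)
  is_pair <- bitwAnd(fl, 2L) > 0L & bitwAnd(fl, 64L) > 0L &
    !is.na(mrnm) & mrnm == rn
  pairs <- table(rn[is_pair])
  cov <- GenomicAlignments::coverage(gal)
  covered <- vapply(names(cov), function(nm) {
    r <- cov[[nm]]
    sum(S4Vectors::runLength(r)[S4Vectors::runValue(r) > 0L])
  }, numeric(1))
  ids <- sort(unique(rn))
  data.frame(
    contig_id = ids,
    mapped_reads = as.integer(reads[ids]),
    mapped_pairs = ifelse(is.na(pairs[ids]), 0L, as.integer(pairs[ids])),
    covered_bases = as.numeric(covered[ids]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a protein hit table
#'
#' Tab-separated with header `contig_id  protein_id  strand  completeness`
#' (strand `+`/`-`, completeness `complete`/`partial`), one row per hit.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` usable by [annotation_metrics()].
#' @export
read_protein_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_protein_hits(df)
}

#' Read an ortholog status table
#'
#' Accepts two dialects: (1) a plain TSV with header
#' `ortholog_group_id  status` and statuses `complete_single`,
#' `duplicated`, `fragmented`, `missing`; (2) a BUSCO v3 `full_table.tsv`
#' (comment lines starting with `#`, columns Busco id / Status / ...),
#' whose `Complete`, `Duplicated`, `Fragmented`, `Missing` statuses are
#' mapped onto the internal four.
#'
#' @param path Path to the table.
#' @return `data.frame` usable by [ortholog_metrics()].
#' @export
read_ortholog_status <- function(path) {
  first <- readLines(path, n = 25L)
  if (any(grepl("^#", first))) {
    ## BUSCO full_table dialect
    df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) txstop("cannot parse BUSCO table: ", path)
    map <- c(Complete = "complete_single", Duplicated = "duplicated",
             Fragmented = "fragmented", Missing = "missing")
    status <- map[as.character(df[[2L]])]
    if (anyNA(status))
      txstop("unknown BUSCO status value(s) in ", path)
    ## duplicated groups appear once per copy in BUSCO output
    out <- unique(data.frame(ortholog_group_id = as.character(df[[1L]]),
                             status = unname(status),
                             stringsAsFactors = FALSE))
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  }
  validate_ortholog_status(out)
}

#' Write a metric vector to JSON and TSV
#'
#' Emits one JSON object and one single-row TSV holding the fifteen
#' parameters plus provenance (assembly id, missing-field flags, input
#' file names).
#'
#' @param mv A `"metric_vector"` from [build_metric_vector()].
#' @param path Output path without extension; `<path>.json` and
#'   `<path>.tsv` are written.
#' @param inputs Optional named list of input file paths recorded as
#'   provenance.
#' @return Invisibly, the JSON path.
#' @export
write_metric_vector <- function(mv, path, inputs = list()) {
  stopifnot(inherits(mv, "metric_vector"))
  obj <- list(
    assembly_id = attr(mv, "assembly_id"),
    parameters = as.list(setNames(as.numeric(mv), TX_PARAMS)),
    trends = as.list(TX_TRENDS),
    missing = as.list(attr(mv, "missing")),
    mean_contig_len_all = attr(mv, "mean_contig_len_all"),
    inputs = inputs
  )
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  row <- data.frame(assembly_id = attr(mv, "assembly_id"),
                    t(as.numeric(mv)), stringsAsFactors = FALSE)
  names(row) <- c("assembly_id", TX_PARAMS)
  utils::write.table(row, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(path, ".json"))
}
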