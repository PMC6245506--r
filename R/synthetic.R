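## Synthetic transcriptomes with controlled degradation, plus a direct
## Gaussian-cluster generator for the multivariate stage. Everything is
## deterministic under a fixed seed, so the whole pipeline is testable
## without external data. Alignment evidence is generated analytically
## (coverage drawn as a fraction of contig length) rather than by
## simulating and mapping reads, because the metric calculators consume
## only the per-contig summary.

#' Degradation specification
#'
#' Controls the four quality axes the evaluation parameters are sensitive
#' to: fragmentation (drives N50 down and fragmented-ortholog percentage
#' up), duplication (duplicated orthologs), N-gap injection (Ns and mean
#' gap length) and chimerism (both-strand annotation hits). Degradations
#' compose in the fixed order fragment -> duplicate -> gapify -> chimerize.
#'
#' @param fragmentation_rate Expected breakpoints per kb of contig.
#' @param duplication_fraction Fraction of contigs re-emitted as a mutated
#'   copy.
#' @param mutation_rate Per-base substitution probability in duplicated
#'   copies.
#' @param gap_rate Expected N-runs injected per kb of contig.
#' @param gap_mean Mean injected N-run length (geometric, >= 1).
#' @param chimera_fraction Fraction of contigs fused pairwise in opposite
#'   orientations.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `"degradation_spec"`.
#' @export
degradation_spec <- function(fragmentation_rate = 0,
                             duplication_fraction = 0,
                             mutation_rate = 0.01,
                             gap_rate = 0, gap_mean = 5,
                             chimera_fraction = 0, seed = 1L) {
  if (fragmentation_rate < 0 || gap_rate < 0 || mutation_rate < 0)
    txstop("rates must be >= 0")
  if (duplication_fraction < 0 || duplication_fraction > 1 ||
      chimera_fraction < 0 || chimera_fraction > 1)
    txstop("fractions must lie in [0, 1]")
  if (gap_mean < 1) txstop("'gap_mean' must be >= 1")
  structure(list(fragmentation_rate = fragmentation_rate,
                 duplication_fraction = duplication_fraction,
                 mutation_rate = mutation_rate,
                 gap_rate = gap_rate, gap_mean = gap_mean,
                 chimera_fraction = chimera_fraction,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Generate a clean base transcriptome with ground truth
#'
#' Transcript lengths are drawn as `min + (max - min) * Beta(1, shape)`,
#' right-skewed like real transcript length distributions (mean
#' `min + (max - min) / (1 + shape)`). Each transcript carries exactly one
#' protein (complete, plus strand) and a configurable fraction belongs to
#' a single-copy ortholog group, so the undegraded truth yields
#' MissAssembl = 0, DuplOrtho = 0, FragOrtho = 0 and ComplOrtho = 100.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range `c(min, max)` transcript length bounds in nt.
#' @param shape Beta shape parameter (> 0) of the length distribution.
#' @param ortholog_fraction Fraction of transcripts assigned to an
#'   ortholog group.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_transcriptome"`: `assembly`
#'   ([assembly_record()]), `proteins` (protein hit table), `orthologs`
#'   (ortholog status table, all `complete_single`), `ortholog_map`
#'   (group id -> transcript id).
#' @export
make_base_transcriptome <- function(n_transcripts, length_range = c(300, 3000),
                                    shape = 2, ortholog_fraction = 0.5,
                                    seed = 1L) {
  if (n_transcripts < 1L) txstop("'n_transcripts' must be >= 1")
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[2] < length_range[1])
    txstop("invalid 'length_range': need 1 <= min <= max")
  if (shape <= 0) txstop("'shape' must be > 0")
  with_seed(seed, {
    lens <- round(length_range[1] +
                    (length_range[2] - length_range[1]) *
                    stats::rbeta(n_transcripts, 1, shape))
    ids <- sprintf("t%05d", seq_len(n_transcripts))
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.28, 0.22, 0.22, 0.28)), collapse = ""), "")
    names(seqs) <- ids
    n_og <- max(1L, round(ortholog_fraction * n_transcripts))
    og_members <- sort(sample(seq_len(n_transcripts), n_og))
    ortholog_map <- setNames(ids[og_members],
                             sprintf("OG%05d", seq_len(n_og)))
    proteins <- data.frame(contig_id = ids,
                           protein_id = sprintf("P%05d",
                                                seq_len(n_transcripts)),
                           strand = "+", completeness = "complete",
                           stringsAsFactors = FALSE)
    orthologs <- data.frame(ortholog_group_id = names(ortholog_map),
                            status = "complete_single",
                            stringsAsFactors = FALSE)
    structure(list(assembly = assembly_record("base", seqs),
                   proteins = proteins, orthologs = orthologs,
                   ortholog_map = ortholog_map),
              class = "synthetic_transcriptome")
  })
}

## substitute bases at `rate` per position (never to the original base)
mutate_sequence <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate & ch %in% c("A", "C", "G", "T"))
  for (i in hit)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  paste(ifelse(ch %in% names(map), map[ch], ch), collapse = "")
}

#' Degrade a synthetic transcriptome
#'
#' Applies, in fixed order: fragmentation (contigs split at uniform
#' internal positions; a grouped transcript split in two or more pieces is
#' marked `fragmented`), duplication (a mutated copy is re-emitted; an
#' unfragmented grouped transcript hit twice is marked `duplicated`), gap
#' injection (non-overlapping runs of Ns replace sequence), and chimera
#' fusion (pairs of contigs fused with the second reverse-complemented, so
#' their protein hits land on both strands). The emitted evidence tables
#' are internally consistent with the degraded FASTA, and the returned
#' `truth` bookkeeping records exactly what was injected.
#'
#' @param base A [make_base_transcriptome()] result.
#' @param spec A [degradation_spec()].
#' @return A list of class `"degraded_transcriptome"`: `assembly`,
#'   `alignment` (alignment summary table), `proteins`, `orthologs`,
#'   `truth` (list with `ns_injected`, `gap_runs`, `fragmented_groups`,
#'   `duplicated_groups`, `chimeric_contigs`).
#' @export
degrade <- function(base, spec) {
  stopifnot(inherits(base, "synthetic_transcriptome"),
            inherits(spec, "degradation_spec"))
  with_seed(spec$seed, {
    seqs <- base$assembly$contigs
    ## protein + group bookkeeping per current contig
    prot_of <- setNames(base$proteins$protein_id, base$proteins$contig_id)
    group_of <- setNames(names(base$ortholog_map), base$ortholog_map)
    status <- setNames(rep("complete_single", length(base$ortholog_map)),
                       names(base$ortholog_map))
    hit_rows <- list()
    frag_of <- list()   # transcript id -> fragment ids

    ## 1) fragmentation
    out <- list()
    for (id in names(seqs)) {
      s <- seqs[[id]]
      L <- nchar(s)
      nb <- stats::rpois(1, spec$fragmentation_rate * L / 1000)
      nb <- min(nb, L - 1L)
      if (nb <= 0L) {
        out[[id]] <- s
        frag_of[[id]] <- id
        next
      }
      cuts <- sort(sample.int(L - 1L, nb))
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, L)
      pieces <- substring(s, starts, ends)
      pids <- paste0(id, "_f", seq_along(pieces))
      out[pids] <- pieces
      frag_of[[id]] <- pids
      g <- group_of[id]
      if (!is.na(g)) status[g] <- "fragmented"
    }
    seqs <- unlist(out)
    src <- rep(names(frag_of), lengths(frag_of))      # original transcript
    names(src) <- unlist(frag_of)

    ## 2) duplication
    n_dup <- round(spec$duplication_fraction * length(seqs))
    if (n_dup > 0L) {
      dup_ids <- sample(names(seqs), n_dup)
      for (id in dup_ids) {
        nid <- paste0(id, "_dup")
        seqs[[nid]] <- mutate_sequence(seqs[[id]], spec$mutation_rate)
        src[nid] <- src[[id]]
        tid <- src[[id]]
        g <- group_of[tid]
        if (!is.na(g) && status[g] == "complete_single")
          status[g] <- "duplicated"
      }
    }
    dup_set <- grep("_dup$", names(seqs), value = TRUE)

    ## 3) gap injection: non-overlapping, non-adjacent runs so the run
    ##    count is exactly the number injected (base has no Ns)
    ns_injected <- 0L
    gap_runs <- 0L
    for (id in names(seqs)) {
      s <- seqs[[id]]
      L <- nchar(s)
      ng <- stats::rpois(1, spec$gap_rate * L / 1000)
      if (ng == 0L) next
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (i in seq_len(ng)) {
        ## strictly interior, non-adjacent runs: the run count stays
        ## exactly the number injected even after later concatenations
        glen <- min(1L + stats::rgeom(1, 1 / spec$gap_mean), L - 2L)
        if (glen < 1L) next
        ok <- FALSE
        for (try in 1:25) {
          pos <- 1L + sample.int(L - glen - 1L, 1L)
          win <- seq.int(pos - 1L, pos + glen)
          if (!any(ch[win] == "N")) { ok <- TRUE; break }
        }
        if (!ok) next
        ch[pos:(pos + glen - 1L)] <- "N"
        ns_injected <- ns_injected + glen
        gap_runs <- gap_runs + 1L
      }
      seqs[[id]] <- paste(ch, collapse = "")
    }

    ## 4) chimera fusion (pairs of distinct transcripts, second revcomp'd)
    chimeric <- character(0)
    n_chi <- floor(spec$chimera_fraction * length(seqs) / 2) * 2
    if (n_chi >= 2L) {
      pool <- sample(names(seqs), n_chi)
      for (i in seq(1L, n_chi, by = 2L)) {
        a <- pool[i]; b <- pool[i + 1L]
        nid <- paste0(a, "~", b)
        seqs[[nid]] <- paste0(seqs[[a]], revcomp(seqs[[b]]))
        src[nid] <- NA_character_
        chim_src <- c(src[[a]], src[[b]])
        seqs <- seqs[setdiff(names(seqs), c(a, b))]
        chimeric <- c(chimeric, nid)
        hit_rows[[nid]] <- data.frame(
          contig_id = nid,
          protein_id = prot_of[stats::na.omit(chim_src)],
          strand = c("+", "-")[seq_along(stats::na.omit(chim_src))],
          completeness = "partial", stringsAsFactors = FALSE)
        src <- src[setdiff(names(src), c(a, b))]
      }
    }

    ## protein hit table for non-chimeric contigs: every fragment/copy of
    ## a transcript keeps a hit to its protein; only an unsplit, unfused
    ## original keeps a 'complete' hit
    min_hit_len <- 90L
    plain <- setdiff(names(seqs), chimeric)
    rows <- lapply(plain, function(id) {
      tid <- src[[id]]
      if (is.na(tid) || nchar(seqs[[id]]) < min_hit_len) return(NULL)
      complete <- identical(id, tid)   # untouched original contig
      data.frame(contig_id = id, protein_id = unname(prot_of[tid]),
                 strand = "+",
                 completeness = if (complete) "complete" else "partial",
                 stringsAsFactors = FALSE)
    })
    proteins <- do.call(rbind, c(rows, unname(hit_rows)))
    if (is.null(proteins))
      proteins <- data.frame(contig_id = character(), protein_id = character(),
                             strand = character(), completeness = character(),
                             stringsAsFactors = FALSE)

    orthologs <- data.frame(ortholog_group_id = names(status),
                            status = unname(status),
                            stringsAsFactors = FALSE)

    ## analytic alignment evidence: coverage breadth as a fraction of
    ## length, depressed on mutated duplicates and chimeras
    lens <- nchar(seqs)
    frac <- stats::runif(length(seqs), 0.80, 0.95)
    is_dup <- names(seqs) %in% dup_set
    frac[is_dup] <- stats::runif(sum(is_dup), 0.40, 0.65)
    is_chi <- names(seqs) %in% chimeric
    frac[is_chi] <- stats::runif(sum(is_chi), 0.65, 0.85)
    reads <- 2L + stats::rpois(length(seqs), pmax(1, lens / 100))
    alignment <- data.frame(
      contig_id = names(seqs),
      mapped_reads = reads,
      mapped_pairs = pmax(1L, reads %/% 2L),
      covered_bases = pmin(lens, round(frac * lens)),
      row.names = NULL, stringsAsFactors = FALSE)

    structure(list(
      assembly = assembly_record(
        paste0(base$assembly$assembly_id, "_degraded"), unlist(seqs)),
      alignment = alignment, proteins = proteins, orthologs = orthologs,
      truth = list(ns_injected = ns_injected, gap_runs = gap_runs,
                   fragmented_groups = names(status)[status == "fragmented"],
                   duplicated_groups = names(status)[status == "duplicated"],
                   chimeric_contigs = chimeric)),
      class = "degraded_transcriptome")
  })
}

#' Write a synthetic fixture set to disk
#'
#' FASTA plus the three evidence tables and a truth JSON, the plain-text
#' bundle the evaluation pipeline consumes.
#'
#' @param deg A [degrade()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture_dir <- function(deg, dir) {
  stopifnot(inherits(deg, "degraded_transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "assembly.fa")
  writeLines(paste0(">", names(deg$assembly$contigs), "\n",
                    deg$assembly$contigs), fa)
  utils::write.table(deg$alignment, file.path(dir, "alignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(deg$proteins, file.path(dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(deg$orthologs, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(deg$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate a parameter matrix with known cluster structure
#'
#' Active individuals are drawn from Gaussian clusters in a latent
#' three-dimensional space (cluster centres scaled by `separation`, unit
#' within-cluster spread) and mapped to the fifteen parameters through a
#' fixed random linear map plus small observation noise. Supplementary
#' rows are placed inside cluster 1, emulating reference transcriptomes
#' that sit among the best assemblies.
#'
#' @param n_active Number of active rows (>= 3).
#' @param n_supplementary Number of supplementary (reference) rows.
#' @param n_clusters Number of latent clusters.
#' @param separation Effect size: distance scale between cluster centres
#'   in within-cluster standard deviation units.
#' @param seed Integer seed.
#' @return A [parameter_matrix()] with attribute `"truth"` holding the
#'   latent cluster label of every row.
#' @export
make_parameter_matrix <- function(n_active, n_supplementary = 2,
                                  n_clusters = 3, separation = 5,
                                  seed = 1L) {
  if (n_active < 3L) txstop("'n_active' must be >= 3")
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_clusters * 3), n_clusters, 3) *
      separation / sqrt(3)
    lab <- rep_len(seq_len(n_clusters), n_active)
    Z <- centers[lab, , drop = FALSE] + matrix(stats::rnorm(n_active * 3),
                                               n_active, 3)
    lab_s <- rep(1L, n_supplementary)
    Zs <- if (n_supplementary > 0)
      centers[lab_s, , drop = FALSE] +
        matrix(stats::rnorm(n_supplementary * 3), n_supplementary, 3)
    A <- matrix(stats::rnorm(3 * length(TX_PARAMS)), 3)
    X <- Z %*% A + matrix(stats::rnorm(n_active * length(TX_PARAMS),
                                       sd = 0.1), n_active)
    df <- data.frame(assembly_id = sprintf("asm%03d", seq_len(n_active)),
                     role = "active", X, stringsAsFactors = FALSE,
                     check.names = FALSE)
    names(df) <- c("assembly_id", "role", TX_PARAMS)
    if (n_supplementary > 0) {
      Xs <- Zs %*% A + matrix(stats::rnorm(n_supplementary *
                                             length(TX_PARAMS), sd = 0.1),
                              n_supplementary)
      dfs <- data.frame(assembly_id = sprintf("ref%02d",
                                              seq_len(n_supplementary)),
                        role = "supplementary", Xs, stringsAsFactors = FALSE,
                        check.names = FALSE)
      names(dfs) <- names(df)
      df <- rbind(df, dfs)
    }
    pm <- parameter_matrix(df)
    attr(pm, "truth") <- c(lab, lab_s)
    pm
  })
}
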