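## Enumeration of the assembly-strategy graph: which candidate assemblies a
## combinatorial short-read/long-read/merging workflow produces, their name
## tags, qualitative factors and dependencies. The enumerator emits a plan
## (graph + factor table + DOT/JSON); it never executes an assembler.
##
## Tag grammar:
##   {stage}{Assembler}K{k}            individual assemblies (stage ct/sc)
##   suffixes _cat, _cd, _rcMin2       concatenation across k-mers,
##                                     redundancy removal, reconciliation
##   ctMIRA, ctEulK29, *_rcCAP3        long-read module
##   aaMin2/<id>/454Cap3, aaRayK{k}/<id>/454Cap3,
##   arMIRA/<id>, arRayK{k}/<id>, rrRayK{k}
##                                     cross-platform merging
##   aaMin2/ctALL/454Cap3, aaMin2/scALL/454Cap3
##                                     all-primaries / all-scaffolded merges

TX_PROGRAMS <- c(Oases = "OASES", Soap = "SOAPdenovo-Trans", Ray = "RAY",
                 Eul = "EULER-SR", MIRA = "MIRA4")

tx_program <- function(tag) unname(TX_PROGRAMS[tag] %||% tag)[1] %||% tag

new_node <- function(assembly_id, module, program, task, kmer, platform,
                     parents) {
  list(assembly_id = assembly_id, module = as.integer(module),
       program = program, task = task, kmer = as.character(kmer),
       platform = platform, parents = as.character(parents))
}

## merged-node k-mer category: keep k when it matches the parent's, else mixed
merge_kmer <- function(parent_kmer, k) {
  if (identical(as.character(parent_kmer), as.character(k))) as.character(k)
  else "mixed"
}

#' Enumerate the short-read assembly module
#'
#' Per assembler: one primary (`ct`) and one scaffolded (`sc`) assembly per
#' k-mer; when two or more k-mers are used, each stage additionally yields
#' a concatenation across k-mers (`_cat`), its 100%-identity
#' redundancy-removed version (`_cd`) and the reconciliation of the latter
#' (`_rcMin2`). With three assemblers and two k-mers this yields 30
#' distinct assemblies.
#'
#' @param assemblers Character vector of assembler tags (default
#'   `c("Oases", "Soap", "Ray")`).
#' @param kmers Integer vector of k-mer sizes (default `c(25, 35)`).
#' @return Named list of strategy nodes.
#' @export
#' @examples
#' length(enumerate_module1())  # 30
enumerate_module1 <- function(assemblers = c("Oases", "Soap", "Ray"),
                              kmers = c(25, 35)) {
  if (length(assemblers) == 0L) txstop("need at least one assembler")
  if (length(kmers) == 0L) txstop("need at least one k-mer")
  if (anyDuplicated(assemblers) || anyDuplicated(kmers))
    txstop("assemblers and kmers must be unique")
  nodes <- list()
  add <- function(n) nodes[[n$assembly_id]] <<- n
  for (a in assemblers) {
    prog <- if (a %in% names(TX_PROGRAMS)) TX_PROGRAMS[[a]] else a
    for (k in kmers) {
      ct <- paste0("ct", a, "K", k)
      add(new_node(ct, 1, prog, "contig", k, "illumina", "reads:illumina"))
      add(new_node(paste0("sc", a, "K", k), 1, prog, "scaffolding", k,
                   "illumina", ct))
    }
    if (length(kmers) >= 2L) {
      for (stage in c("ct", "sc")) {
        base <- paste0(stage, a, "K", kmers)
        cat_id <- paste0(stage, a, "_cat")
        add(new_node(cat_id, 1, "CAT", "concatenation", "mixed",
                     "illumina", base))
        cd_id <- paste0(cat_id, "_cd")
        add(new_node(cd_id, 1, "CD-HIT", "redundancy_removal", "mixed",
                     "illumina", cat_id))
        add(new_node(paste0(cd_id, "_rcMin2"), 1, "Minimus2",
                     "reconciliation", "mixed", "illumina", cd_id))
      }
    }
  }
  nodes
}

#' Enumerate the long-read assembly module
#'
#' Two primary assemblies (an overlap-layout-consensus assembler and a de
#' Bruijn assembler at k-mer 29) and their reconciliation.
#'
#' @return Named list of exactly three strategy nodes: `ctMIRA`,
#'   `ctEulK29` and `ctMIRA_ctEulK29_rcCAP3`.
#' @export
enumerate_module2 <- function() {
  nodes <- list()
  nodes[["ctMIRA"]] <- new_node("ctMIRA", 2, "MIRA4", "contig", "none",
                                "roche454", "reads:roche454")
  nodes[["ctEulK29"]] <- new_node("ctEulK29", 2, "EULER-SR", "contig", "29",
                                  "roche454", "reads:roche454")
  nodes[["ctMIRA_ctEulK29_rcCAP3"]] <-
    new_node("ctMIRA_ctEulK29_rcCAP3", 2, "CAP3", "reconciliation", "mixed",
             "roche454", c("ctMIRA", "ctEulK29"))
  nodes
}

#' Enumerate the cross-platform merging module
#'
#' Three simultaneous merging modes are modelled: reads-reads (`rr`, one
#' node per k-mer), assembly-reads (`ar`, one overlap-assembler node per
#' short-read assembly plus one k-mer-graph node per assembly per k-mer)
#' and assembly-assembly (`aa`, one overlap-merge node per short-read
#' assembly against the long-read reconciled assembly, one k-mer-graph node
#' per individual short-read assembly per k-mer, plus the two special
#' merges of all primaries / all scaffolded assemblies after redundancy
#' removal). Two genuinely ambiguous choice points are exposed:
#' `aa_partners` (pair the short-read assemblies with the reconciled
#' long-read assembly only, the default, or also with its primaries) and
#' `ar_ray` (one k-mer-graph merge node per k-mer, the default, or a single
#' combined node).
#'
#' @param m1,m2 Node lists from [enumerate_module1()] and
#'   [enumerate_module2()]; both must be non-empty.
#' @param kmers K-mer sizes used by the k-mer-graph merger.
#' @param aa_partners `"reconciled"` (default) or `"all"`.
#' @param ar_ray `"per_kmer"` (default) or `"combined"`.
#' @return Named list of strategy nodes.
#' @export
enumerate_module3 <- function(m1, m2, kmers = c(25, 35),
                              aa_partners = c("reconciled", "all"),
                              ar_ray = c("per_kmer", "combined")) {
  if (length(m1) == 0L || length(m2) == 0L)
    txstop("the merging module can only be enabled when both the ",
           "short-read and long-read modules are also enabled")
  aa_partners <- match.arg(aa_partners)
  ar_ray <- match.arg(ar_ray)
  nodes <- list()
  add <- function(n) nodes[[n$assembly_id]] <<- n
  tasks <- vapply(m2, `[[`, "", "task")
  rec_id <- names(m2)[tasks == "reconciliation"]
  if (length(rec_id) != 1L)
    txstop("long-read module must contain exactly one reconciled assembly")
  partner_tag <- function(pid) {
    if (pid == rec_id) "454Cap3"
    else paste0("454", sub("^ct", "", pid))
  }
  partners <- if (aa_partners == "reconciled") rec_id
              else c(names(m2)[tasks == "contig"], rec_id)
  individual <- vapply(m1, function(n)
    n$task %in% c("contig", "scaffolding"), logical(1))
  ## reads-reads
  for (k in kmers)
    add(new_node(paste0("rrRayK", k), 3, "RAY", "merge_rr", k, "hybrid",
                 c("reads:illumina", "reads:roche454")))
  ## assembly-reads
  for (id in names(m1)) {
    n <- m1[[id]]
    add(new_node(paste0("arMIRA/", id), 3, "MIRA4", "merge_ar", n$kmer,
                 "hybrid", c(id, "reads:roche454")))
    if (ar_ray == "per_kmer") {
      for (k in kmers)
        add(new_node(paste0("arRayK", k, "/", id), 3, "RAY", "merge_ar",
                     merge_kmer(n$kmer, k), "hybrid",
                     c(id, "reads:roche454")))
    } else {
      add(new_node(paste0("arRay/", id), 3, "RAY", "merge_ar", "mixed",
                   "hybrid", c(id, "reads:roche454")))
    }
  }
  ## assembly-assembly
  for (id in names(m1)) {
    n <- m1[[id]]
    for (pid in partners)
      add(new_node(paste0("aaMin2/", id, "/", partner_tag(pid)), 3,
                   "Minimus2", "merge_aa", "mixed", "hybrid", c(id, pid)))
    if (individual[[id]]) {
      for (k in kmers) for (pid in partners)
        add(new_node(paste0("aaRayK", k, "/", id, "/", partner_tag(pid)), 3,
                     "RAY", "merge_aa", merge_kmer(n$kmer, k), "hybrid",
                     c(id, pid)))
    }
  }
  ## all-primaries and all-scaffolded merges with the reconciled assembly
  for (stage in c("ct", "sc")) {
    members <- names(m1)[individual &
                           vapply(m1, function(n) substr(n$assembly_id, 1, 2),
                                  "") == stage]
    if (length(members) == 0L) next
    add(new_node(paste0("aaMin2/", stage, "ALL/454Cap3"), 3, "Minimus2",
                 "merge_aa", "mixed", "hybrid", c(members, rec_id)))
  }
  nodes
}

#' Build the full strategy graph
#'
#' @param assemblers,kmers Short-read module configuration.
#' @param modules Integer subset of `c(1, 2, 3)`; module 3 requires both 1
#'   and 2.
#' @param aa_partners,ar_ray Passed to [enumerate_module3()].
#' @return Object of class `"strategy_graph"`: list with `nodes` (named
#'   list of strategy nodes) and `config`.
#' @export
#' @examples
#' g <- strategy_graph()
#' length(g$nodes)  # 181
strategy_graph <- function(assemblers = c("Oases", "Soap", "Ray"),
                           kmers = c(25, 35), modules = c(1, 2, 3),
                           aa_partners = "reconciled",
                           ar_ray = "per_kmer") {
  modules <- sort(unique(as.integer(modules)))
  if (!length(modules) || !all(modules %in% 1:3))
    txstop("'modules' must be a non-empty subset of 1:3")
  if (3L %in% modules && !all(c(1L, 2L) %in% modules))
    txstop("the merging module can only be enabled when both the ",
           "short-read and long-read modules are also enabled")
  m1 <- if (1L %in% modules) enumerate_module1(assemblers, kmers) else list()
  m2 <- if (2L %in% modules) enumerate_module2() else list()
  m3 <- if (3L %in% modules)
    enumerate_module3(m1, m2, kmers, aa_partners, ar_ray) else list()
  structure(list(nodes = c(m1, m2, m3),
                 config = list(assemblers = assemblers, kmers = kmers,
                               modules = modules, aa_partners = aa_partners,
                               ar_ray = ar_ray)),
            class = "strategy_graph")
}

#' @export
print.strategy_graph <- function(x, ...) {
  mods <- vapply(x$nodes, `[[`, integer(1), "module")
  cat("Strategy graph:", length(x$nodes), "assemblies (",
      paste(sprintf("module %d: %d", sort(unique(mods)),
                    table(mods)[as.character(sort(unique(mods)))]),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Qualitative factor table of a strategy graph
#'
#' One row per assembly with the four qualitative factors used by the
#' multivariate stage: the program executed in the last assembling step,
#' the task it performed, the k-mer category (`mixed` for assemblies
#' combining several k-mers, `none` for overlap assemblers) and the
#' sequencing platform (`hybrid` for cross-platform merges).
#'
#' @param graph A [strategy_graph()] (or a plain node list).
#' @return `data.frame` with columns `assembly_id`, `module`, `program`,
#'   `task`, `kmer`, `platform`.
#' @export
factor_table <- function(graph) {
  nodes <- if (inherits(graph, "strategy_graph")) graph$nodes else graph
  data.frame(
    assembly_id = vapply(nodes, `[[`, "", "assembly_id"),
    module = vapply(nodes, `[[`, integer(1), "module"),
    program = vapply(nodes, `[[`, "", "program"),
    task = vapply(nodes, `[[`, "", "task"),
    kmer = vapply(nodes, `[[`, "", "kmer"),
    platform = vapply(nodes, `[[`, "", "platform"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.strategy_graph <- function(x, ...) {
  df <- factor_table(x)
  df$parents <- vapply(x$nodes, function(n)
    paste(n$parents, collapse = ";"), "")
  df
}

#' Parse an assembly name tag back into a strategy node
#'
#' Inverse of the enumerator's naming: given a tag produced under the
#' grammar above (and the configuration it was generated with), rebuilds
#' the node's module, program, task, k-mer category, platform and parents.
#'
#' @param id Assembly name tag.
#' @param assemblers,kmers The configuration the graph was generated with.
#' @return A strategy node (plain list).
#' @export
parse_assembly_tag <- function(id, assemblers = c("Oases", "Soap", "Ray"),
                               kmers = c(25, 35)) {
  rec_id <- "ctMIRA_ctEulK29_rcCAP3"
  partner_from_tag <- function(tag) {
    if (tag == "454Cap3") rec_id else paste0("ct", sub("^454", "", tag))
  }
  if (grepl("^rrRayK[0-9]+$", id)) {
    k <- sub("^rrRayK", "", id)
    return(new_node(id, 3, "RAY", "merge_rr", k, "hybrid",
                    c("reads:illumina", "reads:roche454")))
  }
  m <- regmatches(id, regexec("^arMIRA/(.+)$", id))[[1]]
  if (length(m)) {
    inner <- parse_assembly_tag(m[2], assemblers, kmers)
    return(new_node(id, 3, "MIRA4", "merge_ar", inner$kmer, "hybrid",
                    c(m[2], "reads:roche454")))
  }
  m <- regmatches(id, regexec("^arRayK([0-9]+)/(.+)$", id))[[1]]
  if (length(m)) {
    inner <- parse_assembly_tag(m[3], assemblers, kmers)
    return(new_node(id, 3, "RAY", "merge_ar", merge_kmer(inner$kmer, m[2]),
                    "hybrid", c(m[3], "reads:roche454")))
  }
  m <- regmatches(id, regexec("^aaMin2/(ct|sc)ALL/454Cap3$", id))[[1]]
  if (length(m)) {
    members <- unlist(lapply(assemblers, function(a)
      paste0(m[2], a, "K", kmers)))
    return(new_node(id, 3, "Minimus2", "merge_aa", "mixed", "hybrid",
                    c(members, rec_id)))
  }
  m <- regmatches(id, regexec("^aaMin2/(.+)/(454[A-Za-z0-9]+)$", id))[[1]]
  if (length(m)) {
    return(new_node(id, 3, "Minimus2", "merge_aa", "mixed", "hybrid",
                    c(m[2], partner_from_tag(m[3]))))
  }
  m <- regmatches(id, regexec("^aaRayK([0-9]+)/(.+)/(454[A-Za-z0-9]+)$",
                              id))[[1]]
  if (length(m)) {
    inner <- parse_assembly_tag(m[3], assemblers, kmers)
    return(new_node(id, 3, "RAY", "merge_aa", merge_kmer(inner$kmer, m[2]),
                    "hybrid", c(m[3], partner_from_tag(m[4]))))
  }
  if (id == "ctMIRA")
    return(new_node(id, 2, "MIRA4", "contig", "none", "roche454",
                    "reads:roche454"))
  if (id == "ctEulK29")
    return(new_node(id, 2, "EULER-SR", "contig", "29", "roche454",
                    "reads:roche454"))
  if (id == rec_id)
    return(new_node(id, 2, "CAP3", "reconciliation", "mixed", "roche454",
                    c("ctMIRA", "ctEulK29")))
  m <- regmatches(id, regexec("^(ct|sc)(.+)_cat_cd_rcMin2$", id))[[1]]
  if (length(m))
    return(new_node(id, 1, "Minimus2", "reconciliation", "mixed", "illumina",
                    paste0(m[2], m[3], "_cat_cd")))
  m <- regmatches(id, regexec("^(ct|sc)(.+)_cat_cd$", id))[[1]]
  if (length(m))
    return(new_node(id, 1, "CD-HIT", "redundancy_removal", "mixed",
                    "illumina", paste0(m[2], m[3], "_cat")))
  m <- regmatches(id, regexec("^(ct|sc)(.+)_cat$", id))[[1]]
  if (length(m))
    return(new_node(id, 1, "CAT", "concatenation", "mixed", "illumina",
                    paste0(m[2], m[3], "K", kmers)))
  m <- regmatches(id, regexec("^(ct|sc)([A-Za-z0-9]+?)K([0-9]+)$", id))[[1]]
  if (length(m)) {
    prog <- if (m[3] %in% names(TX_PROGRAMS)) TX_PROGRAMS[[m[3]]] else m[3]
    task <- if (m[2] == "ct") "contig" else "scaffolding"
    parents <- if (m[2] == "ct") "reads:illumina"
               else paste0("ct", m[3], "K", m[4])
    return(new_node(id, 1, prog, task, m[4], "illumina", parents))
  }
  txstop("cannot parse assembly tag: ", id)
}

#' Export a strategy graph
#'
#' `write_strategy_json()` writes the node list as JSON;
#' `write_strategy_dot()` writes a GraphViz DOT file with one edge per
#' parent dependency (read-set sentinels drawn as boxes).
#'
#' @param graph A [strategy_graph()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_strategy_json <- function(graph, path) {
  stopifnot(inherits(graph, "strategy_graph"))
  jsonlite::write_json(list(config = graph$config,
                            nodes = unname(graph$nodes)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_strategy_json
#' @export
write_strategy_dot <- function(graph, path) {
  stopifnot(inherits(graph, "strategy_graph"))
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph strategies {", "  rankdir=LR;")
  sentinels <- unique(unlist(lapply(graph$nodes, function(n)
    grep("^reads:", n$parents, value = TRUE))))
  lines <- c(lines, sprintf("  %s [shape=box];", q(sentinels)))
  for (n in graph$nodes) {
    lines <- c(lines, sprintf("  %s [label=%s];", q(n$assembly_id),
                              q(paste0(n$assembly_id, "\\n", n$program))))
    lines <- c(lines, sprintf("  %s -> %s;", q(n$parents), q(n$assembly_id)))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
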