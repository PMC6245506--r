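# Independent brute-force oracles, deliberately implemented with different
# algorithms than the package (direct scans, no regex run detection, naive
# agglomeration) so agreement is informative.

## Nx by direct cumulative scan over the sorted lengths
oracle_nx <- function(lens, frac) {
  lens <- sort(lens, decreasing = TRUE)
  target <- frac * sum(lens)
  acc <- 0
  for (L in lens) {
    acc <- acc + L
    if (acc >= target) return(L)
  }
  stop("unreachable")
}

## N count and maximal-run count by character-wise rle scan
oracle_nstats <- function(seqs) {
  ns <- 0L; runs <- 0L
  for (s in seqs) {
    is_n <- strsplit(toupper(s), "", fixed = TRUE)[[1]] == "N"
    r <- rle(is_n)
    runs <- runs + sum(r$values)
    ns <- ns + sum(r$lengths[r$values])
  }
  list(ns = ns, runs = runs)
}

## random small assembly with N runs sprinkled in
random_assembly <- function(id = "rnd", n_min = 3, n_max = 25,
                            len_min = 15, len_max = 120) {
  n <- sample(n_min:n_max, 1)
  seqs <- vapply(seq_len(n), function(i) {
    L <- sample(len_min:len_max, 1)
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (runif(1) < 0.6) {
      k <- sample(1:3, 1)
      for (j in seq_len(k)) {
        glen <- sample(1:5, 1)
        pos <- sample(seq_len(max(1, L - glen)), 1)
        ch[pos:(pos + glen - 1)] <- "N"
      }
    }
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- sprintf("%s_c%03d", id, seq_len(n))
  assembly_record(id, seqs)
}

## full SVD-based PCA oracle on the standardized active matrix
oracle_pca <- function(X, population = TRUE) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, function(v)
    sqrt(sum((v - mean(v))^2) / if (population) n else n - 1))
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  sv <- svd(Z)
  lambda <- sv$d^2 / if (population) n else n - 1
  list(Z = Z, eigenvalues = lambda, coords = sv$u %*% diag(sv$d),
       vectors = sv$v)
}

## naive Ward agglomeration: at each step merge the pair of clusters with
## the smallest within-inertia increase; returns the partition after each
## merge as a canonical membership vector
oracle_ward_partitions <- function(coords) {
  n <- nrow(coords)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  repeat {
    m <- length(clusters)
    if (m == 1L) break
    best <- NULL; best_cost <- Inf
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(coords[a, , drop = FALSE])
      cb <- colMeans(coords[b, , drop = FALSE])
      cost <- length(a) * length(b) / (length(a) + length(b)) *
        sum((ca - cb)^2)
      if (cost < best_cost - 1e-12) {
        best_cost <- cost; best <- c(i, j)
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    memb <- integer(n)
    for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- canonical_labels(memb)
  }
  partitions
}

## relabel a membership vector by order of first appearance
canonical_labels <- function(x) {
  match(x, unique(x))
}

## adjusted Rand index between two labelings (closed form)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab))); n <- ch2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

## default monotone degradation grid used in end-to-end recovery checks:
## severity increases jointly along all four axes
degradation_grid <- function(seed) {
  frag <- c(0, 0.5, 1, 2, 3)
  dup <- c(0, 0.1, 0.25, 0.4, 0.6)
  gap <- c(0, 0.1, 0.25, 0.5, 0.8)
  chi <- c(0, 0.05, 0.1, 0.2, 0.3)
  lapply(seq_along(frag), function(i)
    degradation_spec(fragmentation_rate = frag[i],
                     duplication_fraction = dup[i],
                     gap_rate = gap[i], chimera_fraction = chi[i],
                     seed = seed + i))
}

## one end-to-end trial: degrade a reference-like transcriptome along the
## grid, evaluate everything with the metric engine, rank against the
## clean reference, return the MD sequence in grid order
md_degradation_trial <- function(seed, n_transcripts = 60) {
  base <- make_base_transcriptome(n_transcripts, c(300, 1500), seed = seed)
  ref <- degrade(base, degradation_spec(seed = seed + 999))
  levels <- degradation_grid(seed)
  evaluate <- function(d, id) {
    mv <- build_metric_vector(d$assembly, aln = d$alignment,
                              hits = d$proteins, orthologs = d$orthologs,
                              read_mode = "paired")
    data.frame(assembly_id = id, role = "", t(as.numeric(mv)),
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  rows <- lapply(seq_along(levels), function(i)
    evaluate(degrade(base, levels[[i]]), sprintf("lev%d", i)))
  refrow <- evaluate(ref, "reference")
  df <- do.call(rbind, c(rows, list(refrow)))
  names(df) <- c("assembly_id", "role", names(metric_trends()))
  df$role <- c(rep("active", length(levels)), "supplementary")
  keep <- names(metric_trends())[vapply(names(metric_trends()), function(p)
    var(df[[p]][df$role == "active"]) > 0, logical(1))]
  pm <- parameter_matrix(df[, c("assembly_id", "role", keep)])
  model <- fit_pca_with_supplementary(pm, n_components = 3)
  rk <- rank_by_mean_distance(model)
  rk$MD[match(sprintf("lev%d", seq_along(levels)), rk$assembly_id)]
}

## tiny deterministic parameter matrix for multivariate unit tests
toy_pm <- function(n_active = 12, n_sup = 2, p = 5, seed = 101) {
  set.seed(seed)
  X <- matrix(rnorm(n_active * p), nrow = n_active, ncol = p)
  S <- matrix(rnorm(n_sup * p), nrow = n_sup, ncol = p)
  df <- data.frame(
    assembly_id = c(sprintf("a%02d", seq_len(n_active)),
                    sprintf("r%02d", seq_len(n_sup))),
    role = rep(c("active", "supplementary"), c(n_active, n_sup)),
    rbind(X, S), stringsAsFactors = FALSE)
  names(df) <- c("assembly_id", "role", sprintf("p%d", seq_len(p)))
  parameter_matrix(df)
}
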