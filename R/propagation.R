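# Heat-diffusion network propagation of mutated genes over a PPI graph:
# random walk with restart on the symmetrically degree-normalized adjacency,
# iterated to steady state, followed by gene-set scoring and co-clustering of
# sublines and gene sets.

#' Propagation configuration
#'
#' @param restart Restart probability `alpha` in (0, 1]: the update is
#'   `F <- alpha * W' F + (1 - alpha) * F0` with
#'   `W' = D^(-1/2) A D^(-1/2)`. Default 0.5.
#' @param tol L1 convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @param seed_weighting `"binary"` (1 per mutated gene) or `"vaf"` (sum of
#'   passing VAFs per gene).
#' @return List of class `propagation_config`.
#' @export
propagation_config <- function(restart = 0.5, tol = 1e-8, max_iter = 10000L,
                               seed_weighting = c("binary", "vaf")) {
  if (restart <= 0 || restart > 1)
    stop("configuration error: restart must lie in (0, 1]")
  if (tol <= 0) stop("configuration error: tol must be > 0")
  structure(list(restart = restart, tol = tol,
                 max_iter = as.integer(max_iter),
                 seed_weighting = match.arg(seed_weighting)),
            class = "propagation_config")
}

#' Seed heat vector for one subline
#'
#' Binary mode: weight 1 for each graph gene carrying at least one passing
#' variant in this subline. VAF mode: the subline's VAF summed over the
#' gene's passing variants. Mutated genes absent from the graph are dropped
#' (their count is attached as attribute `n_dropped` and messaged). The
#' vector is normalized to sum 1 over all graph vertices.
#'
#' @param trajectories Trajectory data frame from [filter_and_classify()].
#' @param level `"low"` or `"high"` (which resistant subline of the trio).
#' @param graph igraph graph.
#' @param cfg A [propagation_config()].
#' @return Named numeric vector over all graph vertices, summing to 1.
#' @export
seed_vector <- function(trajectories, level, graph,
                        cfg = propagation_config()) {
  nodes <- igraph::V(graph)$name
  sub <- trajectories[trajectories[[paste0("pass_", level)]], , drop = FALSE]
  gene <- toupper(sub$gene)
  w <- if (cfg$seed_weighting == "binary") {
    tapply(rep(1, length(gene)), gene, function(x) 1)
  } else {
    tapply(sub[[paste0("vaf_", level)]], gene, sum)
  }
  w <- stats::setNames(as.numeric(w), names(w))
  present <- names(w) %in% nodes
  n_dropped <- sum(!present)
  if (n_dropped > 0)
    message(n_dropped, " mutated gene(s) absent from the graph were dropped")
  w <- w[present]
  if (length(w) == 0 || sum(w) == 0)
    stop("input error: no mutated gene present in the graph (empty seed)")
  f0 <- stats::setNames(numeric(length(nodes)), nodes)
  f0[names(w)] <- w
  f0 <- f0 / sum(f0)
  attr(f0, "n_dropped") <- n_dropped
  f0
}

#' @keywords internal
norm_adjacency <- function(graph) {
  a <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  d <- Matrix::rowSums(a)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Matrix::Diagonal(x = dinv) %*% a %*% Matrix::Diagonal(x = dinv)
}

#' Propagate heat to steady state
#'
#' Iterates `F <- alpha W' F + (1 - alpha) F0` with symmetric degree
#' normalization `W' = D^(-1/2) A D^(-1/2)` until the L1 change falls below
#' `tol`. The fixed point equals the direct linear solve
#' `(I - alpha W') F = (1 - alpha) F0`. Heat seeded in one graph component
#' never reaches another; isolated vertices only retain their restart mass.
#'
#' @param f0 Seed vector over graph vertices (normalized; see
#'   [seed_vector()]).
#' @param graph igraph graph.
#' @param cfg A [propagation_config()].
#' @return List: `scores` (named steady-state vector), `iterations`,
#'   `residual` (final L1 change).
#' @export
propagate <- function(f0, graph, cfg = propagation_config()) {
  nodes <- igraph::V(graph)$name
  if (is.null(names(f0))) names(f0) <- nodes
  f0 <- f0[nodes]
  if (anyNA(f0)) stop("input error: seed vector does not cover graph nodes")
  w <- norm_adjacency(graph)
  a <- cfg$restart
  f <- f0
  for (it in seq_len(cfg$max_iter)) {
    f_new <- a * as.vector(w %*% f) + (1 - a) * f0
    delta <- sum(abs(f_new - f))
    f <- f_new
    if (delta < cfg$tol)
      return(list(scores = stats::setNames(f, nodes), iterations = it,
                  residual = delta))
  }
  stop("convergence error: propagation did not converge in ", cfg$max_iter,
       " iterations (last L1 change ", format(delta), ")")
}

#' Propagate every subline and assemble the score matrix
#'
#' Runs [seed_vector()] and [propagate()] for the low and high subline of
#' each trio and normalizes each subline's score column to sum 1, so heat is
#' conserved globally per subline.
#'
#' @param trajectories List of trajectory data frames (one per trio).
#' @param graph igraph graph.
#' @param cfg A [propagation_config()].
#' @return List of class `propagation_result`: `scores` (gene x subline
#'   matrix), `iterations` (named vector), `config`.
#' @export
propagate_sublines <- function(trajectories, graph,
                               cfg = propagation_config()) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  cols <- list(); iters <- integer(0)
  for (tr in trajectories) {
    for (level in c("low", "high")) {
      lbl <- subline_label(tr$drug[1], level, tr$replicate[1])
      f0 <- seed_vector(tr, level, graph, cfg)
      pr <- propagate(f0, graph, cfg)
      cols[[lbl]] <- pr$scores / sum(pr$scores)
      iters[lbl] <- pr$iterations
    }
  }
  scores <- do.call(cbind, cols)
  structure(list(scores = scores, iterations = iters, config = cfg),
            class = "propagation_result")
}

#' Gene-set scores from propagated heat
#'
#' Raw entry = mean propagated score over the set's genes present in the
#' graph; the scaled matrix z-scores each gene set across sublines. Sets
#' with no graph genes get an `NA` row (excluded from clustering).
#'
#' @param scores Gene x subline score matrix (e.g.
#'   `propagate_sublines()$scores`).
#' @param gene_sets Named list of gene vectors.
#' @return List: `raw` and `scaled` gene-set x subline matrices.
#' @export
score_genesets <- function(scores, gene_sets) {
  genes <- rownames(scores)
  raw <- t(vapply(gene_sets, function(set) {
    g <- intersect(toupper(set), toupper(genes))
    if (length(g) == 0) return(rep(NA_real_, ncol(scores)))
    colMeans(scores[toupper(genes) %in% toupper(set), , drop = FALSE])
  }, numeric(ncol(scores))))
  colnames(raw) <- colnames(scores)
  scaled <- t(apply(raw, 1, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x)) / s
  }))
  colnames(scaled) <- colnames(scores)
  list(raw = raw, scaled = scaled)
}

#' Cluster column profiles by correlation distance
#'
#' Agglomerative clustering (average linkage) on `1 - Pearson correlation`
#' between columns. `k` is either supplied or chosen by the largest average
#' silhouette width over `k in 2..min(10, n - 1)`. Constant columns (zero
#' variance) are dropped with a warning; a single column yields the identity
#' partition.
#'
#' @param mat Numeric matrix; columns are clustered (pass `t(mat)` to
#'   cluster rows, e.g. gene sets).
#' @param k Number of clusters, or `NULL` for silhouette-automatic.
#' @return Named integer vector of cluster memberships, with attribute `k`.
#' @export
cluster_profiles <- function(mat, k = NULL) {
  mat <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant column(s) dropped before clustering")
    mat <- mat[, sds > 0, drop = FALSE]
  }
  n <- ncol(mat)
  if (n == 0) stop("input error: nothing to cluster")
  if (n == 1) {
    out <- stats::setNames(1L, colnames(mat))
    attr(out, "k") <- 1L
    return(out)
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  hc <- stats::hclust(d, method = "average")
  if (is.null(k)) {
    ks <- 2:min(10L, n - 1L)
    if (length(ks) == 0 || n == 2) {
      k <- min(2L, n)
    } else {
      sil <- vapply(ks, function(kk) {
        cl <- stats::cutree(hc, kk)
        mean(cluster::silhouette(cl, d)[, "sil_width"])
      }, 0)
      k <- ks[which.max(sil)]
    }
  }
  out <- stats::cutree(hc, k)
  attr(out, "k") <- k
  out
}

#' Compare a propagation gene-set matrix with an enrichment matrix
#'
#' Spearman rank correlation per shared gene-set row across shared subline
#' columns, plus the median across rows. No significance is attached.
#'
#' @param prop_mat Gene-set x subline matrix from propagation.
#' @param enrich_mat Gene-set x subline enrichment matrix (e.g. GSVA scores
#'   read via [read_enrichment_matrix()]).
#' @return List: `per_set` (named correlations) and `median`.
#' @export
compare_matrices <- function(prop_mat, enrich_mat) {
  cols <- intersect(colnames(prop_mat), colnames(enrich_mat))
  rows <- intersect(rownames(prop_mat), rownames(enrich_mat))
  if (length(cols) < 3)
    stop("input error: need at least 3 shared subline columns, got ",
         length(cols))
  per_set <- vapply(rows, function(r)
    stats::cor(prop_mat[r, cols], enrich_mat[r, cols], method = "spearman"),
    0)
  list(per_set = per_set, median = stats::median(per_set, na.rm = TRUE))
}
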