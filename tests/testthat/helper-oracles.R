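# Independent oracles used across test files. These deliberately share no
# code with the package: naive loops and dense algebra only.

# Brute-force reimplementation of the filter cascade, one variant at a time.
# vars: data frame with, per stage s in {s, l, h}: called_<s>, depth_<s>,
# alt_<s>; plus consequence and dist.
oracle_cascade <- function(vars, min_depth = 10, smax = 0.05, dmin = 0.15,
                           deep = 20) {
  n <- nrow(vars)
  verdict <- character(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    v <- vars[i, ]
    vaf <- function(called, depth, alt) {
      if (!called || depth == 0) NA_real_ else alt / depth
    }
    vs <- vaf(v$called_s, v$depth_s, v$alt_s)
    vl <- vaf(v$called_l, v$depth_l, v$alt_l)
    vh <- vaf(v$called_h, v$depth_h, v$alt_h)
    covered <- FALSE
    if (v$called_s && v$depth_s > 0 && v$depth_s >= min_depth) covered <- TRUE
    if (v$called_l && v$depth_l > 0 && v$depth_l >= min_depth) covered <- TRUE
    if (v$called_h && v$depth_h > 0 && v$depth_h >= min_depth) covered <- TRUE
    vs0 <- if (is.na(vs)) 0 else vs
    vl0 <- if (is.na(vl)) 0 else vl
    vh0 <- if (is.na(vh)) 0 else vh
    dl <- vl0 - vs0
    dh <- vh0 - vs0
    if (!covered) {
      verdict[i] <- "FAIL_depth"; cls[i] <- "NONE"
    } else if (vs0 >= smax) {
      verdict[i] <- "FAIL_sensitive"; cls[i] <- "NONE"
    } else if (v$consequence == "intronic" && v$dist > deep) {
      verdict[i] <- "FAIL_intronic"; cls[i] <- "NONE"
    } else if (!(max(dl, dh) > dmin)) {
      verdict[i] <- "FAIL_delta"; cls[i] <- "NONE"
    } else {
      verdict[i] <- "PASS"
      if (dh > dmin && dl <= dmin) cls[i] <- "ACQUIRED_HIGH"
      else if (dl > dmin && dh <= dmin) cls[i] <- "LOW_ONLY"
      else if (vl0 - vh0 > dmin) cls[i] <- "SHARED_REDUCED_HIGH"
      else cls[i] <- "SHARED_CONSTANT"
    }
  }
  data.frame(verdict = verdict, clonal_class = cls,
             stringsAsFactors = FALSE)
}

# Random per-variant stage table for the oracle, plus the matching trio in
# the package's calls layout.
random_trio_case <- function(n = 50, seed = 1) {
  set.seed(seed)
  vars <- data.frame(
    chrom = paste0("V", seq_len(n)), pos = 100 + seq_len(n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    consequence = sample(c("missense", "synonymous", "intronic"), n,
                         replace = TRUE),
    dist = sample(c(0, 5, 15, 25, 100), n, replace = TRUE))
  vars$alt <- vapply(vars$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  vars$dist[vars$consequence != "intronic"] <- 0
  for (s in c("s", "l", "h")) {
    called <- stats::runif(n) < 0.8
    depth <- sample(0:60, n, replace = TRUE)
    alt <- rbinom(n, depth, stats::runif(n, 0, 0.7))
    vars[[paste0("called_", s)]] <- called
    vars[[paste0("depth_", s)]] <- depth
    vars[[paste0("alt_", s)]] <- alt
  }
  stage_calls <- function(s) {
    keep <- vars[[paste0("called_", s)]]
    data.frame(chrom = vars$chrom[keep], pos = vars$pos[keep],
               ref = vars$ref[keep], alt = vars$alt[keep],
               gene = vars$chrom[keep], consequence = vars$consequence[keep],
               distance_to_exon = vars$dist[keep],
               depth = vars[[paste0("depth_", s)]][keep],
               alt_depth = vars[[paste0("alt_", s)]][keep],
               stringsAsFactors = FALSE)
  }
  trio <- list(sensitive = stage_calls("s"), low = stage_calls("l"),
               high = stage_calls("h"), drug = "imatinib", replicate = 1L)
  list(vars = vars, trio = trio)
}

# Grid search over the exposure simplex (free non-negative scale solved in
# closed form per grid point) — oracle for 2-signature NNLS fits.
oracle_grid_fit2 <- function(sigmat, p, step = 0.001) {
  stopifnot(ncol(sigmat) == 2)
  best_a <- NA_real_; best_r <- Inf
  for (a in seq(0, 1, by = step)) {
    e <- sigmat[, 1] * a + sigmat[, 2] * (1 - a)
    cc <- max(0, sum(e * p) / sum(e * e))
    r <- sum((cc * e - p)^2)
    if (r < best_r) { best_r <- r; best_a <- a }
  }
  c(best_a, 1 - best_a)
}

# Dense closed-form steady state (I - a W')^{-1} (1-a) F0.
oracle_propagate <- function(graph, f0, alpha) {
  a_mat <- as.matrix(igraph::as_adjacency_matrix(graph))
  deg <- rowSums(a_mat)
  dis <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  w <- diag(dis) %*% a_mat %*% diag(dis)
  as.vector(solve(diag(nrow(a_mat)) - alpha * w, (1 - alpha) * f0))
}

# Newman modularity of a partition, computed from the definition.
oracle_modularity <- function(graph, membership) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(graph)
  q <- 0
  for (c in unique(membership)) {
    in_c <- which(membership == c)
    e_c <- sum(el[, 1] %in% in_c & el[, 2] %in% in_c)
    q <- q + e_c / m - (sum(deg[in_c]) / (2 * m))^2
  }
  q
}

tv_distance <- function(p, q) 0.5 * sum(abs(p / sum(p) - q / sum(q)))

# Adjusted Rand index from the contingency-table definition.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
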