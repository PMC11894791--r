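# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: cluster forming via igraph components, F values
# via direct formulas, the permutation null via full enumeration.

# brute-force cluster forming on a small F matrix
oracle_form_clusters <- function(fmat, thresh, min_run, neighbors) {
  ns <- nrow(fmat); nt <- ncol(fmat)
  keep <- matrix(FALSE, ns, nt)
  for (s in seq_len(ns)) {
    r <- rle(fmat[s, ] > thresh)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_run) keep[s, starts[k]:ends[k]] <- TRUE
    }
  }
  pts <- which(keep, arr.ind = TRUE)
  if (nrow(pts) == 0) return(numeric(0))
  id <- function(s, t) paste(s, t)
  g <- igraph::make_empty_graph(n = nrow(pts), directed = FALSE)
  key <- id(pts[, 1], pts[, 2])
  edges <- c()
  for (a in seq_len(nrow(pts))) {
    s <- pts[a, 1]; t <- pts[a, 2]
    for (cand in list(c(s, t + 1), c(s, t - 1))) {
      b <- match(id(cand[1], cand[2]), key)
      if (!is.na(b) && b > a) edges <- c(edges, a, b)
    }
    for (s2 in neighbors[[s]]) {
      b <- match(id(s2, t), key)
      if (!is.na(b) && b > a) edges <- c(edges, a, b)
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  masses <- vapply(split(seq_len(nrow(pts)), comp),
                   function(ix) sum(fmat[pts[ix, , drop = FALSE]]), numeric(1))
  sort(unname(masses), decreasing = TRUE)
}

# direct paired F = t^2 at one point from raw numbers
oracle_paired_f <- function(d) {
  n <- length(d)
  (mean(d) / (sd(d) / sqrt(n)))^2
}

# exhaustive sign-flip null of the max cluster mass for a paired design
oracle_exhaustive_null <- function(X, ns, nt, thresh, min_run, neighbors) {
  n <- nrow(X)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  apply(signs, 1, function(s) {
    Xs <- X * s
    f <- apply(Xs, 2, oracle_paired_f)
    f[!is.finite(f)] <- 0
    m <- oracle_form_clusters(matrix(f, ns, nt), thresh, min_run, neighbors)
    if (length(m)) m[1] else 0
  })
}

# quick grid layouts/epochs used by several files
make_line_layout <- function(n) {
  pos <- cbind(x = seq_len(n), y = 0, z = 0)
  rownames(pos) <- sprintf("E%03d", seq_len(n))
  edges <- neighbors_from_distance(pos, 1.5)
  structure(
    list(ids = rownames(pos), positions = pos, edges = edges,
         neighbors = erpmem:::edges_to_neighbors(edges, n),
         rois = list(posterior = rownames(pos), anterior = character(0)),
         adjacency_threshold = 1.5),
    class = "sensor_layout"
  )
}

make_epochs <- function(values, conditions, subjects, sample_rate = 250,
                        t0 = 0) {
  nt <- dim(values)[4]
  dt <- 1000 / sample_rate
  epoch_set(values, seq(t0, by = dt, length.out = nt),
            sprintf("E%03d", seq_len(dim(values)[3])), conditions, subjects,
            sample_rate, baseline_ms = c(t0, t0))
}
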