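# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths wherever they act as a
# reference: brute-force enumeration, double loops, closed forms.

# --- exhaustive DAG scoring oracle -----------------------------------------

# Every DAG over `nodes` (feasible up to ~3 nodes: 25 DAGs).
all_dags <- function(nodes) {
  subsets <- function(v) {
    out <- list(character(0))
    for (x in v) out <- c(out, lapply(out, c, x))
    unique(out)
  }
  ps <- lapply(nodes, function(v) subsets(setdiff(nodes, v)))
  combos <- expand.grid(lapply(ps, seq_along))
  dags <- list()
  for (i in seq_len(nrow(combos))) {
    dag <- bn_dag(nodes)
    for (j in seq_along(nodes)) {
      for (p in ps[[j]][[combos[i, j]]]) {
        dag <- fusionlab:::dag_add_edge(dag, p, nodes[j])
      }
    }
    if (!is.null(fusionlab:::topo_order(dag))) dags[[length(dags) + 1]] <- dag
  }
  dags
}

best_exhaustive_score <- function(data) {
  max(vapply(all_dags(names(data)), aic_score, numeric(1), data = data))
}

# Undirected skeleton as a canonical string set.
dag_skeleton <- function(dag) {
  e <- dag_edges(dag)
  if (nrow(e) == 0) return(character(0))
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "~"))
}

skeleton_shd <- function(dag_a, dag_b) {
  sa <- dag_skeleton(dag_a)
  sb <- dag_skeleton(dag_b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# --- 5-node chain fixture for structure recovery ---------------------------

CHAIN_LEVELS <- list(v1 = 3L, v2 = 4L, v3 = 4L, v4 = 5L, v5 = 3L)
CHAIN_TRUTH <- bn_dag(names(CHAIN_LEVELS),
                      rbind(c("v1", "v2"), c("v2", "v3"),
                            c("v3", "v4"), c("v4", "v5")))

# Ancestral sampling down the chain: each child tracks a fixed level map of
# its parent with probability `keep`, else is uniform.
sample_chain_data <- function(n, keep = 0.75) {
  out <- list()
  prev <- NULL
  for (nm in names(CHAIN_LEVELS)) {
    r <- CHAIN_LEVELS[[nm]]
    if (is.null(prev)) {
      x <- sample.int(r, n, replace = TRUE)
    } else {
      map <- (seq_len(CHAIN_LEVELS[[prev]]) - 1L) %% r + 1L
      x <- ifelse(runif(n) < keep, map[out[[prev]]],
                  sample.int(r, n, replace = TRUE))
    }
    out[[nm]] <- x
    prev <- nm
  }
  as.data.frame(lapply(out, function(v) factor(v)))
}

# --- fixed clinical-shaped network for inference checks --------------------

# DAG mirroring the domain structure (Bethesda and age drive risk; sex and
# size disconnected), parameters fitted on one synthetic draw.
make_clinical_net <- function(seed = 42, n = 400) {
  cfg <- generator_config(n_samples = n, n_genes = 2, n_informative = 1,
                          seed = seed)
  d <- discretize_clinical(generate_clinical(cfg))
  bn_data <- d[c("sex", "age_band", "size_band", "bethesda")]
  bn_data$risk <- d$label
  dag <- bn_dag(c("sex", "age_band", "size_band", "bethesda", "risk"),
                rbind(c("bethesda", "risk"), c("age_band", "risk")))
  estimate_parameters(dag, bn_data, iss = 1)
}

# --- rank-sum enumeration oracle -------------------------------------------

# Exact two-sided p by enumerating all assignments of the pooled sample to
# the first group (no ties assumed).
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pooled), nx)
  ws <- apply(splits, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# --- ReliefF double-loop oracle --------------------------------------------

# Straightforward re-statement of the update rule with explicit loops;
# binary classes, m = all instances, Manhattan distance on min-max-scaled
# features, distance ties broken by index.
relieff_oracle <- function(m, y, k) {
  n <- nrow(m)
  p <- ncol(m)
  rngs <- apply(m, 2, function(col) diff(range(col)))
  scale <- ifelse(rngs > 0, rngs, 1)
  ms <- sweep(sweep(m, 2, apply(m, 2, min), "-"), 2, scale, "/")
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sum(abs(ms[i, rngs > 0] - ms[j, rngs > 0]))
    }
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    hits <- hits[order(d[hits], hits)][seq_len(k)]
    misses <- misses[order(d[misses], misses)][seq_len(k)]
    for (f in seq_len(p)) {
      if (rngs[f] == 0) next
      for (h in hits) w[f] <- w[f] - abs(ms[i, f] - ms[h, f]) / (n * k)
      for (mi in misses) w[f] <- w[f] + abs(ms[i, f] - ms[mi, f]) / (n * k)
    }
  }
  w
}

# --- misc ------------------------------------------------------------------

# Trapezoidal AUC of a score against a binary label, independent of pROC.
simple_auc <- function(score, label) {
  pos <- score[label == "malignant"]
  neg <- score[label == "benign"]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

default_test_config <- function(...) {
  generator_config(n_samples = 200, n_genes = 163, n_informative = 15, ...)
}
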