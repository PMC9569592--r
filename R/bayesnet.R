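# Discrete Bayesian networks over clinical variables: DAG container,
# decomposable AIC scoring, Tabu-search structure learning, Dirichlet
# posterior-mean parameter estimation, and inference by likelihood
# weighting or exact enumeration.

#' Construct a directed acyclic graph over named nodes
#'
#' @param nodes Character vector of node names.
#' @param edges Optional two-column matrix or data frame of directed edges
#'   (from, to).
#' @return An object of class `bn_dag`: a node list plus a parent set per
#'   node.
#' @export
bn_dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  parents <- setNames(rep(list(character(0)), length(nodes)), nodes)
  dag <- structure(list(nodes = nodes, parents = parents), class = "bn_dag")
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    for (i in seq_len(nrow(edges))) {
      dag <- dag_add_edge(dag, edges[i, 1], edges[i, 2])
    }
    if (is.null(topo_order(dag))) abort("edge set contains a cycle.")
  }
  dag
}

dag_add_edge <- function(dag, from, to) {
  stopifnot(from %in% dag$nodes, to %in% dag$nodes, from != to)
  if (!(from %in% dag$parents[[to]])) {
    dag$parents[[to]] <- sort(c(dag$parents[[to]], from))
  }
  dag
}

dag_drop_edge <- function(dag, from, to) {
  dag$parents[[to]] <- setdiff(dag$parents[[to]], from)
  dag
}

dag_has_edge <- function(dag, from, to) from %in% dag$parents[[to]]

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<bn_dag> %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  if (nrow(e) > 0) {
    cat(paste0("  ", e$from, " -> ", e$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Edge list of a DAG as a tibble
#' @param dag A [bn_dag()].
#' @return A tibble with columns `from` and `to`, ordered lexicographically.
#' @export
dag_edges <- function(dag) {
  res <- purrr::map_dfr(dag$nodes, function(v) {
    ps <- dag$parents[[v]]
    if (length(ps) == 0) return(tibble::tibble(from = character(0), to = character(0)))
    tibble::tibble(from = ps, to = v)
  })
  dplyr::arrange(res, .data$from, .data$to)
}

# Topological order, or NULL if the graph is cyclic.
topo_order <- function(dag) {
  indeg <- vapply(dag$parents, length, integer(1))
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0])
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    for (w in dag$nodes) {
      if (v %in% dag$parents[[w]]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) avail <- sort(c(avail, w))
      }
    }
  }
  if (length(order) == length(dag$nodes)) order else NULL
}

# Would adding from -> to create a cycle? (is `from` reachable from `to`)
creates_cycle <- function(dag, from, to) {
  frontier <- to
  seen <- character(0)
  children <- dag_children_map(dag)
  while (length(frontier) > 0) {
    v <- frontier[1]
    frontier <- frontier[-1]
    if (v == from) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, children[[v]])
  }
  FALSE
}

dag_children_map <- function(dag) {
  ch <- setNames(rep(list(character(0)), length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) for (p in dag$parents[[v]]) ch[[p]] <- c(ch[[p]], v)
  ch
}

#' Markov blanket of a node
#'
#' Parents, children and the children's other parents.
#' @param dag A [bn_dag()].
#' @param node Node name.
#' @return Character vector of node names (excluding `node` itself).
#' @export
markov_blanket <- function(dag, node) {
  stopifnot(node %in% dag$nodes)
  ch_map <- dag_children_map(dag)
  children <- ch_map[[node]]
  spouses <- unlist(lapply(children, function(c) dag$parents[[c]]))
  sort(setdiff(unique(c(dag$parents[[node]], children, spouses)), node))
}

# Ensure the scoring data is a data.frame of factors covering `nodes`.
as_bn_data <- function(data, nodes = NULL) {
  data <- as.data.frame(data)
  if (!is.null(nodes)) {
    missing_cols <- setdiff(nodes, names(data))
    if (length(missing_cols) > 0) {
      abort(sprintf("data lacks node columns: %s",
                    paste(missing_cols, collapse = ", ")))
    }
    data <- data[nodes]
  }
  for (nm in names(data)) {
    if (!is.factor(data[[nm]])) data[[nm]] <- factor(data[[nm]])
  }
  data
}

# Per-family AIC contribution: multinomial log-likelihood at ML estimates
# minus (r - 1) * q free parameters, with q the full Cartesian parent
# configuration count over declared factor levels.
family_score <- function(node, parents, data) {
  r <- nlevels(data[[node]])
  q <- if (length(parents) == 0) 1 else prod(vapply(data[parents], nlevels, integer(1)))
  tab <- table(data[c(node, parents)])
  counts <- as.vector(tab)
  if (length(parents) == 0) {
    totals <- rep(sum(counts), length(counts))
  } else {
    cfg_tot <- colSums(matrix(counts, nrow = r))
    totals <- rep(cfg_tot, each = r)
  }
  pos <- counts > 0
  ll <- sum(counts[pos] * log(counts[pos] / totals[pos]))
  ll - (r - 1) * q
}

#' AIC network score of a DAG on discrete data
#'
#' Multinomial log-likelihood at maximum-likelihood parameters minus the
#' number of free parameters, summed over node families (so the score
#' decomposes and edge moves can be evaluated locally). Larger is better.
#'
#' @param dag A [bn_dag()].
#' @param data Data frame of discrete (factor) columns including every node.
#' @return A single number.
#' @examples
#' d <- data.frame(a = factor(rep(c("x", "y"), c(6, 4))))
#' aic_score(bn_dag("a"), d) # 6*log(.6) + 4*log(.4) - 1
#' @export
aic_score <- function(dag, data) {
  data <- as_bn_data(data, dag$nodes)
  if (nrow(data) == 0) abort("empty data.")
  sum(vapply(dag$nodes,
             function(v) family_score(v, dag$parents[[v]], data),
             numeric(1)))
}

# All legal single-edge moves from `dag`, in deterministic order.
enumerate_moves <- function(dag) {
  moves <- list()
  nodes <- sort(dag$nodes)
  for (from in nodes) for (to in nodes) {
    if (from == to) next
    if (dag_has_edge(dag, from, to)) {
      moves[[length(moves) + 1]] <- list(type = "delete", from = from, to = to)
      if (!creates_cycle(dag_drop_edge(dag, from, to), to, from)) {
        moves[[length(moves) + 1]] <- list(type = "reverse", from = from, to = to)
      }
    } else if (!dag_has_edge(dag, to, from) && !creates_cycle(dag, from, to)) {
      moves[[length(moves) + 1]] <- list(type = "add", from = from, to = to)
    }
  }
  moves
}

move_key <- function(m) paste(m$type, m$from, m$to)

# The move that undoes `m` (pushed onto the tabu list after applying `m`).
inverse_move <- function(m) {
  switch(m$type,
         add = list(type = "delete", from = m$from, to = m$to),
         delete = list(type = "add", from = m$from, to = m$to),
         reverse = list(type = "reverse", from = m$to, to = m$from))
}

apply_move <- function(dag, m) {
  switch(m$type,
         add = dag_add_edge(dag, m$from, m$to),
         delete = dag_drop_edge(dag, m$from, m$to),
         reverse = dag_add_edge(dag_drop_edge(dag, m$from, m$to), m$to, m$from))
}

#' Learn a Bayesian-network structure by Tabu search under AIC
#'
#' Greedy search over single-edge additions, deletions and reversals,
#' scored by [aic_score()], with a tabu list of recently undone moves to
#' escape local optima (list length 10, 200 iterations, deterministic
#' lexicographic tie-breaking). The best structure visited is polished by
#' hill climbing, so the result is locally maximal under single-edge moves.
#'
#' @param data Data frame of discrete columns; every column becomes a node.
#' @param seed Integer, kept for interface stability; the search itself is
#'   deterministic.
#' @param max_iter Tabu iterations.
#' @param tabu_len Length of the tabu list.
#' @return A [bn_dag()] with attribute `"score"`.
#' @export
learn_structure <- function(data, seed = 1L, max_iter = 200L, tabu_len = 10L) {
  data <- as_bn_data(data)
  if (ncol(data) < 2) abort("need at least 2 columns to learn a structure.")
  if (nrow(data) == 0) abort("empty data.")
  nodes <- names(data)
  if (all(vapply(data, function(x) length(unique(x)) <= 1L, logical(1)))) {
    warn("constant dataset: returning an empty graph.")
    dag <- bn_dag(nodes)
    attr(dag, "score") <- aic_score(dag, data)
    return(dag)
  }

  cache <- new.env(parent = emptyenv())
  fam <- function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(cache[[key]])) cache[[key]] <- family_score(node, parents, data)
    cache[[key]]
  }
  dag_score <- function(dag) {
    sum(vapply(dag$nodes, function(v) fam(v, dag$parents[[v]]), numeric(1)))
  }
  move_delta <- function(dag, m) {
    if (m$type == "reverse") {
      new <- apply_move(dag, m)
      fam(m$from, new$parents[[m$from]]) + fam(m$to, new$parents[[m$to]]) -
        fam(m$from, dag$parents[[m$from]]) - fam(m$to, dag$parents[[m$to]])
    } else {
      new <- apply_move(dag, m)
      fam(m$to, new$parents[[m$to]]) - fam(m$to, dag$parents[[m$to]])
    }
  }

  dag <- bn_dag(nodes)
  score <- dag_score(dag)
  best_dag <- dag
  best_score <- score
  tabu <- character(0)

  for (iter in seq_len(max_iter)) {
    moves <- enumerate_moves(dag)
    if (length(moves) == 0) break
    deltas <- vapply(moves, function(m) move_delta(dag, m), numeric(1))
    keys <- vapply(moves, move_key, character(1))
    allowed <- !(keys %in% tabu) | (score + deltas > best_score + 1e-12)
    if (!any(allowed)) break
    idx <- which(allowed)
    pick <- idx[which.max(deltas[idx])]  # which.max: first max, lexicographic order
    m <- moves[[pick]]
    dag <- apply_move(dag, m)
    score <- score + deltas[pick]
    tabu <- c(move_key(inverse_move(m)), tabu)
    if (length(tabu) > tabu_len) tabu <- tabu[seq_len(tabu_len)]
    if (score > best_score + 1e-12) {
      best_score <- score
      best_dag <- dag
    }
  }

  # hill-climb polish: guarantees local maximality of the returned graph
  repeat {
    moves <- enumerate_moves(best_dag)
    if (length(moves) == 0) break
    deltas <- vapply(moves, function(m) move_delta(best_dag, m), numeric(1))
    if (max(deltas) <= 1e-12) break
    best_dag <- apply_move(best_dag, moves[[which.max(deltas)]])
    best_score <- best_score + max(deltas)
  }

  attr(best_dag, "score") <- best_score
  best_dag
}

#' Estimate conditional probability tables by Bayesian smoothing
#'
#' Each CPT entry is the Dirichlet posterior mean
#' `(n_ijk + iss/(r*q)) / (n_ij + iss/q)` with `r` the node's domain size
#' and `q` its parent-configuration count, so every entry is strictly
#' positive (imaginary sample size `iss` spread uniformly over the joint
#' domain).
#'
#' @param dag A [bn_dag()].
#' @param data Data frame of discrete columns covering the nodes.
#' @param iss Imaginary sample size, > 0.
#' @return An object of class `bayes_net`: the DAG plus one CPT array per
#'   node (node dimension first, then parents in stored order).
#' @export
estimate_parameters <- function(dag, data, iss = 1) {
  assert_scalar_number(iss, "iss", lower = 0, strict_lower = TRUE)
  data <- as_bn_data(data, dag$nodes)
  if (is.null(topo_order(dag))) abort("dag must be acyclic.")
  cpts <- lapply(dag$nodes, function(v) {
    parents <- dag$parents[[v]]
    r <- nlevels(data[[v]])
    q <- if (length(parents) == 0) 1 else
      prod(vapply(data[parents], nlevels, integer(1)))
    tab <- table(data[c(v, parents)])
    counts <- array(as.vector(tab), dim = dim(tab), dimnames = dimnames(tab))
    prior <- iss / (r * q)
    num <- counts + prior
    if (length(parents) == 0) {
      cpt <- num / sum(num)
    } else {
      cfg_tot <- apply(num, seq_along(dim(num))[-1], sum)
      cpt <- sweep(num, seq_along(dim(num))[-1], cfg_tot, "/")
    }
    cpt
  })
  names(cpts) <- dag$nodes
  levels_list <- lapply(data, levels)
  structure(list(dag = dag, cpts = cpts, levels = levels_list),
            class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("<bayes_net> %d nodes, %d edges, %d parameters\n",
              length(x$dag$nodes), nrow(dag_edges(x$dag)),
              sum(vapply(x$cpts, length, integer(1)))))
  invisible(x)
}

#' @describeIn tidy_fusionlab Edge list of a fitted network.
#' @export
#' @exportS3Method generics::tidy
tidy.bayes_net <- function(x, ...) dag_edges(x$dag)

# cpt probabilities for each particle row given current assignments
# (integer level indices). Returns n x r matrix of P(node = k | parents).
cpt_prob_rows <- function(net, node, assign_idx) {
  cpt <- net$cpts[[node]]
  parents <- net$dag$parents[[node]]
  r <- length(net$levels[[node]])
  n <- nrow(assign_idx)
  if (length(parents) == 0) {
    matrix(as.vector(cpt), n, r, byrow = TRUE)
  } else {
    off <- rep(0L, n)
    stride <- r
    for (p in parents) {
      off <- off + (assign_idx[, p] - 1L) * stride
      stride <- stride * length(net$levels[[p]])
    }
    flat <- as.vector(cpt)
    m <- matrix(0, n, r)
    for (k in seq_len(r)) m[, k] <- flat[off + k]
    m
  }
}

# Likelihood-weighting estimate of P(node = value | evidence).
lw_query <- function(net, node, value, evidence, n_draws, seed) {
  order <- topo_order(net$dag)
  n <- n_draws
  with_rng(seed, {
    assign_idx <- matrix(0L, n, length(order),
                         dimnames = list(NULL, order))
    logw <- rep(0, n)
    for (v in order) {
      probs <- cpt_prob_rows(net, v, assign_idx)
      if (v %in% names(evidence)) {
        k <- match(evidence[[v]], net$levels[[v]])
        assign_idx[, v] <- k
        logw <- logw + log(probs[, k])
      } else {
        cum <- probs
        for (k in seq_len(ncol(probs))[-1]) {
          cum[, k] <- cum[, k - 1] + probs[, k]
        }
        u <- runif(n)
        assign_idx[, v] <- pmin(rowSums(u > cum) + 1L, ncol(probs))
      }
    }
    w <- exp(logw - max(logw))
    if (sum(w) == 0) abort("internal error: total likelihood weight is zero.")
    k_target <- match(value, net$levels[[node]])
    sum(w[assign_idx[, node] == k_target]) / sum(w)
  })
}

# Exact posterior P(node = value | evidence) by joint enumeration.
enumerate_query <- function(net, node, value, evidence) {
  order <- topo_order(net$dag)
  grid <- expand.grid(lapply(net$levels[order], seq_along),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- order
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) {
    keep <- keep & grid[[v]] == match(evidence[[v]], net$levels[[v]])
  }
  grid <- grid[keep, , drop = FALSE]
  logp <- rep(0, nrow(grid))
  gm <- as.matrix(grid)
  for (v in order) {
    probs <- cpt_prob_rows(net, v, gm)
    logp <- logp + log(probs[cbind(seq_len(nrow(gm)), gm[, v])])
  }
  p <- exp(logp - max(logp))
  k_target <- match(value, net$levels[[node]])
  sum(p[gm[, node] == k_target]) / sum(p)
}

#' Query the malignancy-risk posterior of a fitted network
#'
#' Estimates `P(risk = malignant | evidence)` by likelihood weighting:
#' non-evidence nodes are sampled in topological order and each particle is
#' weighted by the likelihood of the evidence it was forced to match.
#' Evidence is restricted to the Markov blanket of the risk node — values
#' for nodes outside the blanket carry no additional information and are
#' ignored with a warning. Exact enumeration over the joint domain is
#' available for small networks.
#'
#' @param net A [estimate_parameters()] fit whose DAG contains a node named
#'   `risk` with levels `benign`/`malignant`.
#' @param evidence Named list or character vector of observed node values.
#' @param n_draws Number of likelihood-weighting particles.
#' @param seed Integer seed for the particle draws.
#' @param method `"lw"` (default) or `"exact"` enumeration.
#' @return A single probability in `[0, 1]`.
#' @export
query_risk <- function(net, evidence, n_draws = 1e4, seed = 1L,
                       method = c("lw", "exact")) {
  method <- match.arg(method)
  if (!"risk" %in% net$dag$nodes) abort("network has no `risk` node.")
  assert_count(n_draws, "n_draws")
  evidence <- as.list(evidence)
  evidence <- evidence[!vapply(evidence, function(x) is.na(x), logical(1))]
  mb <- markov_blanket(net$dag, "risk")
  extra <- setdiff(names(evidence), mb)
  if (length(extra) > 0) {
    warn(sprintf("evidence outside the Markov blanket of risk ignored: %s",
                 paste(extra, collapse = ", ")))
    evidence <- evidence[names(evidence) %in% mb]
  }
  for (v in names(evidence)) {
    if (!evidence[[v]] %in% net$levels[[v]]) {
      abort(sprintf("evidence value '%s' not a level of node '%s'.",
                    evidence[[v]], v))
    }
  }
  if (method == "exact") {
    enumerate_query(net, "risk", "malignant", evidence)
  } else {
    lw_query(net, "risk", "malignant", evidence, n_draws, seed)
  }
}
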