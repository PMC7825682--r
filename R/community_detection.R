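# Modularity-based community detection on the compatibility network.
# Modularity of a partition {C_1..C_m}:
#   M = sum_C [ w_in(C) / W  -  (S_C / (2 W))^2 ]
# with W the total edge weight, w_in(C) the intra-community weight and S_C
# the accumulated node strength of C (degrees when unweighted). Maximized
# with a greedy local-move + aggregation (Louvain-style) scheme; an
# exhaustive set-partition oracle covers graphs of up to 10 nodes.

# Internal edge representation: integer endpoints, numeric weights, node
# strengths and total weight.
edge_index <- function(net, weighted = TRUE) {
  nodes <- net$nodes
  from <- match(net$edges$from, nodes)
  to <- match(net$edges$to, nodes)
  w <- if (weighted && nrow(net$edges) > 0) as.numeric(net$edges$weight)
       else rep(1, nrow(net$edges))
  strength <- numeric(length(nodes))
  if (length(from)) {
    for (k in seq_along(from)) {
      strength[from[k]] <- strength[from[k]] + w[k]
      strength[to[k]] <- strength[to[k]] + w[k]
    }
  }
  list(nodes = nodes, from = from, to = to, w = w,
       strength = strength, W = sum(w))
}

modularity_from_index <- function(ei, mem) {
  if (ei$W == 0) return(0)
  w_in <- sum(ei$w[mem[ei$from] == mem[ei$to]])
  s_c <- rowsum(ei$strength, mem)
  w_in / ei$W - sum((s_c / (2 * ei$W))^2)
}

#' Modularity of a partition
#'
#' Evaluates the modularity quality function of a node-to-community
#' assignment on a compatibility network, optionally using edge weights
#' (node strength replaces degree).
#'
#' @param net A `compat_network`.
#' @param membership Named vector (names = node ids) or vector in node order
#'   assigning each node a community id.
#' @param weighted Use edge weights (default TRUE).
#' @return Modularity value in \[-0.5, 1). An empty edge set yields 0 with a
#'   warning.
#' @examples
#' net <- network_from_triangles()
#' modularity_value(net, c(1, 1, 1, 2, 2, 2))
#' @export
modularity_value <- function(net, membership, weighted = TRUE) {
  stopifnot(inherits(net, "compat_network"))
  mem <- align_membership(membership, net$nodes)
  ei <- edge_index(net, weighted)
  if (ei$W == 0) {
    warning("network has no edges; modularity is 0 by convention")
    return(0)
  }
  modularity_from_index(ei, mem)
}

align_membership <- function(membership, nodes) {
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), nodes))
      stop("membership does not cover exactly the node set")
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    stop("membership length does not match node count")
  }
  as.integer(factor(membership))
}

# One Louvain level: greedy local moves on a graph given by edge lists with
# possible self-loops (self-loop weight counted once in W, twice in
# strength). Nodes are visited in the supplied order until a full pass makes
# no move. Ties in the modularity gain go to the smallest community id.
louvain_one_level <- function(n, from, to, w, self_w, order) {
  strength <- numeric(n)
  for (k in seq_along(from)) {
    strength[from[k]] <- strength[from[k]] + w[k]
    strength[to[k]] <- strength[to[k]] + w[k]
  }
  strength <- strength + 2 * self_w
  W <- sum(w) + sum(self_w)
  if (W == 0) {
    out <- seq_len(n)
    attr(out, "improved") <- FALSE
    return(out)
  }
  # adjacency list
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- matrix(0, 0, 2)
  if (length(from)) {
    idx <- c(from, to); nbr <- c(to, from); ww <- c(w, w)
    o <- order(idx)
    idx <- idx[o]; nbr <- nbr[o]; ww <- ww[o]
    starts <- c(1L, which(diff(idx) > 0) + 1L, length(idx) + 1L)
    present <- unique(idx)
    for (k in seq_along(present))
      adj[[present[k]]] <- cbind(nbr[starts[k]:(starts[k + 1L] - 1L)],
                                 ww[starts[k]:(starts[k + 1L] - 1L)])
  }
  comm <- seq_len(n)
  s_tot <- strength # per community
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order) {
      a <- comm[i]
      nb <- adj[[i]]
      if (nrow(nb) == 0) next
      # weight from i to each neighboring community
      k_ic <- rowsum(nb[, 2], comm[nb[, 1]])
      cand <- as.integer(rownames(k_ic))
      k_ia <- if (a %in% cand) k_ic[match(a, cand)] else 0
      s_tot[a] <- s_tot[a] - strength[i]
      gain <- (k_ic - k_ia) / W -
        strength[i] * (s_tot[cand] - s_tot[a]) / (2 * W^2)
      best <- which(gain > 1e-12) # staying put has gain exactly 0
      if (length(best)) {
        gmax <- max(gain[best])
        pick <- cand[best][gain[best] >= gmax - 1e-12]
        b <- min(pick)
        comm[i] <- b
        s_tot[b] <- s_tot[b] + strength[i]
        moved <- TRUE; improved_any <- TRUE
      } else {
        s_tot[a] <- s_tot[a] + strength[i]
      }
    }
    if (!moved) break
  }
  attr(comm, "improved") <- improved_any
  comm
}

louvain <- function(n, from, to, w, order) {
  mem <- seq_len(n) # membership of original nodes
  cur_n <- n; cur_from <- from; cur_to <- to; cur_w <- w
  cur_self <- numeric(n); cur_order <- order
  repeat {
    comm <- louvain_one_level(cur_n, cur_from, cur_to, cur_w, cur_self,
                              cur_order)
    if (!attr(comm, "improved")) break
    comm <- as.integer(factor(comm))
    mem <- comm[mem]
    # aggregate
    new_n <- max(comm)
    if (new_n == cur_n) break
    ends <- cbind(pmin(comm[cur_from], comm[cur_to]),
                  pmax(comm[cur_from], comm[cur_to]))
    new_self <- numeric(new_n)
    agg_self <- rowsum(cur_self, comm)
    new_self[as.integer(rownames(agg_self))] <- agg_self
    loop <- ends[, 1] == ends[, 2]
    if (any(loop)) {
      agg_loop <- rowsum(cur_w[loop], ends[loop, 1])
      new_self[as.integer(rownames(agg_loop))] <-
        new_self[as.integer(rownames(agg_loop))] + agg_loop
    }
    if (any(!loop)) {
      key <- paste(ends[!loop, 1], ends[!loop, 2])
      agg <- rowsum(cur_w[!loop], key)
      parts <- do.call(rbind, strsplit(rownames(agg), " "))
      cur_from <- as.integer(parts[, 1]); cur_to <- as.integer(parts[, 2])
      cur_w <- as.numeric(agg)
    } else {
      cur_from <- integer(0); cur_to <- integer(0); cur_w <- numeric(0)
    }
    cur_self <- new_self
    cur_n <- new_n
    cur_order <- seq_len(cur_n)
  }
  as.integer(factor(mem))
}

#' Detect communities by greedy modularity maximization
#'
#' Louvain-style maximization: repeated greedy local moves followed by
#' community aggregation until modularity stops improving. The seed fixes
#' the node visiting orders of a small set of restarts (the best-modularity
#' result is kept), so results are deterministic given the seed; node
#' relabeling does not change the partition. Isolated nodes become
#' singleton communities.
#'
#' @param net A non-empty `compat_network`.
#' @param seed Integer seed controlling restart visit orders.
#' @param weighted Use edge weights in the objective (default TRUE).
#' @param n_restarts Number of seeded restarts (default 5).
#' @return Object of class `community_partition`: `membership` (named
#'   integer vector, community ids 1..m numbered by first appearance over
#'   sorted node ids), `modularity` and `m`.
#' @examples
#' net <- network_from_triangles()
#' detect_communities(net)$modularity
#' @export
detect_communities <- function(net, seed = 1L, weighted = TRUE,
                               n_restarts = 5L) {
  stopifnot(inherits(net, "compat_network"), length(net$nodes) > 0)
  ord_nodes <- order(net$nodes) # canonical order: sorted ids
  n <- length(net$nodes)
  ei <- edge_index(net, weighted)
  best_mem <- NULL; best_q <- -Inf
  set.seed(seed)
  orders <- c(list(ord_nodes),
              lapply(seq_len(max(0L, n_restarts - 1L)),
                     function(i) sample(n)))
  for (ord in orders) {
    mem <- louvain(n, ei$from, ei$to, ei$w, ord)
    q <- modularity_from_index(ei, mem)
    if (q > best_q + 1e-12) { best_q <- q; best_mem <- mem }
  }
  # renumber communities by first appearance over sorted node ids
  relabel <- match(best_mem, unique(best_mem[ord_nodes]))
  membership <- stats::setNames(as.integer(relabel), net$nodes)
  structure(list(membership = membership,
                 modularity = if (ei$W == 0) 0 else best_q,
                 m = length(unique(relabel))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$m, "communities, modularity",
      round(x$modularity, 4), "\n")
  invisible(x)
}

#' Exhaustive modularity oracle for small graphs
#'
#' Enumerates every set partition of the node set (Bell-number many) and
#' returns the global modularity optimum. Refuses graphs with more than 10
#' nodes.
#'
#' @param net A `compat_network` with at most 10 nodes.
#' @param weighted Use edge weights (default TRUE).
#' @return List with `membership` (named), `modularity` and `m`.
#' @export
exhaustive_modularity_oracle <- function(net, weighted = TRUE) {
  n <- length(net$nodes)
  if (n > 10) stop("oracle refuses graphs with more than 10 nodes")
  ei <- edge_index(net, weighted)
  best_q <- -Inf; best <- integer(n)
  mem <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      q <- modularity_from_index(ei, mem)
      if (q > best_q) { best_q <<- q; best <<- mem }
      return(invisible())
    }
    for (c in seq_len(k + 1L)) {
      mem[i] <<- c
      recurse(i + 1L, max(k, c))
    }
  }
  recurse(1L, 0L)
  structure(list(membership = stats::setNames(best, net$nodes),
                 modularity = if (ei$W == 0) 0 else best_q,
                 m = length(unique(best))),
            class = "community_partition")
}

#' Force-directed network layout
#'
#' Energy-based 2D layout with attraction exponent `a` (adjacent nodes,
#' force magnitude d^a) and repulsion exponent `r` (all node pairs,
#' magnitude d^r). The energy
#' `sum_edges d^(a+1)/(a+1) - sum_pairs d^(r+1)/(r+1)` (log replacing the
#' second term at r = -1) is minimized by damped force integration with
#' backtracking, so the reported energy never increases across iterations.
#' The defaults a = 1, r = -1 place the layout in the regime where layout
#' clusters coincide with modularity communities.
#'
#' @param net A `compat_network`.
#' @param a Attraction exponent, >= 0.
#' @param r Repulsion exponent, in \[-1, 0\].
#' @param iterations Number of accepted integration steps.
#' @param seed Seed for the initial random positions.
#' @return Object of class `force_layout`: `coordinates` (data frame `id`,
#'   `x`, `y`), `params`, and the `energy` trace.
#' @export
force_layout <- function(net, a = 1, r = -1, iterations = 200L, seed = 1L) {
  stopifnot(inherits(net, "compat_network"), a >= 0, r <= 0, r >= -1)
  n <- length(net$nodes)
  set.seed(seed)
  pos <- matrix(stats::runif(2 * n, -1, 1), ncol = 2)
  ei <- edge_index(net, weighted = FALSE)
  if (n == 1) {
    return(structure(list(
      coordinates = data.frame(id = net$nodes, x = pos[, 1], y = pos[, 2]),
      params = list(a = a, r = r, iterations = 0L, seed = seed),
      energy = numeric(0)), class = "force_layout"))
  }
  eps <- 1e-9
  energy <- function(p) {
    d <- as.matrix(stats::dist(p)) + eps
    rep_term <- if (r == -1) log(d) else d^(r + 1) / (r + 1)
    att <- if (length(ei$from))
      sum(d[cbind(ei$from, ei$to)]^(a + 1)) / (a + 1) else 0
    att - sum(rep_term[upper.tri(rep_term)])
  }
  forces <- function(p) {
    dx <- outer(p[, 1], p[, 1], "-"); dy <- outer(p[, 2], p[, 2], "-")
    d <- sqrt(dx^2 + dy^2) + eps
    # repulsion pushes i away from j: magnitude d^r, direction (p_i - p_j)/d
    coef <- d^(r - 1); diag(coef) <- 0
    fx <- rowSums(coef * dx); fy <- rowSums(coef * dy)
    if (length(ei$from)) {
      ddx <- p[ei$to, 1] - p[ei$from, 1]
      ddy <- p[ei$to, 2] - p[ei$from, 2]
      dd <- sqrt(ddx^2 + ddy^2) + eps
      m <- dd^(a - 1)
      fx_e <- m * ddx; fy_e <- m * ddy
      for (k in seq_along(ei$from)) {
        i <- ei$from[k]; j <- ei$to[k]
        fx[i] <- fx[i] + fx_e[k]; fy[i] <- fy[i] + fy_e[k]
        fx[j] <- fx[j] - fx_e[k]; fy[j] <- fy[j] - fy_e[k]
      }
    }
    cbind(fx, fy)
  }
  e <- energy(pos)
  trace <- numeric(iterations)
  step <- 0.05
  for (it in seq_len(iterations)) {
    f <- forces(pos)
    # cap displacement to keep the integration stable
    norms <- sqrt(rowSums(f^2))
    cap <- stats::quantile(norms, 0.9) + eps
    f <- f * pmin(1, cap / (norms + eps))
    accepted <- FALSE
    for (try in 1:25) {
      cand <- pos + step * f
      if (!all(is.finite(cand))) { step <- step / 2; next }
      e_cand <- energy(cand)
      if (is.finite(e_cand) && e_cand <= e) {
        pos <- cand; e <- e_cand; step <- step * 1.1
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted && step < 1e-12)
      stop("force layout failed to find a descending step")
    trace[it] <- e
  }
  structure(list(coordinates = data.frame(id = net$nodes, x = pos[, 1],
                                          y = pos[, 2],
                                          stringsAsFactors = FALSE),
                 params = list(a = a, r = r, iterations = iterations,
                               seed = seed),
                 energy = trace),
            class = "force_layout")
}

#' Agreement between a layout and a community partition
#'
#' Ratio of the mean intra-community to the mean inter-community Euclidean
#' distance in the layout. Values below 1 indicate that the geometric
#' clusters of the layout line up with the modularity communities.
#'
#' @param layout A `force_layout` result.
#' @param partition A `community_partition` on the same node set.
#' @return The distance ratio (single number).
#' @export
layout_community_agreement <- function(layout, partition) {
  co <- layout$coordinates
  mem <- partition$membership[co$id]
  if (anyNA(mem)) stop("layout and partition node sets differ")
  if (length(unique(mem)) < 2)
    stop("agreement ratio undefined for a single community")
  d <- as.matrix(stats::dist(cbind(co$x, co$y)))
  same <- outer(mem, mem, "==")
  ut <- upper.tri(d)
  intra <- d[ut & same]
  inter <- d[ut & !same]
  if (length(intra) == 0) stop("no intra-community pairs")
  mean(intra) / mean(inter)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Two disjoint triangles, a canonical test network
#'
#' @param weight Edge weight for all six edges.
#' @return A `compat_network` with nodes a..f and two 3-cliques.
#' @export
network_from_triangles <- function(weight = 1) {
  nodes <- letters[1:6]
  edges <- data.frame(from = c("a", "a", "b", "d", "d", "e"),
                      to = c("b", "c", "c", "e", "f", "f"),
                      weight = weight, stringsAsFactors = FALSE)
  network_from_edges(nodes, edges)
}
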