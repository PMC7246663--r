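# Weighted modularity, Louvain (Blondel two-phase) community detection and
# an exhaustive optimal-partition oracle for small graphs.
#
# Internal graph representation: integer node ids 1..n, undirected edge
# arrays (a, b, w) with a != b, and a per-node self-loop weight sl (only
# non-zero on aggregated levels). Conventions: m = sum(w) + sum(sl); a
# self-loop of weight s contributes s to its community's internal weight
# and 2s to its node's degree — the convention under which modularity is
# preserved exactly across aggregation levels.

.intGraph <- function(network) {
  codes <- network@nodes$code
  list(n = length(codes),
       a = match(network@edges$from, codes),
       b = match(network@edges$to, codes),
       w = as.numeric(network@edges$weight),
       sl = numeric(length(codes)),
       codes = codes)
}

.nodeDegrees <- function(g) {
  d <- numeric(g$n)
  if (length(g$a)) {
    ta <- rowsum(g$w, g$a)
    tb <- rowsum(g$w, g$b)
    d[as.integer(rownames(ta))] <- d[as.integer(rownames(ta))] + ta[, 1]
    d[as.integer(rownames(tb))] <- d[as.integer(rownames(tb))] + tb[, 1]
  }
  d + 2 * g$sl
}

.modQint <- function(g, comm, gamma = 1) {
  m <- sum(g$w) + sum(g$sl)
  if (m <= 0) stop("modularity is undefined on an edgeless network",
                   call. = FALSE)
  intra <- if (length(g$a)) sum(g$w[comm[g$a] == comm[g$b]]) else 0
  Wc <- intra + sum(g$sl)                       # total, then split by comm
  # per-community internal weight
  WcByC <- numeric(max(comm))
  if (length(g$a)) {
    same <- comm[g$a] == comm[g$b]
    if (any(same)) {
      t1 <- rowsum(g$w[same], comm[g$a][same])
      WcByC[as.integer(rownames(t1))] <- WcByC[as.integer(rownames(t1))] + t1[, 1]
    }
  }
  if (any(g$sl > 0)) {
    t2 <- rowsum(g$sl, comm)
    WcByC[as.integer(rownames(t2))] <- WcByC[as.integer(rownames(t2))] + t2[, 1]
  }
  d <- .nodeDegrees(g)
  dByC <- numeric(max(comm))
  t3 <- rowsum(d, comm)
  dByC[as.integer(rownames(t3))] <- t3[, 1]
  sum(WcByC / m - gamma * (dByC / (2 * m))^2)
}

.alignMembership <- function(network, membership) {
  if (is(membership, "CommunityPartition"))
    membership <- membership@membership
  codes <- network@nodes$code
  if (!is.null(names(membership))) {
    if (!all(codes %in% names(membership)))
      stop("membership does not cover all network nodes", call. = FALSE)
    membership <- membership[codes]
  } else if (length(membership) != length(codes)) {
    stop("membership must cover all network nodes", call. = FALSE)
  }
  as.integer(factor(membership))   # 1..K for internal use
}

# Relabel community ids to 0-based contiguous integers in order of first
# appearance over the node order.
.canonicalRelabel <- function(comm) {
  match(comm, unique(comm)) - 1L
}

#' Weighted modularity of a node partition
#'
#' Computes `Q = sum_c ( W_c / m - gamma * (d_c / (2 m))^2 )`, where `W_c`
#' is the total intra-community edge weight, `d_c` the total weighted
#' degree of community c, and `m` the total edge weight: the fraction of
#' edge weight falling within communities minus the expectation under the
#' configuration null model. `Q` lies in \[-1, 1\]. Isolated nodes
#' contribute nothing (their degree is zero).
#'
#' @param network a [ComorbidityNetwork-class] with at least one edge.
#' @param membership a [CommunityPartition-class], a named vector
#'   (code -> community), or an unnamed vector parallel to the node table.
#' @param gamma resolution parameter (default 1 = plain modularity).
#' @return Modularity Q as a single number.
#' @examples
#' # any partition putting all nodes in one community has Q = 0
#' @export
modularityScore <- function(network, membership, gamma = 1) {
  stopifnot(is(network, "ComorbidityNetwork"), gamma > 0)
  g <- .intGraph(network)
  comm <- .alignMembership(network, membership)
  .modQint(g, comm, gamma)
}

# --- Louvain ---------------------------------------------------------------

# One local-moving phase on the internal graph. Returns list(comm, moved).
.louvainPhase <- function(g, gamma, m) {
  n <- g$n
  adjn <- vector("list", n)
  adjw <- vector("list", n)
  if (length(g$a)) {
    ord <- order(c(g$a, g$b))
    nb <- c(g$b, g$a)[ord]
    wb <- c(g$w, g$w)[ord]
    src <- c(g$a, g$b)[ord]
    splitIdx <- split(seq_along(src), src)
    for (k in names(splitIdx)) {
      i <- as.integer(k)
      adjn[[i]] <- nb[splitIdx[[k]]]
      adjw[[i]] <- wb[splitIdx[[k]]]
    }
  }
  deg <- .nodeDegrees(g)
  comm <- seq_len(n)
  commDeg <- deg
  movedAny <- FALSE
  repeat {
    nmoves <- 0L
    for (i in sample.int(n)) {
      nbrs <- adjn[[i]]
      if (is.null(nbrs) || !length(nbrs)) next
      ci <- comm[i]
      kin <- rowsum(adjw[[i]], comm[nbrs])
      cand <- as.integer(rownames(kin))
      kinv <- kin[, 1]
      if (!ci %in% cand) {
        cand <- c(cand, ci)
        kinv <- c(kinv, 0)
      }
      commDeg[ci] <- commDeg[ci] - deg[i]
      gain <- kinv / m - gamma * deg[i] * commDeg[cand] / (2 * m^2)
      base <- gain[match(ci, cand)]
      imp <- gain - base
      best <- max(imp)
      tgt <- min(cand[imp >= best - 1e-12])   # tie-break: lowest community id
      if (best > 1e-12 && tgt != ci) {
        comm[i] <- tgt
        nmoves <- nmoves + 1L
      }
      commDeg[comm[i]] <- commDeg[comm[i]] + deg[i]
    }
    if (nmoves == 0L) break
    movedAny <- TRUE
  }
  list(comm = comm, moved = movedAny)
}

# Aggregate communities into super-nodes; intra-community weight (plus old
# self-loops) becomes the new self-loop weight.
.aggregate <- function(g, comm) {
  labs <- match(comm, unique(comm))
  K <- max(labs)
  sl <- numeric(K)
  t0 <- rowsum(g$sl, labs)
  sl[as.integer(rownames(t0))] <- t0[, 1]
  a <- b <- integer(0); w <- numeric(0)
  if (length(g$a)) {
    ca <- labs[g$a]; cb <- labs[g$b]
    same <- ca == cb
    if (any(same)) {
      t1 <- rowsum(g$w[same], ca[same])
      sl[as.integer(rownames(t1))] <- sl[as.integer(rownames(t1))] + t1[, 1]
    }
    if (any(!same)) {
      lo <- pmin(ca[!same], cb[!same])
      hi <- pmax(ca[!same], cb[!same])
      key <- (lo - 1) * K + hi
      t2 <- rowsum(g$w[!same], key)
      key2 <- as.numeric(rownames(t2))
      a <- as.integer((key2 - 1) %/% K + 1)
      b <- as.integer((key2 - 1) %% K + 1)
      w <- t2[, 1]
    }
  }
  list(g = list(n = K, a = a, b = b, w = w, sl = sl, codes = NULL),
       labs = labs)
}

#' Louvain community detection by modularity optimization
#'
#' The two-phase greedy optimizer of Blondel et al.: phase 1 sweeps nodes
#' in seeded-random order (re-drawn each sweep), moving each node to the
#' neighboring community with the largest positive modularity gain, ties
#' broken by lowest community id, until a sweep makes no move; phase 2
#' aggregates communities into super-nodes (intra-community weight becomes
#' a self-loop) and repeats. Stops when a pass yields no move or
#' `maxPasses` is reached. Modularity is non-decreasing across passes
#' (asserted internally). Identical network, seed and gamma give an
#' identical partition.
#'
#' @param network a [ComorbidityNetwork-class] with at least one edge.
#' @param seed integer RNG seed for the sweep order.
#' @param gamma resolution parameter (default 1).
#' @param maxPasses maximum number of aggregation passes.
#' @return A [CommunityPartition-class]; its `modularity` slot equals
#'   [modularityScore()] of its membership. If `maxPasses` is exhausted
#'   the partition is returned with `converged = FALSE` and a warning.
#' @references Blondel, Guillaume, Lambiotte, Lefebvre (2008). Fast
#'   unfolding of communities in large networks. J. Stat. Mech. P10008.
#' @export
louvain <- function(network, seed = 1L, gamma = 1, maxPasses = 100L) {
  stopifnot(is(network, "ComorbidityNetwork"), gamma > 0)
  if (nrow(network@edges) == 0)
    stop("louvain requires a network with at least one edge", call. = FALSE)
  g0 <- .intGraph(network)
  m <- sum(g0$w)
  mapping <- seq_len(g0$n)   # original node -> current super-node
  g <- g0
  converged <- FALSE
  withSeed(seed, {
    Qprev <- .modQint(g0, mapping, gamma)
    for (pass in seq_len(maxPasses)) {
      res <- .louvainPhase(g, gamma, m)
      if (!res$moved) { converged <- TRUE; break }
      agg <- .aggregate(g, res$comm)
      mapping <- agg$labs[mapping]
      Qnow <- .modQint(g0, mapping, gamma)
      stopifnot(Qnow >= Qprev - 1e-9)   # Q non-decreasing across passes
      Qprev <- Qnow
      g <- agg$g
    }
  })
  if (!converged)
    warning("louvain: pass limit reached before convergence", call. = FALSE)
  comm <- .canonicalRelabel(mapping)
  names(comm) <- g0$codes
  new("CommunityPartition", membership = comm,
      modularity = .modQint(g0, mapping, gamma), gamma = gamma,
      seed = as.integer(seed), converged = converged)
}

# --- exhaustive oracle -----------------------------------------------------

#' Exact maximum-modularity partition by exhaustive enumeration
#'
#' Enumerates every set partition of the nodes (restricted-growth-string
#' order) and returns the partition with maximal modularity. Ties are
#' broken by fewest communities, then by enumeration (canonical label)
#' order. Intended as an oracle for validating heuristic optimizers on
#' small graphs; refuses more than 12 nodes (Bell-number bound).
#'
#' @inheritParams louvain
#' @return A [CommunityPartition-class] with `seed = NA`.
#' @export
bruteForceBestPartition <- function(network, gamma = 1) {
  stopifnot(is(network, "ComorbidityNetwork"), gamma > 0)
  n <- nrow(network@nodes)
  if (n > 12L)
    stop("exhaustive enumeration refused for more than 12 nodes",
         call. = FALSE)
  if (nrow(network@edges) == 0)
    stop("modularity is undefined on an edgeless network", call. = FALSE)
  g <- .intGraph(network)
  m <- sum(g$w)
  A <- matrix(0, n, n)
  for (k in seq_along(g$a)) {
    A[g$a[k], g$b[k]] <- A[g$a[k], g$b[k]] + g$w[k]
    A[g$b[k], g$a[k]] <- A[g$b[k], g$a[k]] + g$w[k]
  }
  d <- .nodeDegrees(g)
  K <- A - gamma * outer(d, d) / (2 * m)
  # Q(partition) = sum of K over same-community (ordered) pairs / (2m)
  a <- integer(n)                       # RGS, 0-based labels
  best <- NULL; bestQ <- -Inf; bestK <- n + 1L
  repeat {
    s <- 0
    for (cid in unique(a)) {
      idx <- which(a == cid)
      s <- s + sum(K[idx, idx])
    }
    Q <- s / (2 * m)
    ncomm <- length(unique(a))
    if (Q > bestQ + 1e-12 ||
        (Q > bestQ - 1e-12 && ncomm < bestK)) {
      best <- a; bestQ <- Q; bestK <- ncomm
    }
    # next restricted growth string: increment the rightmost position j
    # with a[j] <= max(a[1..j-1]), zeroing the tail
    if (n == 1L) break
    pmax_ <- integer(n)                 # max of a[1..j-1]
    for (j in 2:n) pmax_[j] <- max(pmax_[j - 1], a[j - 1])
    j <- n
    while (j >= 2L && a[j] > pmax_[j]) j <- j - 1L
    if (j < 2L) break
    a[j] <- a[j] + 1L
    if (j < n) a[(j + 1L):n] <- 0L
  }
  comm <- .canonicalRelabel(best + 1L)
  names(comm) <- g$codes
  new("CommunityPartition", membership = comm,
      modularity = .modQint(g, best + 1L, gamma), gamma = gamma,
      seed = NA_integer_, converged = TRUE)
}

# --- partition accessors / report ------------------------------------------

#' Accessors for CommunityPartition objects
#'
#' @param x a [CommunityPartition-class].
#' @return `membershipVector()` the named integer assignment;
#'   `modularityValue()` the modularity Q; `nCommunities()` the number of
#'   communities.
#' @name CommunityPartition-accessors
#' @aliases membershipVector modularityValue nCommunities
NULL

#' @rdname CommunityPartition-accessors
#' @export
setMethod("membershipVector", "CommunityPartition", function(x) x@membership)

#' @rdname CommunityPartition-accessors
#' @export
setMethod("modularityValue", "CommunityPartition", function(x) x@modularity)

#' @rdname CommunityPartition-accessors
#' @export
setMethod("nCommunities", "CommunityPartition",
          function(x) length(unique(x@membership)))

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition: %d nodes in %d communities, Q = %.4f%s\n",
              length(object@membership),
              length(unique(object@membership)), object@modularity,
              if (isTRUE(object@converged)) "" else " (NOT converged)"))
  sz <- sort(table(object@membership), decreasing = TRUE)
  cat("  sizes:", paste(as.integer(sz), collapse = ", "), "\n")
  invisible(NULL)
})

#' Per-module membership report
#'
#' Enumerates the communities of a partition (modules are numbered, not
#' named), sorted by size descending; members within a module are sorted by
#' prevalence descending, ties by code.
#'
#' @param network the [ComorbidityNetwork-class] that was partitioned.
#' @param partition a [CommunityPartition-class] over its nodes.
#' @return data.frame with columns `module` (1-based rank by size), `size`,
#'   and `members` (list column of code vectors in prevalence order).
#' @export
moduleReport <- function(network, partition) {
  stopifnot(is(network, "ComorbidityNetwork"),
            is(partition, "CommunityPartition"))
  memb <- partition@membership
  if (!all(network@nodes$code %in% names(memb)))
    stop("partition does not cover the network nodes", call. = FALSE)
  nd <- network@nodes
  prev <- setNames(nd$prevalence, nd$code)
  byComm <- split(names(memb), memb)
  members <- lapply(byComm, function(cs) cs[order(-prev[cs], cs)])
  sizes <- vapply(members, length, 1L)
  ord <- order(-sizes, as.integer(names(byComm)))
  out <- data.frame(module = seq_along(ord), size = sizes[ord])
  out$members <- unname(members[ord])
  rownames(out) <- NULL
  out
}
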