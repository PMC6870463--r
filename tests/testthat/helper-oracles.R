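# Independent reference implementations used as oracles. Deliberately
# plain and self-contained: no code shared with the package internals.

# Reference MCL: dense, textbook loop (add self-loops, column-normalize,
# square, inflate, renormalize, prune) with base-R component extraction.
reference_mcl <- function(edges, nodes, inflation, prune = 1e-5,
                          tol = 1e-6, max_iter = 200) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$node1[k], nodes)
    j <- match(edges$node2[k], nodes)
    A[i, j] <- edges$r[k]
    A[j, i] <- edges$r[k]
  }
  for (i in seq_len(n)) A[i, i] <- max(A[i, ])
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    M_old <- M
    M <- M %*% M
    M <- M ^ inflation
    M[M < prune] <- 0
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s == 0) { M[j, j] <- 1; s <- 1 }
      M[, j] <- M[, j] / s
    }
    if (max(abs(M - M_old)) < tol) break
  }
  # components of the symmetrized support graph, by flood fill
  B <- (M > prune) | (t(M) > prune)
  diag(B) <- TRUE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(B[v, ] & is.na(comp)))
    }
  }
  split(nodes, comp)
}

# canonical partition representation for comparing clusterings
partition_signature <- function(groups) {
  sig <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1)))
  paste(sig, collapse = ";")
}

mcl_partition_signature <- function(fit, include_unclustered = TRUE) {
  mem <- fit$membership
  groups <- split(mem$node[!is.na(mem$cluster)],
                  mem$cluster[!is.na(mem$cluster)])
  if (include_unclustered) {
    for (nd in mem$node[is.na(mem$cluster)]) {
      groups[[paste0("u_", nd)]] <- nd
    }
  }
  partition_signature(groups)
}

# fixture graph builders -----------------------------------------------

# union of disjoint cliques with weight w
clique_graph <- function(sizes, w = 1) {
  nodes <- character(0)
  edges <- list()
  for (ci in seq_along(sizes)) {
    members <- sprintf("c%d_n%02d", ci, seq_len(sizes[ci]))
    nodes <- c(nodes, members)
    if (sizes[ci] >= 2) {
      pr <- t(utils::combn(members, 2))
      edges[[ci]] <- tibble::tibble(node1 = pr[, 1], node2 = pr[, 2],
                                    r = w)
    }
  }
  list(edges = dplyr::bind_rows(edges), nodes = nodes)
}

# two dense modules joined by a configurable number of weak bridges
planted_partition_graph <- function(n_per = 6, in_w = 0.95,
                                    bridge_w = 0.3, n_bridges = 1,
                                    seed = 1) {
  set.seed(seed)
  a <- sprintf("a%02d", seq_len(n_per))
  b <- sprintf("b%02d", seq_len(n_per))
  edge <- function(members, w) {
    pr <- t(utils::combn(members, 2))
    tibble::tibble(node1 = pr[, 1], node2 = pr[, 2],
                   r = w * stats::runif(nrow(pr), 0.95, 1))
  }
  bridges <- tibble::tibble(node1 = sample(a, n_bridges, replace = TRUE),
                            node2 = sample(b, n_bridges, replace = TRUE),
                            r = bridge_w)
  list(edges = dplyr::bind_rows(edge(a, in_w), edge(b, in_w), bridges),
       nodes = c(a, b),
       modules = list(a = a, b = b))
}

# Exhaustive contiguous-partition optimum for dosage grouping: enumerate
# every split of the sorted log2(x + 0.5) values into 1..3 groups.
brute_force_dosage_partition <- function(values, penalty = 0.5) {
  x <- sort(log2(values + 0.5))
  n <- length(x)
  ss <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  best <- list(score = Inf, k = NA, cuts = NULL)
  # k = 1
  cand <- list(list(k = 1, cuts = integer()))
  for (c1 in 1:(n - 1)) cand[[length(cand) + 1]] <-
    list(k = 2, cuts = c1)
  for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1)) {
    cand[[length(cand) + 1]] <- list(k = 3, cuts = c(c1, c2))
  }
  for (cc in cand) {
    b <- c(0, cc$cuts, n)
    sc <- sum(sapply(seq_len(cc$k), function(i) ss(x[(b[i] + 1):b[i + 1]]))) +
      penalty * (cc$k - 1)
    if (sc < best$score - 1e-12) best <- list(score = sc, k = cc$k,
                                              cuts = cc$cuts)
  }
  best
}

# two-pass textbook Pearson correlation
pearson_two_pass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# hypergeometric upper tail by explicit pmf summation
hyper_tail_by_enumeration <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
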