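#' Pearson correlation matrix of an expression table
#'
#' Builds the full symmetric correlation matrix either between genes
#' (rows) or between samples (columns). Zero-variance vectors are excluded
#' with a warning since their correlation is undefined.
#'
#' @param expr Wide expression tibble (`gene` + sample columns).
#' @param mode `"gene_to_gene"` (default) or `"sample_to_sample"`.
#' @param transform `"none"` (correlate raw TPM, default) or `"log2"`
#'   (correlate `log2(TPM + 1)`).
#' @return A symmetric numeric matrix with unit diagonal, dimnames = gene
#'   or sample ids.
#' @export
correlation_matrix <- function(expr,
                               mode = c("gene_to_gene",
                                        "sample_to_sample"),
                               transform = c("none", "log2")) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  m <- expr_values(expr)
  if (transform == "log2") m <- log2(m + 1)
  x <- if (mode == "gene_to_gene") t(m) else m
  if (nrow(x) < 3L) {
    stop("need at least 3 observations per vector", call. = FALSE)
  }
  v <- apply(x, 2L, stats::var)
  if (any(v == 0 | is.na(v))) {
    warning("excluding ", sum(v == 0 | is.na(v)),
            " zero-variance vector(s)")
    x <- x[, v > 0 & !is.na(v), drop = FALSE]
  }
  r <- stats::cor(x)
  diag(r) <- 1
  r
}

#' Threshold a correlation matrix into an undirected graph
#'
#' Keeps every off-diagonal pair with correlation at or above `r_min` as a
#' weighted edge. Nodes without any surviving edge stay in the node list
#' but are marked unclustered downstream.
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @param r_min Minimum Pearson r for an edge (the thresholds in routine
#'   use are 0.97 for sample-to-sample and 0.8-0.85 for gene-to-gene
#'   graphs).
#' @return An object of class `correlation_graph`: `edges` tibble
#'   (`node1`, `node2`, `r`; node1 < node2), `nodes` (all ids),
#'   `r_min`.
#' @export
threshold_graph <- function(corr, r_min) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  nodes <- rownames(corr)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(corr)))
  idx <- which(upper.tri(corr) & corr >= r_min, arr.ind = TRUE)
  edges <- tibble::tibble(
    node1 = nodes[idx[, 1]],
    node2 = nodes[idx[, 2]],
    r = corr[idx]
  )
  structure(list(edges = edges, nodes = nodes, r_min = r_min),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("<correlation_graph> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges at r >= ", x$r_min, "\n", sep = "")
  invisible(x)
}

#' Markov clustering (MCL) of a correlation graph
#'
#' Canonical MCL on the weighted adjacency matrix: self-loops are added
#' (weight = the node's maximum incident edge weight), columns are
#' normalized to a stochastic matrix, and expansion (matrix squaring) and
#' inflation (elementwise power then column renormalization, with entries
#' below `prune_threshold` removed) alternate until successive matrices
#' differ by less than `tol` in max-norm or `max_iter` is reached.
#' Clusters are the connected components of the attractor structure of the
#' limit matrix; they are renumbered by decreasing size (ties broken by
#' smallest member id) starting at 1. Isolated nodes and clusters smaller
#' than `min_cluster_size` are reported as unclustered.
#'
#' @param graph A `correlation_graph` (or a tibble of edges `node1`,
#'   `node2`, `r`).
#' @param inflation Inflation exponent, > 1; 1.7 gives the coarse
#'   granularity appropriate for replicate samples of one cell type.
#' @param expansion Matrix-power of the expansion step (default 2).
#' @param prune_threshold Entries below this are zeroed after inflation
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance in max-norm (default 1e-6).
#' @param min_cluster_size Clusters below this size are left unclustered
#'   (default 3).
#' @param binarize If `TRUE` edge weights are replaced by 1 before
#'   normalization (default `FALSE`: weighted by r).
#' @return An object of class `mcl_clusters`: `membership` tibble
#'   (`node`, `cluster`; `NA` cluster = unclustered), `sizes` tibble,
#'   `n_clusters`, `converged`, `iterations`, `inflation`.
#' @examples
#' corr <- diag(6); corr[1:3, 1:3] <- 0.9; corr[4:6, 4:6] <- 0.9
#' diag(corr) <- 1; dimnames(corr) <- list(letters[1:6], letters[1:6])
#' mcl(threshold_graph(corr, 0.8), inflation = 1.7)$n_clusters
#' @export
mcl <- function(graph, inflation = 1.7, expansion = 2L,
                prune_threshold = 1e-5, max_iter = 200L, tol = 1e-6,
                min_cluster_size = 3L, binarize = FALSE) {
  edges <- if (inherits(graph, "correlation_graph")) graph$edges else graph
  all_nodes <- if (inherits(graph, "correlation_graph")) graph$nodes else
    sort(unique(c(edges$node1, edges$node2)))
  if (length(all_nodes) == 0) stop("empty graph", call. = FALSE)
  if (inflation <= 1) stop("inflation must exceed 1", call. = FALSE)

  active <- sort(unique(c(edges$node1, edges$node2)))
  isolated <- setdiff(all_nodes, active)
  if (length(active) == 0) {
    membership <- tibble::tibble(node = all_nodes, cluster = NA_integer_)
    return(structure(list(membership = membership,
                          sizes = tibble::tibble(cluster = integer(),
                                                 size = integer()),
                          n_clusters = 0L, converged = TRUE,
                          iterations = 0L, inflation = inflation),
                     class = "mcl_clusters"))
  }
  n <- length(active)
  A <- matrix(0, n, n, dimnames = list(active, active))
  i <- match(edges$node1, active)
  j <- match(edges$node2, active)
  w <- if (binarize) rep(1, nrow(edges)) else edges$r
  if (any(w < 0)) {
    stop("MCL needs nonnegative edge weights; threshold at r >= 0",
         call. = FALSE)
  }
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  # self-loops at the node's maximum incident weight
  diag(A) <- apply(A, 1L, max)

  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M_prev <- M
    # expansion
    E <- M
    for (p in seq_len(expansion - 1L)) E <- E %*% M
    # inflation + pruning + renormalization
    E <- E ^ inflation
    E[E < prune_threshold] <- 0
    cs <- colSums(E)
    dead <- cs == 0
    if (any(dead)) {   # fully pruned column: restore self-loop
      E[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M <- sweep(E, 2L, cs, "/")
    if (max(abs(M - M_prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current clustering")
  }

  # clusters = connected components of the attractor structure
  B <- (M > prune_threshold) | (t(M) > prune_threshold)
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  membership <- tibble::tibble(node = active, raw = unname(comp))

  sizes <- membership |>
    dplyr::count(.data$raw, name = "size") |>
    dplyr::left_join(
      membership |>
        dplyr::group_by(.data$raw) |>
        dplyr::summarise(first_member = min(.data$node), .groups = "drop"),
      by = "raw"
    ) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first_member)
  sizes$cluster <- seq_len(nrow(sizes))
  sizes$cluster[sizes$size < min_cluster_size] <- NA_integer_
  kept <- sizes[!is.na(sizes$cluster), ]
  kept$cluster <- seq_len(nrow(kept))
  relabel <- stats::setNames(rep(NA_integer_, nrow(sizes)), sizes$raw)
  relabel[as.character(kept$raw)] <- kept$cluster

  membership$cluster <- unname(relabel[as.character(membership$raw)])
  membership$raw <- NULL
  membership <- dplyr::bind_rows(
    membership,
    tibble::tibble(node = isolated, cluster = NA_integer_)
  )
  membership <- membership[match(all_nodes, membership$node), ]

  structure(list(
    membership = membership,
    sizes = tibble::tibble(cluster = kept$cluster, size = kept$size),
    n_clusters = nrow(kept),
    converged = converged,
    iterations = iter,
    inflation = inflation
  ), class = "mcl_clusters")
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat("<mcl_clusters> ", x$n_clusters, " clusters (inflation ",
      x$inflation, ", ", x$iterations, " iterations",
      if (!x$converged) ", NOT converged" else "", "); sizes: ",
      paste(utils::head(x$sizes$size, 8), collapse = ", "),
      if (nrow(x$sizes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Mean expression profiles of clusters
#'
#' For each cluster, the arithmetic mean TPM across member genes in every
#' sample, plus an LPS trend label from the paired fold change of the
#' profile: `"up with LPS"` when the (pseudocounted) LPS/control fold of
#' the profile exceeds `fold`, `"down with LPS"` below `1/fold`, else
#' `"unchanged"`. Empty clusters are excluded.
#'
#' @param clusters An `mcl_clusters` object.
#' @param expr Wide expression tibble containing the clustered genes.
#' @param samples Optional sample sheet (`sample`, `treatment`) enabling
#'   the trend label.
#' @param fold Trend fold threshold (default 2).
#' @return Tibble: `cluster`, `size`, one column per sample with the mean
#'   profile, and `trend` when treatments are supplied.
#' @export
cluster_profiles <- function(clusters, expr, samples = NULL, fold = 2) {
  mem <- clusters$membership
  mem <- mem[!is.na(mem$cluster) & mem$node %in% expr$gene, ]
  if (nrow(mem) == 0) {
    return(tibble::tibble(cluster = integer(), size = integer()))
  }
  m <- expr_values(expr)
  prof <- purrr::map_dfr(sort(unique(mem$cluster)), function(cl) {
    members <- mem$node[mem$cluster == cl]
    p <- colMeans(m[members, , drop = FALSE])
    dplyr::bind_cols(tibble::tibble(cluster = cl,
                                    size = length(members)),
                     tibble::as_tibble(as.list(p)))
  })
  if (!is.null(samples)) {
    ids <- setdiff(names(prof), c("cluster", "size"))
    tr <- samples$treatment[match(ids, samples$sample)]
    pm <- as.matrix(prof[, ids, drop = FALSE])
    mean_c <- rowMeans(pm[, tr == "control", drop = FALSE])
    mean_l <- rowMeans(pm[, tr == "LPS", drop = FALSE])
    fc <- (mean_l + 0.5) / (mean_c + 0.5)
    prof$trend <- dplyr::case_when(fc > fold ~ "up with LPS",
                                   fc < 1 / fold ~ "down with LPS",
                                   TRUE ~ "unchanged")
  }
  prof
}

#' Hypergeometric gene-set enrichment of a cluster
#'
#' Local replacement for web-service annotation: for each annotation set,
#' the upper-tail hypergeometric probability of observing at least the
#' actual overlap between the cluster and the set, drawn from the given
#' universe, with Benjamini-Hochberg adjustment across sets.
#'
#' @param cluster_genes Character vector of cluster member genes.
#' @param gene_sets Named list of character vectors (annotation sets).
#' @param universe Character vector of all assayable genes (must contain
#'   the cluster genes; outsiders are dropped with a warning).
#' @return Tibble: `set`, `set_size` (within universe), `overlap`,
#'   `expected`, `p`, `q` (BH), sorted by `p`.
#' @examples
#' gene_set_enrichment(letters[1:5],
#'                     list(mySet = letters[1:5]),
#'                     letters[1:20])$p  # 1 / choose(20, 5)
#' @export
gene_set_enrichment <- function(cluster_genes, gene_sets, universe) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  outside <- setdiff(cluster_genes, universe)
  if (length(outside) > 0) {
    warning("dropping ", length(outside),
            " cluster gene(s) missing from the universe")
    cluster_genes <- intersect(cluster_genes, universe)
  }
  N <- length(universe)
  n <- length(cluster_genes)
  res <- purrr::imap_dfr(gene_sets, function(set, nm) {
    set <- intersect(set, universe)
    K <- length(set)
    k <- length(intersect(cluster_genes, set))
    p <- if (K == 0 || n == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = K, overlap = k,
                   expected = n * K / N, p = p)
  })
  res$q <- stats::p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p)
}
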