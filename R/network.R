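#' Binarize a connectivity matrix at a target sparsity
#'
#' Proportional ("global") thresholding: keep the
#' `round(s * n(n-1)/2)` strongest edges by weight, ties at the cutoff
#' broken by fixed lexicographic pair order (deterministic across
#' runs), and set them to 1.
#'
#' @param m a `"pli_matrix"` or plain symmetric weight matrix.
#' @param s target sparsity (edge density) in (0, 1).
#' @return object of class `"adjacency_matrix"`: binary symmetric `a`,
#'   achieved `sparsity`, and `n_edges`.
#' @export
binarize_by_sparsity <- function(m, s) {
  w <- if (inherits(m, "pli_matrix")) m$m else m
  stopifnot(is.matrix(w), nrow(w) == ncol(w), s > 0, s < 1)
  n <- nrow(w)
  n_pairs <- n * (n - 1L) / 2L
  k <- round(s * n_pairs)
  if (k < 1L) stop("sparsity too small: zero edges would survive")
  idx <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  ord <- order(-wt, idx[, "row"], idx[, "col"])
  keep <- ord[seq_len(k)]
  a <- matrix(0L, n, n, dimnames = dimnames(w))
  a[idx[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  structure(list(a = a, sparsity = k / n_pairs, n_edges = k),
            class = "adjacency_matrix")
}

# unweighted all-pairs shortest-path distances (BFS per node via igraph)
adj_distances <- function(adj) {
  a <- if (inherits(adj, "adjacency_matrix")) adj$a else adj
  stopifnot(is.matrix(a), nrow(a) == ncol(a), nrow(a) >= 2L)
  g <- igraph::graph_from_adjacency_matrix(a != 0, mode = "undirected",
                                           diag = FALSE)
  igraph::distances(g, algorithm = "unweighted")
}

#' Global efficiency of a binary network
#'
#' Mean over ordered node pairs of the inverse shortest-path length,
#' with `1/Inf = 0` for disconnected pairs. Lies in \[0, 1\]; 1 for the
#' complete graph.
#'
#' @param adj an `"adjacency_matrix"` (or binary symmetric matrix).
#' @return scalar global efficiency.
#' @export
global_efficiency <- function(adj) {
  d <- adj_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(d) * (nrow(d) - 1L))
}

#' Characteristic path length of a binary network
#'
#' Mean shortest-path length over *connected* ordered node pairs;
#' disconnected pairs are excluded and their count attached as
#' attribute `"n_excluded"`. At least one edge must exist.
#'
#' @param adj an `"adjacency_matrix"` (or binary symmetric matrix).
#' @return scalar path length (>= 1 when any edge exists).
#' @export
characteristic_path_length <- function(adj) {
  d <- adj_distances(adj)
  diag(d) <- NA
  off <- d[!is.na(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0L) stop("graph has zero edges: path length undefined")
  out <- mean(fin)
  attr(out, "n_excluded") <- sum(!is.finite(off))
  out
}

#' Nodal efficiency of every node
#'
#' For node i, the mean over j != i of the inverse shortest-path
#' length `1/d(i, j)` (0 for disconnected pairs). The mean of the
#' nodal efficiencies equals the global efficiency exactly under these
#' conventions.
#'
#' @param adj an `"adjacency_matrix"` (or binary symmetric matrix).
#' @return numeric vector of per-node efficiencies in \[0, 1\].
#' @export
nodal_efficiency <- function(adj) {
  d <- adj_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(inv) - 1L)
}

#' Network metrics across a proportional sparsity sweep
#'
#' Binarizes the weighted matrix at each sparsity level, computes
#' global efficiency, characteristic path length and nodal efficiency,
#' and aggregates each metric as the trapezoidal area under its curve
#' over the sparsity range (the scalar used for group statistics).
#'
#' @param m a `"pli_matrix"` or plain symmetric weight matrix.
#' @param s_min,s_max,step sparsity range and step (defaults 0.1, 0.5,
#'   0.05).
#' @return object of class `"network_metrics"`: data.frame `per_level`
#'   (sparsity, e_global, char_path_length, n_excluded_pairs), matrix
#'   `e_nodal` (level x node), and list `auc` with `e_global`,
#'   `char_path_length`, `e_nodal` (per node).
#' @export
sparsity_sweep <- function(m, s_min = 0.1, s_max = 0.5, step = 0.05) {
  stopifnot(s_min < s_max, step > 0)
  s_levels <- seq(s_min, s_max, by = step)
  if (length(s_levels) < 2L) stop("sweep needs at least two sparsity levels")
  rows <- vector("list", length(s_levels))
  w <- if (inherits(m, "pli_matrix")) m$m else m
  e_nodal <- matrix(NA_real_, length(s_levels), nrow(w))
  for (k in seq_along(s_levels)) {
    adj <- binarize_by_sparsity(m, s_levels[k])
    eg <- global_efficiency(adj)
    cpl <- characteristic_path_length(adj)
    e_nodal[k, ] <- nodal_efficiency(adj)
    rows[[k]] <- data.frame(sparsity = s_levels[k], e_global = eg,
                            char_path_length = as.numeric(cpl),
                            n_excluded_pairs = attr(cpl, "n_excluded"))
  }
  per_level <- do.call(rbind, rows)
  auc <- list(
    e_global = trapz(s_levels, per_level$e_global),
    char_path_length = trapz(s_levels, per_level$char_path_length),
    e_nodal = apply(e_nodal, 2L, function(y) trapz(s_levels, y)))
  structure(list(per_level = per_level, e_nodal = e_nodal,
                 s_levels = s_levels, auc = auc),
            class = "network_metrics")
}

# trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> sparsity %g-%g (%d levels)\n",
              min(x$s_levels), max(x$s_levels), length(x$s_levels)))
  cat(sprintf("  AUC: e_global = %.4f, char_path_length = %.4f\n",
              x$auc$e_global, x$auc$char_path_length))
  invisible(x)
}
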