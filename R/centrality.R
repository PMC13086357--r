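#' PageRank centrality along the supply chain
#'
#' Power-iteration PageRank on the stored buyer-to-supplier orientation: a
#' random walk starts at some outlet and repeatedly follows a random
#' out-link, tracing purchases back up the chain, so the suppliers visited
#' most often score highest. A node's score is the damped sum of its
#' in-neighbours' scores divided by their outgoing-link counts `C(N)`
#' (self-loops count in `C(N)` and feed a node's score back to itself).
#'
#' Two variants are provided:
#' * `"normalised"` (default): the convention of standard library
#'   implementations - per-node teleport mass `(1 - d) / N`, and the mass
#'   of dangling nodes (out-degree 0, here the top-level suppliers) is
#'   redistributed uniformly at every iteration; scores sum to 1.
#' * `"eq1_literal"`: the fixed point of the recursive definition in its
#'   classic textbook form `PR(A) = (1 - d) + d * sum(PR(N_i) / C(N_i))`,
#'   with no `1/N` teleport scaling and no dangling redistribution
#'   (dangling nodes simply contribute nothing); on a network without
#'   dangling nodes the scores sum to the node count.
#'
#' @param net a `supply_network`.
#' @param damping damping factor `d` in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param variant `"normalised"` or `"eq1_literal"`.
#' @return a `pagerank_result`: `scores` (named), `damping`, `out_counts`,
#'   `iterations`, `converged`, `variant`.
#' @export
pagerank <- function(net, damping = 0.85, tol = 1e-10, max_iter = 1000,
                     variant = c("normalised", "eq1_literal")) {
  variant <- match.arg(variant)
  N <- n_nodes(net)
  if (N == 0) stop("empty network", call. = FALSE)
  stopifnot(damping > 0, damping < 1)
  A <- adjacency_matrix(net)
  C <- Matrix::rowSums(A)
  dangling <- C == 0
  Csafe <- ifelse(dangling, 1, C)
  M <- Matrix::t(A / Csafe)  # column j holds node j's outgoing shares

  x <- if (variant == "normalised") rep(1 / N, N) else rep(1, N)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    inflow <- as.numeric(M %*% ifelse(dangling, 0, x))
    x_new <- if (variant == "normalised") {
      (1 - damping) / N + damping * (inflow + sum(x[dangling]) / N)
    } else {
      (1 - damping) + damping * inflow
    }
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(scores = setNames(as.numeric(x), net$nodes$node_id),
         damping = damping,
         out_counts = setNames(as.numeric(C), net$nodes$node_id),
         iterations = iter, converged = converged, variant = variant),
    class = "pagerank_result"
  )
}

#' @export
print.pagerank_result <- function(x, ...) {
  cat(sprintf("<pagerank_result> %s, d = %g, %d iterations%s\n",
              x$variant, x$damping, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  top <- head(sort(x$scores, decreasing = TRUE), 5)
  cat("  top:", paste(names(top), signif(top, 4), sep = "=",
                      collapse = ", "), "\n")
  invisible(x)
}

# clustering building blocks over the loop-free binary adjacency
clustering_terms <- function(net) {
  A <- adjacency_matrix(net)
  Matrix::diag(A) <- 0  # self-loops never form triangles
  A <- (A != 0) * 1
  At <- Matrix::t(A)
  S <- A + At
  S2 <- S %*% S
  tri2 <- Matrix::rowSums(S2 * At + S2 * A)  # diag(S^3)
  U <- (S != 0) * 1
  U2 <- U %*% U
  triu <- Matrix::rowSums(U2 * U)  # diag(U^3)
  list(
    T_dir = as.numeric(tri2) / 2,
    deg_tot = as.numeric(Matrix::rowSums(A) + Matrix::colSums(A)),
    deg_bi = as.numeric(Matrix::rowSums(A * At)),
    L_und = as.numeric(triu) / 2,
    d_und = as.numeric(Matrix::rowSums(U))
  )
}

clustering_all <- function(net, mode, convention) {
  ct <- clustering_terms(net)
  vals <- if (mode == "undirected") {
    denom <- ct$d_und * (ct$d_und - 1)
    ifelse(denom > 0, 2 * ct$L_und / denom, 0)
  } else {
    denom <- ct$deg_tot * (ct$deg_tot - 1) - 2 * ct$deg_bi
    scale <- if (convention == "fagiolo") 1 else 2
    ifelse(denom > 0, ct$T_dir / (scale * denom), 0)
  }
  setNames(vals, net$nodes$node_id)
}

#' Local clustering coefficient
#'
#' How strongly a node's trading partners trade with each other.
#'
#' * `mode = "undirected"`: the network is symmetrised and
#'   `C_u = 2 L_u / (d_u (d_u - 1))`, with `L_u` the number of links among
#'   the `d_u` neighbours of `u`.
#' * `mode = "directed"` (default): all directed triangle configurations
#'   through `u` are counted, `T(u) = diag((A + A')^3)_u / 2`, and
#'   normalised by the number of possible triangles
#'   `deg_tot(u) (deg_tot(u) - 1) - 2 deg_bi(u)`, where `deg_tot` is
#'   in-degree plus out-degree and `deg_bi` the number of reciprocated
#'   partners. With `convention = "fagiolo"` (default) the normalisation is
#'   Fagiolo's `T / denom`, the convention of standard network libraries
#'   and the one under which a fully reciprocal network matches the
#'   undirected coefficient; `convention = "printed"` uses the halved form
#'   `T / (2 denom)` found in some published statements of the formula.
#'
#' Self-loops are excluded throughout; nodes with fewer than two partners
#' (or a non-positive denominator) return 0 by convention.
#'
#' @param net a `supply_network`.
#' @param nodes node ids to return (default all).
#' @param mode `"directed"` or `"undirected"`.
#' @param convention `"fagiolo"` or `"printed"` (directed mode only).
#' @return named numeric vector of coefficients in `[0, 1]`.
#' @export
local_clustering <- function(net, nodes = NULL,
                             mode = c("directed", "undirected"),
                             convention = c("fagiolo", "printed")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  vals <- clustering_all(net, mode, convention)
  if (is.null(nodes)) return(vals)
  unknown <- setdiff(nodes, names(vals))
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  vals[nodes]
}

#' Average clustering coefficient
#'
#' Arithmetic mean of [local_clustering()] over all nodes; nodes with too
#' few partners contribute 0, so the average is always defined on a
#' non-empty network.
#'
#' @inheritParams local_clustering
#' @return numeric.
#' @export
average_clustering <- function(net, mode = c("directed", "undirected"),
                               convention = c("fagiolo", "printed")) {
  if (n_nodes(net) == 0) stop("empty network", call. = FALSE)
  mean(clustering_all(net, match.arg(mode), match.arg(convention)))
}

#' Rank nodes by PageRank
#'
#' Orders nodes by descending score with a deterministic tie-break on
#' `node_id`, and reports the in-degree alongside so that link-count
#' importance and walk-based importance can be compared (the two need not
#' pick the same top node).
#'
#' @param result a [pagerank()] result.
#' @param net the network the result was computed on.
#' @return tibble with `rank`, `node_id`, `score`, `in_degree`.
#' @export
rank_nodes <- function(result, net) {
  stopifnot(inherits(result, "pagerank_result"))
  deg <- node_degrees(net, loops = TRUE)
  ids <- names(result$scores)
  ord <- order(-result$scores, ids)
  tibble::tibble(
    rank = seq_along(ids),
    node_id = ids[ord],
    score = as.numeric(result$scores[ord]),
    in_degree = deg$`in`[match(ids[ord], net$nodes$node_id)]
  )
}
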