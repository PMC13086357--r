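#' Top-level suppliers of a network
#'
#' Nodes with stored out-degree 0 once self-loops are ignored: businesses
#' that name no supplier of their own, i.e. the importers/manufacturers at
#' the head of the chains. The set is network-relative, so a sub-network can
#' expose more top-level nodes than its parent.
#'
#' @param net a `supply_network`.
#' @return character vector of node ids (node-table order).
#' @export
top_level_suppliers <- function(net) {
  deg <- node_degrees(net, loops = FALSE)
  net$nodes$node_id[deg$out == 0]
}

#' Retail outlets of a network
#'
#' Nodes whose declared role is `RETAILER` or `PHARMACY_WHOLESALER` - the
#' businesses that sell to end customers (licensed pharmacies and OTC
#' shops).
#'
#' @param net a `supply_network`.
#' @return character vector of node ids.
#' @export
retailer_nodes <- function(net) {
  net$nodes$node_id[net$nodes$role %in% c("RETAILER", "PHARMACY_WHOLESALER")]
}

#' Path-count matrix
#'
#' The `n`-th power of the adjacency matrix; entry `(i, j)` is the number
#' of directed walks of length `n` from `i` to `j`.
#'
#' @param net a `supply_network`.
#' @param n walk length, `>= 1`.
#' @return a sparse matrix with node ids as dimnames.
#' @export
path_counts <- function(net, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be an integer >= 1", call. = FALSE)
  }
  G <- adjacency_matrix(net)
  P <- G
  for (i in seq_len(n - 1)) P <- P %*% G
  P
}

#' Count directed loops of a given length
#'
#' Trace-based loop detection: for `n = 1` the count is `Tr(G)`, the number
#' of self-loops. For `n > 1` the trace is taken over powers of the
#' adjacency with the diagonal removed, so that a self-loop walked `n`
#' times is not mistaken for an `n`-link loop; the result counts closed
#' directed walks of length `n` avoiding self-loops, which in a network
#' whose only short cycles are self-loops equals (and certifies) the number
#' of genuine directed `n`-loops - zero for a healthy supply chain.
#'
#' @param net a `supply_network`.
#' @param n loop length, `>= 1`.
#' @return numeric count (each `n`-cycle is reported once per starting
#'   node, i.e. a triangle contributes 3).
#' @export
count_cycles <- function(net, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be an integer >= 1", call. = FALSE)
  }
  G <- adjacency_matrix(net)
  if (n == 1) return(sum(Matrix::diag(G)))
  Matrix::diag(G) <- 0
  P <- G
  for (i in seq_len(n - 1)) P <- P %*% G
  sum(Matrix::diag(P))
}

#' Supply-chain length statistics
#'
#' The chain length between a retailer `r` and a top-level supplier `t` is
#' the directed shortest-path distance from `r` to `t` along the stored
#' buyer-to-supplier edges - the number of purchases a drug passes through
#' on its way down to the retailer. Statistics are collected over reachable
#' ordered pairs `(r, t)` with `r != t`:
#' * `l_max` - the longest such distance (the network "diameter" in the
#'   supply-chain sense),
#' * `l_min` - the shortest (1 whenever some retailer buys directly from a
#'   top-level supplier),
#' * `l_avg` - the mean, either over all reachable pairs (default) or over
#'   each retailer's nearest top-level supplier
#'   (`mode = "per_retailer_min"`),
#' * `n_direct` - the number of direct links: edges running from a
#'   retailer-role node straight to a top-level node.
#'
#' @param net a `supply_network`.
#' @param mode `"all_pairs"` or `"per_retailer_min"`.
#' @return a `chain_stats` list: `l_max`, `l_min`, `l_avg`, `n_direct`,
#'   `pair_count`, `mode`.
#' @export
chain_stats <- function(net, mode = c("all_pairs", "per_retailer_min")) {
  mode <- match.arg(mode)
  retailers <- retailer_nodes(net)
  tops <- top_level_suppliers(net)
  if (length(retailers) == 0 || length(tops) == 0) {
    stop("no retailer/top-level pair exists", call. = FALSE)
  }
  g <- as_igraph(net)
  D <- igraph::distances(g, v = retailers, to = tops, mode = "out")
  if (length(intersect(retailers, tops)) > 0) {
    D[cbind(match(intersect(retailers, tops), retailers),
            match(intersect(retailers, tops), tops))] <- Inf
  }
  finite <- is.finite(D) & D >= 1
  if (!any(finite)) {
    stop("no retailer reaches a top-level supplier", call. = FALSE)
  }
  lens <- D[finite]
  l_avg <- if (mode == "all_pairs") {
    mean(lens)
  } else {
    per_min <- apply(D, 1, function(row) {
      m <- suppressWarnings(min(row[is.finite(row)]))
      if (is.finite(m)) m else NA_real_
    })
    mean(per_min, na.rm = TRUE)
  }
  lp <- link_pairs(net)
  n_direct <- sum(lp$buyer_id %in% retailers & lp$supplier_id %in% tops &
                    lp$buyer_id != lp$supplier_id)
  structure(
    list(l_max = max(lens), l_min = min(lens), l_avg = l_avg,
         n_direct = n_direct,
         pair_count = if (mode == "all_pairs") length(lens) else
           sum(apply(D, 1, function(row) any(is.finite(row)))),
         mode = mode),
    class = "chain_stats"
  )
}

#' @export
print.chain_stats <- function(x, ...) {
  cat(sprintf(
    "<chain_stats> L_max/L_min = %g/%g, L_avg = %.3f (%s over %d pairs), direct links = %d\n",
    x$l_max, x$l_min, x$l_avg, x$mode, x$pair_count, x$n_direct))
  invisible(x)
}

#' Average total degree
#'
#' `2 * links / nodes`: each link contributes one in-degree and one
#' out-degree.
#'
#' @param net a `supply_network`.
#' @return numeric.
#' @export
average_degree <- function(net) {
  if (n_nodes(net) == 0) stop("empty network", call. = FALSE)
  2 * n_links(net) / n_nodes(net)
}
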