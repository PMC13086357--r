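#' @importFrom stats rnorm runif rlnorm setNames pchisq coef predict lm
#' @importFrom utils read.csv write.csv head
NULL

#' Outlet roles recognised in a supply network
#'
#' The four business roles of the node taxonomy: importers (or local
#' manufacturers) at the head of chains, wholesalers, pharmacies that also
#' wholesale, and retail outlets (licensed pharmacies and over-the-counter
#' medicine shops).
#' @export
SUPPLY_ROLES <- c("IMPORTER", "WHOLESALER", "PHARMACY_WHOLESALER", "RETAILER")

#' Medicine price categories carried on supply links
#' @export
PRICE_CATEGORIES <- c("CHEAP", "INTERMEDIATE", "EXPENSIVE")

NODE_COLUMNS <- c("node_id", "name", "role", "latitude", "longitude",
                  "region", "visited")
EDGE_COLUMNS <- c("buyer_id", "supplier_id", "price_category")

#' Construct a directed supply network
#'
#' Builds a `supply_network` from a node table and an edge table. Edges are
#' stored in the buyer-to-supplier orientation: an edge from `u` to `v` means
#' outlet `u` buys medicine from `v`. Under this orientation a node's
#' in-degree counts its customers (the distribution network view) and its
#' out-degree counts its suppliers (the purchasing network view).
#'
#' Duplicate `(buyer, supplier, price_category)` triples are collapsed to a
#' single link; the same buyer-supplier pair may appear once per price
#' category, but the binary adjacency (and the link count) is over distinct
#' ordered pairs. Self-loops (`buyer_id == supplier_id`) are permitted and
#' are read as a business manufacturing and supplying from the same premises.
#'
#' @param nodes data frame with columns `node_id`, `name`, `role`,
#'   `latitude`, `longitude`, `region`, `visited`. Extra columns (such as the
#'   generator's `level`) are retained.
#' @param links data frame with columns `buyer_id`, `supplier_id`,
#'   `price_category` (`NA` or `"UNSET"` when not recorded).
#' @param strict if `TRUE`, an edge endpoint absent from the node table is an
#'   error; if `FALSE` (default) a placeholder node is created for it (role
#'   `WHOLESALER`, `visited = FALSE`, unknown coordinates) and the event is
#'   recorded in the load report. This mirrors surveyed networks in which
#'   suppliers of suppliers are nominated but never visited.
#' @return A `supply_network` object: a list with `nodes` and `links` tibbles
#'   and a `report` list (duplicates dropped, placeholder nodes added).
#' @seealso [load_network()], [adjacency_matrix()]
#' @export
supply_network <- function(nodes, links, strict = FALSE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  miss <- setdiff(NODE_COLUMNS, names(nodes))
  if (length(miss) > 0 && !(nrow(nodes) == 0 && ncol(nodes) == 0)) {
    stop("schema error: node table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(nodes) == 0) {
    nodes <- empty_node_table()
  }
  miss <- setdiff(EDGE_COLUMNS, names(links))
  if (length(miss) > 0 && !(nrow(links) == 0 && ncol(links) == 0)) {
    stop("schema error: edge table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(links) == 0) {
    links <- empty_edge_table()
  }

  nodes$node_id <- as.character(nodes$node_id)
  nodes$role <- toupper(as.character(nodes$role))
  nodes$visited <- as.logical(nodes$visited)
  nodes$latitude <- as.numeric(nodes$latitude)
  nodes$longitude <- as.numeric(nodes$longitude)
  nodes$region <- as.character(nodes$region)

  if (anyDuplicated(nodes$node_id)) {
    stop("node_id values must be unique; duplicated: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(nodes$role), SUPPLY_ROLES)
  if (length(bad_role) > 0) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  ok_lat <- is.na(nodes$latitude) | (nodes$latitude >= -90 & nodes$latitude <= 90)
  ok_lon <- is.na(nodes$longitude) | (nodes$longitude >= -180 & nodes$longitude <= 180)
  if (!all(ok_lat)) stop("latitude out of [-90, 90]", call. = FALSE)
  if (!all(ok_lon)) stop("longitude out of [-180, 180]", call. = FALSE)

  links$buyer_id <- as.character(links$buyer_id)
  links$supplier_id <- as.character(links$supplier_id)
  pc <- toupper(as.character(links$price_category))
  pc[is.na(pc) | pc == "" | pc == "NA"] <- "UNSET"
  bad_pc <- setdiff(unique(pc), c(PRICE_CATEGORIES, "UNSET"))
  if (length(bad_pc) > 0) {
    stop("unknown price category: ", paste(bad_pc, collapse = ", "), call. = FALSE)
  }
  links$price_category <- pc

  key <- paste(links$buyer_id, links$supplier_id, links$price_category, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  links <- links[!dup, , drop = FALSE]

  referenced <- unique(c(links$buyer_id, links$supplier_id))
  dangling <- setdiff(referenced, nodes$node_id)
  if (length(dangling) > 0) {
    if (strict) {
      stop("edge references unknown node(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
    placeholders <- data.frame(
      node_id = dangling,
      name = paste("placeholder", dangling),
      role = "WHOLESALER",
      latitude = NA_real_, longitude = NA_real_,
      region = NA_character_, visited = FALSE,
      stringsAsFactors = FALSE
    )
    for (extra in setdiff(names(nodes), names(placeholders))) {
      placeholders[[extra]] <- NA
    }
    nodes <- rbind(nodes[names(nodes)], placeholders[names(nodes)])
  }

  rownames(nodes) <- NULL
  rownames(links) <- NULL
  structure(
    list(
      nodes = tibble::as_tibble(nodes),
      links = tibble::as_tibble(links[EDGE_COLUMNS]),
      report = list(
        duplicates_dropped = n_dup,
        placeholder_nodes = if (length(dangling) > 0) dangling else character(0)
      )
    ),
    class = "supply_network"
  )
}

empty_node_table <- function() {
  data.frame(node_id = character(0), name = character(0), role = character(0),
             latitude = numeric(0), longitude = numeric(0),
             region = character(0), visited = logical(0),
             stringsAsFactors = FALSE)
}

empty_edge_table <- function() {
  data.frame(buyer_id = character(0), supplier_id = character(0),
             price_category = character(0), stringsAsFactors = FALSE)
}

#' Load a supply network from node and edge CSV files
#'
#' Reads the two-table CSV representation (see [supply_network()] for the
#' schema) and assembles the network. Lines starting with `#` are treated as
#' comments, so report files that carry a seed header can be re-read.
#'
#' @param node_table path to the node CSV, or a data frame.
#' @param edge_table path to the edge CSV, or a data frame.
#' @param strict passed to [supply_network()].
#' @return A `supply_network`.
#' @export
load_network <- function(node_table, edge_table, strict = FALSE) {
  read_tab <- function(x) {
    if (is.character(x) && length(x) == 1) {
      read.csv(x, stringsAsFactors = FALSE, comment.char = "#",
               colClasses = NA)
    } else {
      x
    }
  }
  supply_network(read_tab(node_table), read_tab(edge_table), strict = strict)
}

#' @export
print.supply_network <- function(x, ...) {
  cat(sprintf("<supply_network> %d nodes, %d links (%d self-loops)\n",
              n_nodes(x), n_links(x), n_self_loops(x)))
  if (x$report$duplicates_dropped > 0) {
    cat(sprintf("  load report: %d duplicate link(s) dropped\n",
                x$report$duplicates_dropped))
  }
  if (length(x$report$placeholder_nodes) > 0) {
    cat(sprintf("  load report: %d placeholder node(s) created\n",
                length(x$report$placeholder_nodes)))
  }
  invisible(x)
}

#' Number of nodes in a supply network
#' @param net a `supply_network`.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' Number of distinct directed links in a supply network
#'
#' Counts distinct ordered buyer-supplier pairs: a pair recorded under
#' several price categories is one link, matching the binary adjacency.
#' @param net a `supply_network`.
#' @export
n_links <- function(net) nrow(link_pairs(net))

#' Number of self-loops
#' @param net a `supply_network`.
#' @export
n_self_loops <- function(net) {
  lp <- link_pairs(net)
  sum(lp$buyer_id == lp$supplier_id)
}

# distinct ordered (buyer, supplier) pairs, in first-appearance order
link_pairs <- function(net) {
  lk <- net$links
  key <- paste(lk$buyer_id, lk$supplier_id, sep = "\r")
  lk[!duplicated(key), c("buyer_id", "supplier_id"), drop = FALSE]
}

#' Binary adjacency matrix of a supply network
#'
#' Returns the sparse binary matrix `G` with `G[u, v] = 1` iff there is a
#' link from buyer `u` to supplier `v`. Row/column order follows node-table
#' row order, so the matrix is reproducible for a given input. The matrix is
#' asymmetric in general; the sum of its entries equals the link count and
#' its trace the number of self-loops.
#'
#' @param net a `supply_network`.
#' @return a `dgCMatrix` with node ids as dimnames (0 x 0 for an empty
#'   network).
#' @export
adjacency_matrix <- function(net) {
  ids <- net$nodes$node_id
  n <- length(ids)
  lp <- link_pairs(net)
  Matrix::sparseMatrix(
    i = match(lp$buyer_id, ids),
    j = match(lp$supplier_id, ids),
    x = 1,
    dims = c(n, n),
    dimnames = list(ids, ids)
  )
}

# igraph view (vertex order = node-table order, isolated nodes kept)
as_igraph <- function(net) {
  lp <- link_pairs(net)
  igraph::graph_from_data_frame(
    data.frame(from = lp$buyer_id, to = lp$supplier_id,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes$node_id, stringsAsFactors = FALSE)
  )
}

# in/out degrees over distinct pairs; self-loops add 1 to each by default
node_degrees <- function(net, loops = TRUE) {
  ids <- net$nodes$node_id
  lp <- link_pairs(net)
  if (!loops) lp <- lp[lp$buyer_id != lp$supplier_id, , drop = FALSE]
  list(
    out = as.numeric(table(factor(lp$buyer_id, levels = ids))),
    `in` = as.numeric(table(factor(lp$supplier_id, levels = ids)))
  )
}

#' Compare declared node roles with roles derived from the link pattern
#'
#' Derives each node's role from its position in the chain, read in the
#' drug-flow orientation (the reverse of the stored buyer-to-supplier
#' arrows), and reports it next to the declared role:
#' * stored out-degree 0 (ignoring self-loops) with at least one customer:
#'   top of a chain, `IMPORTER`;
#' * both suppliers and customers: `WHOLESALER`, or `PHARMACY_WHOLESALER`
#'   when the declared role carries a retail flag (`RETAILER` or
#'   `PHARMACY_WHOLESALER`);
#' * suppliers only: `RETAILER`;
#' * no links at all (or a self-loop only): `UNKNOWN`.
#'
#' @param net a `supply_network`.
#' @return tibble with `node_id`, `declared_role`, `derived_role`,
#'   `consistent`.
#' @export
classify_roles <- function(net) {
  deg <- node_degrees(net, loops = FALSE)
  retail_flag <- net$nodes$role %in% c("RETAILER", "PHARMACY_WHOLESALER")
  derived <- ifelse(
    deg$out == 0 & deg$`in` == 0, "UNKNOWN",
    ifelse(deg$out == 0, "IMPORTER",
           ifelse(deg$`in` == 0, "RETAILER",
                  ifelse(retail_flag, "PHARMACY_WHOLESALER", "WHOLESALER")))
  )
  tibble::tibble(
    node_id = net$nodes$node_id,
    declared_role = net$nodes$role,
    derived_role = derived,
    consistent = derived == net$nodes$role
  )
}

#' Write a supply network as a GeoJSON FeatureCollection
#'
#' One Point feature per node (properties: `node_id`, `name`, `role`,
#' `region`) and one LineString feature per link (properties: `buyer_id`,
#' `supplier_id`, `price_category`). Coordinates are WGS84 `[longitude,
#' latitude]`. Links with an endpoint lacking coordinates are omitted.
#'
#' @param net a `supply_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(net, path) {
  nd <- net$nodes
  pts <- lapply(seq_len(nrow(nd)), function(i) {
    list(
      type = "Feature",
      geometry = if (is.na(nd$longitude[i]) || is.na(nd$latitude[i])) NULL else
        list(type = "Point",
             coordinates = c(nd$longitude[i], nd$latitude[i])),
      properties = list(node_id = nd$node_id[i], name = nd$name[i],
                        role = nd$role[i], region = nd$region[i])
    )
  })
  coords <- function(id) {
    i <- match(id, nd$node_id)
    c(nd$longitude[i], nd$latitude[i])
  }
  lk <- net$links
  lines <- lapply(seq_len(nrow(lk)), function(i) {
    a <- coords(lk$buyer_id[i]); b <- coords(lk$supplier_id[i])
    if (anyNA(c(a, b))) return(NULL)
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = list(a, b)),
      properties = list(buyer_id = lk$buyer_id[i],
                        supplier_id = lk$supplier_id[i],
                        price_category = lk$price_category[i])
    )
  })
  lines <- Filter(Negate(is.null), lines)
  fc <- list(type = "FeatureCollection", features = c(pts, lines))
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 10,
                              null = "null"), path)
  invisible(path)
}
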