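#' Regional sub-network
#'
#' Extracts the supply network serving one region. The seed set is the
#' retailer-role nodes located in the region (by region label, or by a
#' latitude/longitude bounding box); by default the full upstream closure is
#' included: every node reachable from a seed along the stored
#' buyer-to-supplier edges, together with all traversed edges, so chains of
#' any length survive the extraction. `mode = "one_hop"` keeps only the
#' seeds, their immediate suppliers and the connecting edges.
#'
#' @param net a `supply_network`.
#' @param region region label; must exist in the node table unless `bbox`
#'   is given.
#' @param mode `"closure"` (default) or `"one_hop"`.
#' @param bbox optional `c(lat_min, lat_max, lon_min, lon_max)` selecting
#'   seed retailers by coordinates instead of the region label.
#' @return a `supply_network` (possibly empty, with a warning, when the
#'   region holds no retailers).
#' @export
regional_subnetwork <- function(net, region, mode = c("closure", "one_hop"),
                                bbox = NULL) {
  mode <- match.arg(mode)
  if (is.null(bbox)) {
    if (!region %in% net$nodes$region) {
      stop("region not present in node table: ", region, call. = FALSE)
    }
    in_region <- !is.na(net$nodes$region) & net$nodes$region == region
  } else {
    stopifnot(length(bbox) == 4)
    in_region <- !is.na(net$nodes$latitude) & !is.na(net$nodes$longitude) &
      net$nodes$latitude >= bbox[1] & net$nodes$latitude <= bbox[2] &
      net$nodes$longitude >= bbox[3] & net$nodes$longitude <= bbox[4]
  }
  seeds <- intersect(net$nodes$node_id[in_region], retailer_nodes(net))
  if (length(seeds) == 0) {
    warning("region '", region, "' holds no retailers; empty sub-network",
            call. = FALSE)
    return(subset_network(net, character(0)))
  }
  if (mode == "closure") {
    g <- as_igraph(net)
    keep <- unique(unlist(lapply(seeds, function(s) {
      names(igraph::subcomponent(g, s, mode = "out"))
    })))
    subset_network(net, keep)
  } else {
    lp <- link_pairs(net)
    first <- lp[lp$buyer_id %in% seeds, , drop = FALSE]
    keep_nodes <- union(seeds, first$supplier_id)
    sub <- subset_network(net, keep_nodes)
    kl <- sub$links[sub$links$buyer_id %in% seeds, , drop = FALSE]
    sub$links <- kl
    sub
  }
}

# induced sub-network on a node-id set, preserving node-table order
subset_network <- function(net, keep_ids) {
  nd <- net$nodes[net$nodes$node_id %in% keep_ids, , drop = FALSE]
  lk <- net$links[net$links$buyer_id %in% keep_ids &
                    net$links$supplier_id %in% keep_ids, , drop = FALSE]
  supply_network(nd, lk)
}

#' Price-category sub-network
#'
#' Keeps the links labelled with one medicine price category, plus their
#' incident nodes. Links whose category was never recorded (`UNSET`) belong
#' to no price sub-network.
#'
#' @param net a `supply_network`.
#' @param category `"CHEAP"`, `"INTERMEDIATE"` or `"EXPENSIVE"`
#'   (case-insensitive).
#' @return a `supply_network`.
#' @export
price_subnetwork <- function(net, category) {
  category <- toupper(category)
  category <- match.arg(category, PRICE_CATEGORIES)
  if (nrow(net$links) > 0 && all(net$links$price_category == "UNSET")) {
    stop("no price categories recorded on any link", call. = FALSE)
  }
  lk <- net$links[net$links$price_category == category, , drop = FALSE]
  ids <- unique(c(lk$buyer_id, lk$supplier_id))
  nd <- net$nodes[net$nodes$node_id %in% ids, , drop = FALSE]
  supply_network(nd, lk)
}

#' Network attribute table
#'
#' One row per network with the eight structural attributes: node and link
#' counts, average degree, longest/shortest/average supply-chain length,
#' direct-link count, and average (directed) clustering coefficient. Rows
#' whose chain statistics cannot be computed (no retailer reaches a
#' top-level supplier, or an empty network) carry `NA` in those columns and
#' a diagnostic note instead of aborting the table.
#'
#' @param networks named list of `supply_network` objects; names label the
#'   rows.
#' @param convention clustering convention, see [average_clustering()].
#' @return tibble with columns `label`, `nodes`, `links`, `avg_degree`,
#'   `l_max`, `l_min`, `l_avg`, `direct_links`, `c_avg`, `note`.
#' @export
attribute_table <- function(networks, convention = c("fagiolo", "printed")) {
  convention <- match.arg(convention)
  stopifnot(length(networks) >= 1)
  if (is.null(names(networks)) || any(names(networks) == "")) {
    stop("networks must be a fully named list", call. = FALSE)
  }
  rows <- lapply(names(networks), function(label) {
    nt <- networks[[label]]
    row <- tibble::tibble(
      label = label, nodes = n_nodes(nt), links = n_links(nt),
      avg_degree = NA_real_, l_max = NA_real_, l_min = NA_real_,
      l_avg = NA_real_, direct_links = NA_integer_, c_avg = NA_real_,
      note = ""
    )
    note <- character(0)
    row$avg_degree <- tryCatch(average_degree(nt), error = function(e) {
      note <<- c(note, conditionMessage(e)); NA_real_
    })
    cs <- tryCatch(chain_stats(nt), error = function(e) {
      note <<- c(note, conditionMessage(e)); NULL
    })
    if (!is.null(cs)) {
      row$l_max <- cs$l_max
      row$l_min <- cs$l_min
      row$l_avg <- cs$l_avg
      row$direct_links <- cs$n_direct
    }
    row$c_avg <- tryCatch(
      average_clustering(nt, mode = "directed", convention = convention),
      error = function(e) {
        note <<- c(note, conditionMessage(e)); NA_real_
      })
    row$note <- paste(note, collapse = "; ")
    row
  })
  do.call(rbind, rows)
}

#' Whole-network plus standard sub-network decomposition
#'
#' Convenience assembly of the networks reported side by side in a survey
#' analysis: the whole network, one sub-network per region present among
#' the retailers, and one per recorded price category.
#'
#' @param net a `supply_network`.
#' @return named list of `supply_network` objects, starting with
#'   `"Whole Network"`.
#' @export
standard_subnetworks <- function(net) {
  out <- list("Whole Network" = net)
  regions <- unique(net$nodes$region[net$nodes$node_id %in%
                                       retailer_nodes(net)])
  regions <- sort(regions[!is.na(regions)])
  for (r in regions) {
    out[[r]] <- suppressWarnings(regional_subnetwork(net, r))
  }
  cats <- intersect(PRICE_CATEGORIES, unique(net$links$price_category))
  for (cc in cats) {
    out[[tools::toTitleCase(tolower(cc))]] <- price_subnetwork(net, cc)
  }
  out
}
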