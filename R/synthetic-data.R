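#' Configuration for the layered supply-network generator
#'
#' Describes a synthetic supply network with the structural signature of a
#' surveyed antimalarial supply chain: a power-law in-degree tail, a
#' log-normal supplier count bounded by `max_suppliers`, no directed cycles
#' beyond a handful of self-loops, chains of bounded length, and a dominant
#' geographic hub.
#'
#' Nodes are arranged in `n_levels` levels: level 0 holds the top-level
#' suppliers (importers/manufacturers), the last level holds retailers, and
#' intermediate levels hold wholesalers. Every non-top node buys from nodes
#' at strictly lower levels, which enforces acyclicity and bounds every
#' retailer-to-top chain at `n_levels - 1` links.
#'
#' @param n_retailers number of retail outlets (bottom level).
#' @param n_levels number of levels, `>= 2`; the default 5 gives a maximum
#'   chain length of 4.
#' @param level_sizes optional integer vector of length `n_levels` (top
#'   level first). When `NULL`, the top level gets `round(n_retailers / 3)`
#'   nodes and the intermediate levels share `round(0.575 * n_retailers)`,
#'   ratios taken from surveyed role counts.
#' @param target_exponent exponent `b` of the in-degree power law the
#'   generated networks are designed to exhibit; enters through the
#'   supplier-capacity distribution (see Details).
#' @param out_mu,out_sigma log-normal parameters of the supplier-count draw
#'   (number of distinct suppliers a non-top node uses).
#' @param max_suppliers cap on suppliers per node (observed out-degrees run
#'   0 to 6).
#' @param n_self_loops number of self-loops, placed on the top-level nodes
#'   of highest in-degree (manufacturer-and-supplier businesses).
#' @param epsilon additive attachment offset; a supplier's attachment
#'   weight is `(in_degree + epsilon * capacity) * affinity`.
#' @param redundancy_penalty multiplier in `[0, 1]` applied to the weight
#'   of a candidate supplier that already trades with one of the buyer's
#'   chosen suppliers. Buying from both an intermediary and that
#'   intermediary's own source is commercially redundant, so surveyed
#'   chains are close to tree-like; the penalty keeps the generated
#'   clustering coefficient near zero while leaving occasional triads.
#' @param attractiveness_range upper truncation of the Pareto capacity
#'   distribution (lower end 1).
#' @param regions data frame with columns `name`, `latitude`, `longitude`,
#'   `spread` (degrees, s.d. of node scatter) and `retailer_share`
#'   (shares must sum to 1).
#' @param hub_region region holding most top-level nodes.
#' @param hub_share probability that a top-level node sits in `hub_region`.
#' @param price_mix length-3 probability vector (cheap, intermediate,
#'   expensive) for edge price categories.
#' @param expensive_direct_bias fraction of EXPENSIVE edges forced onto
#'   direct retailer-to-top links.
#' @param seed RNG seed; all draws come from one generator seeded here.
#'
#' @details The attachment rule is preferential: a buyer at level `l` picks
#' each of its suppliers among nodes at levels `< l`, without replacement,
#' with probability proportional to `(current in-degree + epsilon * c_i) *
#' affinity`, where the capacity `c_i` is drawn from a Pareto distribution
#' with shape `target_exponent` truncated to `[1, attractiveness_range]`,
#' and affinity is 2 for a supplier in the buyer's own region, 1.5 for one
#' in the hub region and 1 otherwise. The Pareto capacities make realised
#' in-degrees a Poisson mixture over power-law rates, so the in-degree
#' distribution follows `k^-b` over the observed range with
#' `b = target_exponent`, while the in-degree term keeps the rich-get-richer
#' reinforcement of classical preferential attachment.
#'
#' @return a `generator_config` list.
#' @seealso [generate_network()], [ghana_like_preset()]
#' @export
generator_config <- function(n_retailers,
                             n_levels = 5L,
                             level_sizes = NULL,
                             target_exponent = 1.57,
                             out_mu = 0.5,
                             out_sigma = 0.4,
                             max_suppliers = 6L,
                             n_self_loops = 6L,
                             epsilon = 1,
                             redundancy_penalty = 0.1,
                             attractiveness_range = 3000,
                             regions = NULL,
                             hub_region = NULL,
                             hub_share = 0.7,
                             price_mix = c(cheap = 0.60, intermediate = 0.27,
                                           expensive = 0.13),
                             expensive_direct_bias = 0.9,
                             seed = 1L) {
  if (is.null(regions)) {
    regions <- data.frame(name = "Central", latitude = 0, longitude = 0,
                          spread = 0.5, retailer_share = 1,
                          stringsAsFactors = FALSE)
  }
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (is.null(hub_region)) hub_region <- regions$name[1]
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  if (max_suppliers < 1) stop("max_suppliers must be >= 1", call. = FALSE)
  if (target_exponent <= 0) stop("target_exponent must be positive", call. = FALSE)
  if (abs(sum(regions$retailer_share) - 1) > 1e-8) {
    stop("region retailer shares must sum to 1", call. = FALSE)
  }
  if (any(price_mix < 0) || abs(sum(price_mix) - 1) > 1e-8) {
    stop("price_mix must be probabilities summing to 1", call. = FALSE)
  }
  if (hub_share < 0 || hub_share > 1) stop("hub_share must lie in [0, 1]", call. = FALSE)
  if (redundancy_penalty < 0 || redundancy_penalty > 1) {
    stop("redundancy_penalty must lie in [0, 1]", call. = FALSE)
  }
  if (!hub_region %in% regions$name) stop("hub_region not in region table", call. = FALSE)
  if (is.null(level_sizes)) {
    n_top <- max(1L, round(n_retailers / 3))
    if (n_levels == 2) {
      level_sizes <- c(n_top, n_retailers)
    } else {
      n_mid_total <- max(n_levels - 2L, round(0.575 * n_retailers))
      n_mid <- rep(n_mid_total %/% (n_levels - 2L), n_levels - 2L)
      n_mid[1] <- n_mid[1] + n_mid_total - sum(n_mid)
      level_sizes <- c(n_top, n_mid, n_retailers)
    }
  }
  level_sizes <- as.integer(level_sizes)
  if (length(level_sizes) != n_levels) {
    stop("level_sizes must have length n_levels", call. = FALSE)
  }
  structure(
    list(n_retailers = as.integer(n_retailers), n_levels = n_levels,
         level_sizes = level_sizes, target_exponent = target_exponent,
         out_mu = out_mu, out_sigma = out_sigma,
         max_suppliers = as.integer(max_suppliers),
         n_self_loops = as.integer(n_self_loops), epsilon = epsilon,
         redundancy_penalty = redundancy_penalty,
         attractiveness_range = attractiveness_range,
         regions = regions, hub_region = hub_region, hub_share = hub_share,
         price_mix = price_mix,
         expensive_direct_bias = expensive_direct_bias,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Preset emulating the surveyed Ghana antimalarial network
#'
#' Six regions (three urban, three rural) with 20 retail outlets each, 69
#' intermediate wholesalers over three levels, 40 top-level suppliers
#' concentrated in the Accra hub, and 6 self-loops: 229 nodes in total, with
#' every supply chain at most 4 links long.
#'
#' @param seed RNG seed for [generate_network()].
#' @param ... overrides passed to [generator_config()].
#' @return a `generator_config`.
#' @export
ghana_like_preset <- function(seed = 1L, ...) {
  regions <- data.frame(
    name = c("Accra", "Kumasi", "Tamale", "Upper East", "Volta",
             "Western North"),
    latitude = c(5.56, 6.69, 9.40, 10.79, 6.61, 6.21),
    longitude = c(-0.20, -1.62, -0.84, -0.85, 0.47, -2.49),
    spread = c(0.15, 0.15, 0.15, 0.25, 0.25, 0.25),
    retailer_share = rep(1 / 6, 6),
    stringsAsFactors = FALSE
  )
  args <- list(
    n_retailers = 120L,
    n_levels = 5L,
    level_sizes = c(40L, 23L, 23L, 23L, 120L),
    regions = regions,
    hub_region = "Accra",
    seed = seed
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(generator_config, args)
}

# inverse-cdf draw from a Pareto density ~ x^-shape truncated to [1, xmax]
rtrunc_pareto <- function(n, shape, xmax) {
  u <- runif(n)
  if (abs(shape - 1) < 1e-12) {
    exp(u * log(xmax))
  } else {
    (1 - u * (1 - xmax^(1 - shape)))^(1 / (1 - shape))
  }
}

#' Generate a synthetic supply network
#'
#' Layered preferential-attachment construction (see [generator_config()]
#' for the mechanism). Guarantees, for every seed: no directed cycle of
#' length greater than 1 (levels strictly decrease along every non-loop
#' edge); non-top out-degrees in `[1, max_suppliers]`; top-level out-degree
#' 0 apart from the `n_self_loops` self-loops, which sit on the top-level
#' nodes of highest in-degree; every retailer-to-top chain at most
#' `n_levels - 1` links. EXPENSIVE price labels are biased onto direct
#' retailer-to-top edges and self-loops are always CHEAP (locally
#' manufactured stock).
#'
#' @param config a [generator_config()].
#' @return a `supply_network`; the node table carries the generator's
#'   `level` column (0 = top-level supplier).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  sizes <- config$level_sizes
  if (any(sizes < 1)) {
    stop("generation error: level ", which(sizes < 1)[1] - 1,
         " has no candidate nodes", call. = FALSE)
  }
  n_levels <- config$n_levels
  N <- sum(sizes)
  level <- rep(seq_along(sizes) - 1L, sizes)
  rg <- config$regions
  hub <- config$hub_region

  # region assignment: top level hub-weighted; intermediates by retailer
  # share with a doubled hub weight; retailers by exact shares
  region <- character(N)
  top_ix <- which(level == 0)
  w_top <- ifelse(rg$name == hub, config$hub_share,
                  (1 - config$hub_share) * ifelse(rep(nrow(rg) > 1, nrow(rg)),
                                                  1 / max(1, nrow(rg) - 1), 1))
  region[top_ix] <- sample(rg$name, length(top_ix), replace = TRUE, prob = w_top)
  mid_ix <- which(level > 0 & level < n_levels - 1)
  w_mid <- rg$retailer_share + ifelse(rg$name == hub, 1, 0)
  if (length(mid_ix) > 0) {
    region[mid_ix] <- sample(rg$name, length(mid_ix), replace = TRUE,
                             prob = w_mid / sum(w_mid))
  }
  ret_ix <- which(level == n_levels - 1)
  counts <- floor(rg$retailer_share * length(ret_ix))
  rem <- length(ret_ix) - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  region[ret_ix] <- rep(rg$name, counts)

  ri <- match(region, rg$name)
  latitude <- rg$latitude[ri] + rnorm(N, 0, rg$spread[ri])
  longitude <- rg$longitude[ri] + rnorm(N, 0, rg$spread[ri])

  # supplier capacities: truncated Pareto with tail index target_exponent
  capacity <- rep(1, N)
  sup_ix <- which(level < n_levels - 1)
  capacity[sup_ix] <- rtrunc_pareto(length(sup_ix), config$target_exponent,
                                    config$attractiveness_range)

  indeg <- numeric(N)
  nbrs <- vector("list", N)  # trading partners, both directions
  buyers <- integer(0)
  suppliers <- integer(0)
  for (l in seq_len(n_levels - 1)) {
    vs <- which(level == l)
    cands <- which(level < l)
    aff_hub <- ifelse(region[cands] == hub, 1.5, 1)
    for (v in vs) {
      s <- round(rlnorm(1, config$out_mu, config$out_sigma))
      s <- min(max(1L, s), config$max_suppliers, length(cands))
      aff <- ifelse(region[cands] == region[v], 2, aff_hub)
      w <- (indeg[cands] + config$epsilon * capacity[cands]) * aff
      pick <- integer(s)
      for (j in seq_len(s)) {
        pj <- cands[sample.int(length(cands), 1, prob = w)]
        pick[j] <- pj
        w[match(pj, cands)] <- 0  # no duplicate suppliers
        # discourage suppliers already trading with a chosen one
        linked <- match(nbrs[[pj]], cands)
        linked <- linked[!is.na(linked)]
        w[linked] <- w[linked] * config$redundancy_penalty
      }
      buyers <- c(buyers, rep(v, s))
      suppliers <- c(suppliers, pick)
      indeg[pick] <- indeg[pick] + 1
      for (pj in pick) nbrs[[pj]] <- c(nbrs[[pj]], v)
      nbrs[[v]] <- pick
    }
  }

  # self-loops on the best-connected top-level nodes
  n_sl <- min(config$n_self_loops, length(top_ix))
  loop_ix <- top_ix[order(-indeg[top_ix], top_ix)][seq_len(n_sl)]

  # price categories; expensive biased onto direct retailer-to-top edges
  E <- length(buyers)
  direct <- level[buyers] == n_levels - 1 & level[suppliers] == 0
  pm <- config$price_mix
  price <- character(E)
  n_exp <- round(pm[["expensive"]] * E)
  want_direct <- round(config$expensive_direct_bias * n_exp)
  if (want_direct > sum(direct)) {
    n_exp_direct <- sum(direct)
    n_exp_other <- floor(n_exp_direct * (1 - config$expensive_direct_bias) /
                           max(config$expensive_direct_bias, 1e-9))
  } else {
    n_exp_direct <- want_direct
    n_exp_other <- n_exp - want_direct
  }
  di <- which(direct)
  oi <- which(!direct)
  exp_edges <- c(
    if (n_exp_direct > 0) di[sample.int(length(di), n_exp_direct)],
    if (n_exp_other > 0) oi[sample.int(length(oi), min(n_exp_other, length(oi)))]
  )
  price[exp_edges] <- "EXPENSIVE"
  rest <- setdiff(seq_len(E), exp_edges)
  p_ci <- pm[c("cheap", "intermediate")]
  price[rest] <- sample(c("CHEAP", "INTERMEDIATE"), length(rest),
                        replace = TRUE, prob = p_ci / sum(p_ci))

  ids <- sprintf("N%04d", seq_len(N))
  role <- ifelse(level == 0, "IMPORTER",
                 ifelse(level == n_levels - 1, "RETAILER", "WHOLESALER"))
  nodes <- data.frame(
    node_id = ids,
    name = paste(tolower(role), seq_len(N), sep = "_"),
    role = role,
    latitude = latitude, longitude = longitude,
    region = region,
    visited = level > 0,  # top-level suppliers are nominated, not visited
    level = level,
    stringsAsFactors = FALSE
  )
  links <- data.frame(
    buyer_id = ids[c(buyers, loop_ix)],
    supplier_id = ids[c(suppliers, loop_ix)],
    price_category = c(price, rep("CHEAP", n_sl)),
    stringsAsFactors = FALSE
  )
  supply_network(nodes, links)
}

#' Write a network as the two-table CSV survey schema
#'
#' Emits `nodes.csv` and `edges.csv` in the [supply_network()] schema so
#' that [load_network()] on the output reproduces the network exactly.
#' Generator-internal columns (such as `level`) are not written.
#'
#' @param net a `supply_network`.
#' @param dir destination directory (created if needed).
#' @return named character vector with the two file paths, invisibly.
#' @export
generate_survey_tables <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  node_path <- file.path(dir, "nodes.csv")
  edge_path <- file.path(dir, "edges.csv")
  write.csv(as.data.frame(net$nodes)[NODE_COLUMNS], node_path,
            row.names = FALSE)
  write.csv(as.data.frame(net$links)[EDGE_COLUMNS], edge_path,
            row.names = FALSE)
  invisible(c(nodes = node_path, edges = edge_path))
}
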