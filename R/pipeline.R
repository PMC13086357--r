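#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: either a pair of input CSV
#' paths or a generator configuration (exactly one of the two), a seed, the
#' metric selection and output options.
#'
#' @param node_csv,edge_csv input table paths (both or neither).
#' @param preset a [generator_config()] to generate the input instead.
#' @param seed integer seed recorded in every output and used for all
#'   randomness (it overrides the seed inside `preset`).
#' @param out_dir output directory.
#' @param metrics subset of `c("attributes", "fits", "pagerank",
#'   "clustering", "geojson")`.
#' @param strict strict table loading (see [load_network()]).
#' @param damping,pagerank_variant,pagerank_tol PageRank options.
#' @param use_counts,dof_correction degree-fit chi-squared options.
#' @param clustering_convention see [average_clustering()].
#' @return a `run_config` list.
#' @export
run_config <- function(node_csv = NULL, edge_csv = NULL, preset = NULL,
                       seed = 1L, out_dir = tempfile("supplynet_run_"),
                       metrics = c("attributes", "fits", "pagerank",
                                   "clustering", "geojson"),
                       strict = FALSE, damping = 0.85,
                       pagerank_variant = "normalised",
                       pagerank_tol = 1e-10,
                       use_counts = TRUE, dof_correction = FALSE,
                       clustering_convention = "fagiolo") {
  has_input <- !is.null(node_csv) || !is.null(edge_csv)
  if (has_input && (is.null(node_csv) || is.null(edge_csv))) {
    stop("node_csv and edge_csv must be given together", call. = FALSE)
  }
  if (has_input && !is.null(preset)) {
    stop("exactly one of {input tables, generator preset} may be set",
         call. = FALSE)
  }
  if (!has_input && is.null(preset)) {
    stop("either input tables or a generator preset is required",
         call. = FALSE)
  }
  structure(
    list(node_csv = node_csv, edge_csv = edge_csv, preset = preset,
         seed = as.integer(seed), out_dir = out_dir,
         metrics = match.arg(metrics, several.ok = TRUE),
         strict = strict, damping = damping,
         pagerank_variant = pagerank_variant, pagerank_tol = pagerank_tol,
         use_counts = use_counts, dof_correction = dof_correction,
         clustering_convention = clustering_convention),
    class = "run_config"
  )
}

write_report_csv <- function(df, path, seed) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", seed), con)
  write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) a network, computes the selected reports and writes
#' them to the output directory, together with a manifest listing every
#' output file with its MD5 checksum. For a fixed configuration and seed
#' the outputs - including the manifest - are byte-identical across runs.
#'
#' Outputs (as selected): `nodes.csv` / `edges.csv` (the network),
#' `attributes.csv` (whole network plus regional and price sub-networks),
#' `degree_fits.csv` (three models by two directions, with the winner
#' flagged), `rankings.csv` (PageRank with in-degree and local clustering),
#' `network.geojson`, `manifest.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the network, the computed reports and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log <- character(0)

  if (!is.null(config$preset)) {
    preset <- config$preset
    preset$seed <- config$seed
    net <- generate_network(preset)
  } else {
    net <- load_network(config$node_csv, config$edge_csv,
                        strict = config$strict)
  }
  set.seed(config$seed)  # fit restarts etc. draw from here
  if (net$report$duplicates_dropped > 0) {
    log <- c(log, sprintf("%d duplicate link(s) dropped",
                          net$report$duplicates_dropped))
  }
  if (length(net$report$placeholder_nodes) > 0) {
    log <- c(log, sprintf("%d placeholder node(s) created",
                          length(net$report$placeholder_nodes)))
  }

  paths <- generate_survey_tables(net, config$out_dir)
  outputs <- c(outputs, paths)
  reports <- list(network = net)

  if ("attributes" %in% config$metrics) {
    tab <- attribute_table(standard_subnetworks(net),
                           convention = config$clustering_convention)
    p <- file.path(config$out_dir, "attributes.csv")
    write_report_csv(format_table(tab), p, config$seed)
    outputs <- c(outputs, p)
    reports$attributes <- tab
  }

  if ("fits" %in% config$metrics) {
    rows <- list()
    for (dir in c("in", "out")) {
      dist <- degree_distribution(net, dir)
      fits <- lapply(c("power_law", "exponential", "log_normal"),
                     function(m) fit_model(dist, m,
                                           use_counts = config$use_counts,
                                           dof_correction = config$dof_correction))
      best <- select_best_model(fits)
      for (f in fits) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          direction = dir, model = f$model,
          param1 = names(f$params)[1], value1 = unname(f$params[1]),
          param2 = names(f$params)[2], value2 = unname(f$params[2]),
          chi2 = f$chi2, dof = f$dof, p_value = f$p_value,
          best = f$model == best$model
        )
      }
    }
    fit_tab <- do.call(rbind, rows)
    p <- file.path(config$out_dir, "degree_fits.csv")
    write_report_csv(format_table(fit_tab), p, config$seed)
    outputs <- c(outputs, p)
    reports$degree_fits <- fit_tab
  }

  if (any(c("pagerank", "clustering") %in% config$metrics)) {
    pr <- pagerank(net, damping = config$damping,
                   tol = config$pagerank_tol,
                   variant = config$pagerank_variant)
    ranks <- rank_nodes(pr, net)
    if ("clustering" %in% config$metrics) {
      cl <- local_clustering(net, mode = "directed",
                             convention = config$clustering_convention)
      ranks$clustering_local <- as.numeric(cl[ranks$node_id])
    }
    p <- file.path(config$out_dir, "rankings.csv")
    write_report_csv(format_table(ranks), p, config$seed)
    outputs <- c(outputs, p)
    reports$rankings <- ranks
    reports$pagerank <- pr
  }

  if ("geojson" %in% config$metrics) {
    p <- file.path(config$out_dir, "network.geojson")
    write_geojson(net, p)
    outputs <- c(outputs, p)
  }

  manifest <- list(
    seed = config$seed,
    source = if (is.null(config$preset)) "tables" else "preset",
    n_nodes = n_nodes(net), n_links = n_links(net),
    log = log,
    outputs = lapply(unname(outputs), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  reports$manifest <- manifest
  invisible(reports)
}

# 4-significant-digit presentation for report files; full precision stays
# in the returned objects
format_table <- function(df) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !all(df[[col]] == round(df[[col]]),
                                      na.rm = TRUE)) {
      df[[col]] <- signif(df[[col]], 4)
    }
  }
  df
}
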