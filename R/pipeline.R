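# Command-line orchestration of the full workflow.  Every subcommand is a
# thin wrapper over the exported functions, so results from the CLI and
# from direct library calls are byte-identical given the same parameters.

default_config <- function() {
  list(
    z_cutoff = 1.96,          # standardized coexpression score cutoff
    t_d = 0.65,               # clustering density threshold
    t_s = 0.5,                # clustering support threshold
    min_cluster_size = 3,
    t_d_grid = "0.1,0.2,0.3,0.4,0.5,0.6,0.7,0.8,0.9",
    min_set_size = 10,        # gene-set size filter, lower bound
    max_set_size = 1500,      # gene-set size filter, upper bound
    es_cutoff = 1.3,          # annotation ES cutoff (q < 0.05)
    q_cutoff = 0.01,          # DE / perturbation selection cutoff
    enrich_q_cutoff = 0.1,    # sweep-evaluation enrichment cutoff
    min_weight = 0.80,        # first-neighbor edge-weight cutoff
    min_profile_set = 10,     # perturbation minimum profiled genes/cluster
    seed = 1
  )
}

parse_cli_args <- function(args) {
  if (length(args) == 0L)
    stop("usage: coexnet <subcommand> [--key value ...]; subcommands: ",
         "simulate, build-network, cluster, sweep, evaluate, annotate, ",
         "de, perturb, neighbors")
  sub <- args[[1L]]
  rest <- args[-1L]
  if (length(rest) %% 2L != 0L)
    stop("options must come in --key value pairs")
  keys <- if (length(rest)) rest[c(TRUE, FALSE)] else character()
  vals <- if (length(rest)) rest[c(FALSE, TRUE)] else character()
  if (!all(startsWith(keys, "--")))
    stop("malformed option(s): ", paste(keys[!startsWith(keys, "--")],
                                        collapse = ", "))
  keys <- gsub("-", "_", substring(keys, 3L))
  list(subcommand = sub, options = stats::setNames(as.list(vals), keys))
}

read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=\t]", perl = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  stats::setNames(lapply(kv, function(x) trimws(paste(x[-1L], collapse = "="))),
                  gsub("-", "_", trimws(vapply(kv, `[`, "", 1L))))
}

merge_config <- function(options) {
  cfg <- default_config()
  if (!is.null(options$config)) {
    file_cfg <- read_config_file(options$config)
    cfg[names(file_cfg)] <- file_cfg
    options$config <- NULL
  }
  cfg[names(options)] <- options
  numeric_keys <- setdiff(names(default_config()), "t_d_grid")
  for (k in intersect(names(cfg), numeric_keys))
    cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

write_manifest <- function(out_dir, subcommand, config, counts) {
  manifest <- list(subcommand = subcommand, config = config, counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

need_opt <- function(cfg, key, what) {
  if (is.null(cfg[[key]]))
    stop("missing required option --", gsub("_", "-", key), " (", what, ")")
  cfg[[key]]
}

parse_grid <- function(txt) as.numeric(strsplit(as.character(txt), ",")[[1L]])

load_network <- function(cfg) {
  edges <- need_opt(cfg, "edges", "edge-list TSV")
  read_network_edges(edges, nodes_path = cfg$nodes)
}

maybe_filtered_matrix <- function(cfg) {
  mat <- read_expression_matrix(need_opt(cfg, "expression", "expression TSV"))
  if (!is.null(cfg$grouping) && !is.null(cfg$average) &&
      as.logical(cfg$average)) {
    mat <- average_replicates(mat, read_sample_grouping(cfg$grouping))
  }
  if (!is.null(cfg$iqr_filter) && as.logical(cfg$iqr_filter)) {
    mat <- iqr_filter(mat)$matrix
  }
  mat
}

#' Run a pipeline subcommand
#'
#' The package's command-line entry point (installed as
#' \code{exec/coexnet}); can equally be called directly with an argv-style
#' character vector.  Subcommands: \code{simulate}, \code{build-network},
#' \code{cluster}, \code{sweep}, \code{evaluate}, \code{annotate},
#' \code{de}, \code{perturb}, \code{neighbors}.  Options are
#' \code{--key value} pairs; \code{--config FILE} loads key=value
#' defaults that individual flags override.  Every run writes its outputs
#' plus a \code{run_manifest.json} recording the subcommand, the resolved
#' parameters, and headline counts, into \code{--out-dir} (default the
#' working directory).
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(args) {
  parsed <- parse_cli_args(args)
  cfg <- merge_config(parsed$options)
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pathv <- function(...) file.path(out_dir, ...)
  sub <- parsed$subcommand
  written <- switch(
    sub,
    "simulate" = {
      design <- planted_design(
        n_genes = as.integer(need_opt(cfg, "n_genes", "total gene count")),
        n_conditions = as.integer(if (is.null(cfg$n_conditions)) 45L else cfg$n_conditions),
        block_sizes = as.integer(parse_grid(
          if (is.null(cfg$block_sizes)) "30,30,30,30,30" else cfg$block_sizes)),
        rho_in = if (is.null(cfg$rho_in)) 0.9 else as.numeric(cfg$rho_in),
        rho_out = if (is.null(cfg$rho_out)) 0 else as.numeric(cfg$rho_out),
        seed = as.integer(cfg$seed))
      sim <- simulate_expression(design)
      write_expression_matrix(sim$matrix, pathv("expression.tsv"))
      utils::write.table(
        data.frame(gene_id = names(sim$truth), block = unname(sim$truth)),
        pathv("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(out_dir, sub, cfg,
                     list(n_genes = nrow(sim$matrix),
                          n_conditions = ncol(sim$matrix)))
      c(expression = pathv("expression.tsv"), truth = pathv("truth.tsv"))
    },
    "build-network" = {
      mat <- maybe_filtered_matrix(cfg)
      scores <- pairwise_scores(mat)
      net <- threshold_network(scores, z_cutoff = cfg$z_cutoff)
      write_edge_list(net, pathv("edges.tsv"), nodes_path = pathv("nodes.tsv"))
      if (!is.null(cfg$sif)) write_sif(net, pathv(cfg$sif))
      if (!is.null(cfg$graphml)) write_graphml(net, pathv(cfg$graphml))
      write_manifest(out_dir, sub, cfg, list(
        n_genes = igraph::vcount(net), n_edges = igraph::ecount(net),
        edge_fraction = igraph::graph_attr(net, "edge_fraction"),
        min_r = igraph::graph_attr(net, "min_r")))
      c(edges = pathv("edges.tsv"), nodes = pathv("nodes.tsv"))
    },
    "cluster" = {
      net <- load_network(cfg)
      cs <- spici_cluster(net, clustering_params(cfg$t_d, cfg$t_s,
                                                 cfg$min_cluster_size))
      write_clusters(cs, pathv("clusters.tsv"))
      write_manifest(out_dir, sub, cfg, list(
        n_clusters = length(cs$clusters),
        n_clustered_genes = sum(lengths(cs$clusters)),
        n_unclustered = length(cs$unclustered)))
      c(clusters = pathv("clusters.tsv"))
    },
    "sweep" = ,
    "evaluate" = {
      net <- load_network(cfg)
      grid <- parse_grid(cfg$t_d_grid)
      sw <- sweep_cluster(net, grid, cfg$t_s, cfg$min_cluster_size)
      paths <- character()
      for (td in names(sw)) {
        f <- pathv(sprintf("clusters_td%s.tsv", td))
        write_clusters(sw[[td]], f)
        paths[paste0("clusters_", td)] <- f
      }
      gs <- NULL
      if (!is.null(cfg$gmt)) {
        gs <- read_gmt(cfg$gmt, universe = igraph::V(net)$name)
        gs <- filter_genesets(gs, min_size = cfg$min_set_size,
                              max_size = min(cfg$max_set_size, 499))
      }
      report <- evaluate_sweep(sw, net, genesets = gs,
                               q_cutoff = cfg$enrich_q_cutoff)
      write_sweep_report(report, pathv("sweep_report.tsv"))
      write_manifest(out_dir, sub, cfg, list(
        t_d_values = names(sw),
        n_clusters = stats::setNames(report$n_clusters, names(sw))))
      c(paths, report = pathv("sweep_report.tsv"))
    },
    "annotate" = {
      cs <- read_clusters(need_opt(cfg, "clusters", "cluster TSV"))
      gs <- read_gmt(need_opt(cfg, "gmt", "gene sets (GMT)"))
      gs <- filter_genesets(gs, cfg$min_set_size, cfg$max_set_size)
      res <- annotate_clusters(cs, gs, es_cutoff = cfg$es_cutoff)
      utils::write.table(res, pathv("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_manifest(out_dir, sub, cfg, list(
        n_pairs = nrow(res), n_annotated = sum(res$annotated)))
      c(enrichment = pathv("enrichment.tsv"))
    },
    "de" = {
      mat <- maybe_filtered_matrix(cfg)
      grouping <- read_sample_grouping(need_opt(cfg, "grouping",
                                                "sample grouping TSV"))
      prof <- de_test(mat, grouping,
                      c(need_opt(cfg, "treatment", "treatment group"),
                        need_opt(cfg, "control", "control group")))
      write_de_profile(prof, pathv("de.tsv"))
      write_de_profile(prof, pathv("fold_changes.tsv"),
                       fold_change_only = TRUE)
      sel <- select_de(prof, q_cutoff = cfg$q_cutoff)
      writeLines(sel$up, pathv("up_genes.txt"))
      writeLines(sel$down, pathv("down_genes.txt"))
      write_manifest(out_dir, sub, cfg, list(
        n_tested = nrow(prof), n_up = length(sel$up),
        n_down = length(sel$down)))
      c(de = pathv("de.tsv"), fold_changes = pathv("fold_changes.tsv"))
    },
    "perturb" = {
      fc <- read_fold_changes(need_opt(cfg, "profile",
                                       "two-column fold-change TSV"))
      cs <- read_clusters(need_opt(cfg, "clusters", "cluster TSV"))
      res <- page_zscores(fc, cs, min_set_size = cfg$min_profile_set)
      write_perturbation(res, pathv("perturbation.tsv"))
      sel <- select_perturbed(res, q_cutoff = cfg$q_cutoff)
      write_perturbation(sel, pathv("perturbation_selected.tsv"))
      write_manifest(out_dir, sub, cfg, list(
        n_scored = nrow(res), n_selected = nrow(sel),
        n_skipped = length(attr(res, "skipped"))))
      c(all = pathv("perturbation.tsv"),
        selected = pathv("perturbation_selected.tsv"))
    },
    "neighbors" = {
      net <- load_network(cfg)
      sub_g <- first_neighbors(net, need_opt(cfg, "gene", "query gene id"),
                               min_weight = cfg$min_weight)
      write_edge_list(sub_g, pathv("neighbors.tsv"),
                      nodes_path = pathv("neighbor_nodes.tsv"))
      if (!is.null(cfg$sif)) write_sif(sub_g, pathv(cfg$sif))
      write_manifest(out_dir, sub, cfg, list(
        n_neighbors = igraph::vcount(sub_g) - 1L,
        n_edges = igraph::ecount(sub_g)))
      c(neighbors = pathv("neighbors.tsv"))
    },
    stop("unknown subcommand: ", sub)
  )
  invisible(as.list(written))
}
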