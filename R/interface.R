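#' Load a run configuration
#'
#' Reads a YAML configuration whose keys mirror [evolution_config()] plus an
#' optional `topology` block (`kind`, `n_cells`, `p`, `branching`, `seed`)
#' and an optional `output_dir`. Unknown keys are rejected. A missing seed is
#' drawn once and recorded so the run stays reproducible. (The size key is
#' `n_cells`, not `n`: YAML 1.1 would read a bare `n` as a boolean.)
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list with elements `evolution`
#'   ([evolution_config()]), `topology` (a [topology][make_topology] or
#'   `NULL`), `output_dir`, `seed`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("population_size", "group_size", "generations",
             "mutation_probability", "mutation_sd_fraction", "mode",
             "alpha", "beta", "beta_sd_floor", "seed", "topology",
             "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seed <- raw$seed %||% sample.int(.Machine$integer.max, 1)
  topo <- NULL
  if (!is.null(raw$topology)) {
    tspec <- raw$topology
    topo <- make_topology(tspec$kind, tspec$n_cells, p = tspec$p,
                          branching = tspec$branching %||% 2L,
                          seed = tspec$seed)
  }
  ev_args <- raw[setdiff(names(raw), c("topology", "output_dir", "seed"))]
  if (!is.null(topo)) ev_args$group_size <- topo$n_cells
  ev_args$seed <- seed
  structure(list(evolution = do.call(evolution_config, ev_args),
                 topology = topo,
                 output_dir = raw$output_dir,
                 seed = seed),
            class = "run_config")
}

#' Write run metadata
#'
#' Records everything needed to reproduce a run bit-exactly: the full
#' configuration, seed, package version, and a timestamp.
#'
#' @param cfg A `run_config` or [evolution_config()] (or any list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_metadata <- function(cfg, path) {
  payload <- list(
    config = unclass(if (inherits(cfg, "run_config")) {
      list(evolution = unclass(cfg$evolution),
           topology = if (is.null(cfg$topology)) NULL else
             list(kind = cfg$topology$kind, n = cfg$topology$n_cells),
           output_dir = cfg$output_dir, seed = cfg$seed)
    } else cfg),
    package_version = as.character(utils::packageVersion("dolnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `dolnet` command-line script
#' (`inst/cli/dolnet.R`). Options are `--key value` pairs. Topologies come
#' either from `--topology KIND --n N [--p P --branching B --seed S]` or from
#' `--graph FILE [--format edge_list|graphml]`. Scalar results are printed
#' as JSON on stdout; grid results go to `--out FILE` as CSV; `--meta FILE`
#' writes reproducibility metadata.
#'
#' Subcommands: `fitness`, `stability`, `alpha-star`, `optimize`,
#' `phase-map`, `sweep-sparsity`, `evolve`, `meanfield`, `measure-f`,
#' `generate-graph`.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit code, invisibly (0 on success).
#' @export
run_cli <- function(argv) {
  code <- tryCatch({
    run_cli_impl(argv)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

run_cli_impl <- function(argv) {
  if (length(argv) == 0) stop("no subcommand given.", call. = FALSE)
  cmd <- argv[[1]]
  opts <- parse_cli_opts(argv[-1])
  out_json <- function(x) cat(jsonlite::toJSON(x, auto_unbox = TRUE,
                                               digits = NA), "\n")
  num <- function(key, default = NULL) {
    if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
  }
  grid <- function(key, default) {
    if (is.null(opts[[key]])) default else
      as.numeric(strsplit(opts[[key]], ",")[[1]])
  }
  seed <- if (is.null(opts$seed)) NULL else as.integer(opts$seed)

  switch(cmd,
    "generate-graph" = {
      t <- cli_topology(opts)
      write_graph_file(t, req(opts, "out"),
                       format = opts$format %||% "edge_list")
    },
    "fitness" = {
      t <- cli_topology(opts)
      cmat <- build_sharing(t, num("beta", 1))
      v <- as.numeric(strsplit(req(opts, "strategy"), ",")[[1]])
      out_json(list(W = group_fitness(v, cmat, num("alpha", 1))))
    },
    "stability" = {
      rep_ <- stability_report(cli_topology(opts), num("alpha", 1),
                               num("beta", 1))
      out_json(glance(rep_))
    },
    "alpha-star" = {
      out_json(list(alpha_star = alpha_star(cli_topology(opts))))
    },
    "optimize" = {
      opt <- maximize_fitness(cli_topology(opts), num("alpha", 1),
                              num("beta", 1),
                              restarts = num("restarts", 20), seed = seed)
      out_json(list(best_fitness = opt$best_fitness,
                    specialization = opt$specialization,
                    best_strategy = opt$best_strategy))
    },
    "phase-map" = {
      res <- phase_map(cli_topology(opts),
                       alphas = grid("alphas", seq(0.5, 1.5, 0.1)),
                       betas = grid("betas", seq(0, 1, 0.1)),
                       mode = opts$mode %||% "optimize", seed = seed)
      utils::write.csv(res, req(opts, "out"), row.names = FALSE)
    },
    "sweep-sparsity" = {
      res <- sparsity_sweep(
        n = num("n", 10),
        connection_fractions = grid("fractions", seq(0, 1, 0.1)),
        alphas = grid("alphas", seq(0.5, 1.5, 0.1)),
        replicates = num("replicates", 10), seed = seed)
      utils::write.csv(res, req(opts, "out"), row.names = FALSE)
    },
    "evolve" = {
      cfg <- load_config(req(opts, "config"))
      t <- cfg$topology %||% cli_topology(opts)
      res <- run_evolution(cfg$evolution, t)
      utils::write.csv(res$trajectory, req(opts, "out"), row.names = FALSE)
      if (!is.null(opts$meta)) save_metadata(cfg, opts$meta)
    },
    "meanfield" = {
      z <- num("z"); X <- num("x", 0.5)
      out_json(list(
        generalist_fitness = generalist_fitness_mf(num("n", 10)),
        specialist_fitness = specialist_fitness_mf(num("n", 10), z,
                                                   num("f", 1), X),
        f_threshold = f_threshold(z, X),
        min_fecundity_fraction = min_fecundity_fraction(z)))
    },
    "measure-f" = {
      t <- cli_topology(opts)
      lab <- utils::read.csv(req(opts, "labels"))
      labels <- lab$label[order(lab$cell)]
      out_json(list(f = as.numeric(measure_f(t, labels))))
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(NULL)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--")) stop("expected --option, got: ", key,
                                     call. = FALSE)
    if (i + 1 > length(args)) stop("missing value for ", key, call. = FALSE)
    opts[[sub("^--", "", key)]] <- args[[i + 1]]
    i <- i + 2
  }
  opts
}

req <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required --", key, call. = FALSE)
  opts[[key]]
}

cli_topology <- function(opts) {
  if (!is.null(opts$graph)) {
    return(read_graph_file(opts$graph, format = opts$format %||% "edge_list"))
  }
  make_topology(req(opts, "topology"), as.integer(req(opts, "n")),
                p = if (is.null(opts$p)) NULL else as.numeric(opts$p),
                branching = as.integer(opts$branching %||% 2L),
                seed = if (is.null(opts$seed)) NULL else
                  as.integer(opts$seed))
}
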