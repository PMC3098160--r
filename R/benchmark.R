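#' Benchmark configuration
#'
#' Bundles every knob of the simulated benchmark. Defaults reproduce the
#' reference protocol: 26 time points over \[0, 200\], 3 replicates, 5%
#' multiplicative noise, 200 interpolated points, solver tolerance 1e-6,
#' knockout steady states for every gene.
#'
#' @param sizes network sizes to benchmark.
#' @param n_networks independent networks per size.
#' @param procedures inference procedures to score; any of `"SOO"`,
#'   `"DSp"`, `"MOO-dSp"`, `"MOO-Tr"`, `"MOO-Sr"`, `"MOO-Tc"`, `"MOO-Sc"`,
#'   `"MOO-Tr+Sr"`, `"MOO-Tens"`, `"MOO-Sens"`.
#' @param seed master seed; everything downstream derives from it.
#' @param source optional [grn_network()] source topology. By default a
#'   scale-free source of `source_size` genes is generated.
#' @param source_size,source_avg_degree,activation_fraction source topology
#'   parameters.
#' @param n_timepoints,t_max,replicates,noise_level time-course protocol.
#' @param n_interp_points,max_degree interpolation settings.
#' @param max_delay,t_o delayed-correlation settings (grid steps).
#' @param ko_coverage fraction of genes with knockout data.
#' @param ratio_convention sign convention of the knockout ratio objective
#'   used by the benchmark (see [ratio_objective()]; `"log"` matches the
#'   historical ratio-based objectives whose directed-signed accuracy is
#'   poor but whose magnitudes are strong).
#' @param sqe_slack,tolerance optimizer settings (see [moo_fit()]).
#' @param kinetics_mode `"hill"` or `"linear"` data-generating dynamics.
#' @return a `grn_benchmark_config` list.
#' @export
benchmark_config <- function(sizes = c(20, 35, 50), n_networks = 10,
                             procedures = c("SOO", "DSp", "MOO-dSp", "MOO-Tr",
                                            "MOO-Sr", "MOO-Tc", "MOO-Sc",
                                            "MOO-Tr+Sr", "MOO-Tens", "MOO-Sens"),
                             seed = 1, source = NULL, source_size = 150,
                             source_avg_degree = 2, activation_fraction = 0.6,
                             n_timepoints = 26, t_max = 200, replicates = 3,
                             noise_level = 0.05, n_interp_points = 200,
                             max_degree = 6, max_delay = 20, t_o = 1,
                             ko_coverage = 1.0, ratio_convention = "log",
                             sqe_slack = 0.05, tolerance = 1e-6,
                             kinetics_mode = "hill") {
  procedures <- match.arg(procedures, several.ok = TRUE)
  cfg <- list(
    sizes = sizes, n_networks = check_count(n_networks, "n_networks"),
    procedures = procedures, seed = as.integer(seed), source = source,
    source_size = source_size, source_avg_degree = source_avg_degree,
    activation_fraction = activation_fraction,
    n_timepoints = n_timepoints, t_max = t_max, replicates = replicates,
    noise_level = noise_level, n_interp_points = n_interp_points,
    max_degree = max_degree, max_delay = max_delay, t_o = t_o,
    ko_coverage = ko_coverage, ratio_convention = ratio_convention,
    sqe_slack = sqe_slack, tolerance = tolerance, kinetics_mode = kinetics_mode
  )
  structure(cfg, class = "grn_benchmark_config")
}

proc_needs <- function(procedures) {
  list(
    dsp = any(procedures %in% c("DSp", "MOO-dSp")),
    ko_steady = any(procedures %in% c("MOO-Sr", "MOO-Sc", "MOO-Sens", "MOO-Tr+Sr")),
    ko_tc = any(procedures %in% c("MOO-Tr", "MOO-Tc", "MOO-Tens", "MOO-Tr+Sr"))
  )
}

# simulate one benchmark instance: network, data, objectives
benchmark_instance <- function(cfg, size, net_seed, needs = NULL) {
  needs <- needs %||% proc_needs(cfg$procedures)
  source <- cfg$source %||% generate_source_topology(
    cfg$source_size, cfg$source_avg_degree, cfg$activation_fraction,
    seed = derive_seed(cfg$seed, 0)
  )
  net <- extract_subnetwork(source, size, seed = net_seed)
  model <- sample_kinetics(net, mode = cfg$kinetics_mode, seed = derive_seed(net_seed, 1))
  pert <- sample_perturbation(model, seed = derive_seed(net_seed, 2))
  tc <- simulate_timecourse(
    model, pert, n_timepoints = cfg$n_timepoints, t_max = cfg$t_max,
    replicates = cfg$replicates, noise_level = cfg$noise_level,
    seed = derive_seed(net_seed, 3)
  )
  series <- interpolate_timecourse(average_replicates(tc),
                                   n_points = cfg$n_interp_points,
                                   max_degree = cfg$max_degree)
  inst <- list(network = net, model = model, series = series, seed = net_seed)
  if (needs$dsp) {
    inst$dsp <- delayed_spearman_objective(series, max_delay = cfg$max_delay, t_o = cfg$t_o)
  }
  if (needs$ko_steady) {
    inst$ko_steady <- simulate_knockout_compendium(
      model, mode = "steady", coverage = cfg$ko_coverage,
      noise_level = cfg$noise_level, seed = derive_seed(net_seed, 4)
    )
  }
  if (needs$ko_tc) {
    inst$ko_tc <- simulate_knockout_compendium(
      model, mode = "timecourse", coverage = cfg$ko_coverage,
      noise_level = cfg$noise_level, seed = derive_seed(net_seed, 5),
      n_timepoints = cfg$n_timepoints, t_max = cfg$t_max
    )
    inst$tp <- select_tp(inst$ko_tc, series)
  }
  inst
}

# fit (or score) a single procedure on a prepared instance; `cache` is an
# environment reusing component fits across ensemble procedures
fit_procedure <- function(procedure, inst, cfg, cache, fit_seed) {
  if (!is.null(cache[[procedure]])) return(cache[[procedure]])
  term_of <- function(kind) {
    obj <- switch(kind,
      dsp = inst$dsp$objective,
      tr = ratio_objective(inst$ko_tc, at = "tp", sign_convention = cfg$ratio_convention, tp = inst$tp),
      sr = ratio_objective(inst$ko_steady, at = "steady", sign_convention = cfg$ratio_convention),
      tc = correlation_objective(inst$ko_tc, at = "tp", tp = inst$tp),
      sc = correlation_objective(inst$ko_steady, at = "steady")
    )
    scale_objective(obj, "unit_max")
  }
  moo <- function(terms) {
    moo_fit(inst$series, terms, sqe_slack = cfg$sqe_slack,
            tolerance = cfg$tolerance, init_seed = fit_seed)
  }
  fit <- switch(procedure,
    "SOO" = soo_fit(inst$series, tolerance = cfg$tolerance, init_seed = fit_seed),
    "DSp" = grn_fit(inst$dsp$objective$O, rep(0, inst$network$n), role = "score",
                    gene_names = inst$network$gene_names),
    "MOO-dSp" = moo(term_of("dsp")),
    "MOO-Tr" = moo(term_of("tr")),
    "MOO-Sr" = moo(term_of("sr")),
    "MOO-Tc" = moo(term_of("tc")),
    "MOO-Sc" = moo(term_of("sc")),
    "MOO-Tr+Sr" = moo(list(term_of("tr"), term_of("sr"))),
    "MOO-Tens" = ensemble_combine(
      fit_procedure("MOO-Tr", inst, cfg, cache, fit_seed),
      fit_procedure("MOO-Tc", inst, cfg, cache, fit_seed)
    ),
    "MOO-Sens" = ensemble_combine(
      fit_procedure("MOO-Sr", inst, cfg, cache, fit_seed),
      fit_procedure("MOO-Sc", inst, cfg, cache, fit_seed)
    ),
    stop_bad("unknown procedure '%s'", procedure)
  )
  cache[[procedure]] <- fit
  fit
}

#' Run the simulated-network benchmark
#'
#' Orchestrates the full pipeline — subnetwork extraction, kinetic
#' sampling, noisy time-course and knockout simulation, replicate
#' averaging, polynomial interpolation, objective construction, SOO/MOO
#' fitting and AUC scoring — for every requested (size, network,
#' procedure) combination. Fully seeded: rerunning with the same
#' configuration reproduces the table bit for bit.
#'
#' @param config a [benchmark_config()].
#' @param verbose print progress lines?
#' @return a tibble of class `grn_benchmark` with columns `network_id`,
#'   `size`, `procedure`, `mode` (`"undirected"`/`"directed_signed"`),
#'   `auc`, `seed`.
#' @export
run_benchmark <- function(config = benchmark_config(), verbose = FALSE) {
  stopifnot(inherits(config, "grn_benchmark_config"))
  needs <- proc_needs(config$procedures)
  rows <- list()
  for (size in config$sizes) {
    for (k in seq_len(config$n_networks)) {
      net_seed <- derive_seed(config$seed, size, k)
      inst <- benchmark_instance(config, size, net_seed, needs)
      cache <- new.env(parent = emptyenv())
      for (p in seq_along(config$procedures)) {
        procedure <- config$procedures[p]
        fit <- tryCatch(
          fit_procedure(procedure, inst, config, cache, fit_seed = derive_seed(net_seed, 10, p)),
          error = function(e) {
            stop_bad("benchmark failure (size %d, network %d, %s): %s",
                     size, k, procedure, conditionMessage(e))
          }
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          network_id = sprintf("n%d_%d", size, k), size = size,
          procedure = procedure,
          mode = c("undirected", "directed_signed"),
          auc = c(auc_undirected(fit, inst$network),
                  auc_directed_signed(fit, inst$network)),
          seed = net_seed
        )
        if (verbose) {
          message(sprintf("size %d net %d %-9s AUC %.3f / %.3f", size, k, procedure,
                          rows[[length(rows)]]$auc[1], rows[[length(rows)]]$auc[2]))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grn_benchmark", class(out))
  attr(out, "config") <- config
  out
}

#' @export
summary.grn_benchmark <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$size, .data$procedure, .data$mode),
    n = dplyr::n(),
    mean_auc = mean(.data$auc),
    median_auc = median(.data$auc),
    .groups = "drop"
  )
}

#' Boxplots of benchmark AUC distributions
#'
#' One panel per (network size, evaluation mode), boxplots of per-network
#' AUC by inference procedure — the standard way benchmark accuracy
#' distributions are displayed.
#'
#' @param object a `grn_benchmark` tibble from [run_benchmark()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.grn_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$procedure <- factor(df$procedure, levels = unique(df$procedure))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$procedure, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_grid(.data$mode ~ .data$size,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "AUC") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
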