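#' End-to-end pipeline
#'
#' Orchestrates simulate -> networks -> metrics -> nulls -> robustness ->
#' sampling -> stats, with deterministic substream seeding (stage x site)
#' from the single configuration seed, and writes tidy long-format CSV
#' outputs plus a machine-readable run manifest.
#'
#' @name pipeline
NULL

stage_seed <- function(seed, stage, k = 0L) {
  offsets <- c(simulate = 0L, build = 1L, metrics = 2L, nulls = 3L,
               robustness = 4L, sampling = 5L, stats = 6L)
  (as.integer(seed) + 101L * offsets[[stage]] + 7919L * as.integer(k)) %%
    .Machine$integer.max
}

pipeline_stages <- c("simulate", "build", "metrics", "nulls", "robustness",
                     "sampling", "stats")

#' Default path-model DAG
#'
#' Hypothesised effects of fragmentation on network structure and
#' stability: island area and isolation act on connectance, modularity,
#' nestedness and robustness; connectance also acts on modularity and
#' nestedness; all three structure metrics act on robustness. Structure and
#' robustness enter as null-model z-scores, area and isolation as log10
#' values; the only non-adjacent endogenous pair (modularity, nestedness)
#' yields the single d-separation claim.
#'
#' @return edge data frame for [piecewise_sem()].
#' @export
default_sem_edges <- function() {
  rbind(
    expand.grid(from = c("log_area", "log_isolation"),
                to = c("connectance_z", "modularity_z", "wnodf_z",
                       "robustness_z"), stringsAsFactors = FALSE),
    data.frame(from = c("connectance_z", "connectance_z", "connectance_z",
                        "modularity_z", "wnodf_z"),
               to = c("modularity_z", "wnodf_z", "robustness_z",
                      "robustness_z", "robustness_z"),
               stringsAsFactors = FALSE))
}

write_networks <- function(networks, out_dir) {
  meta <- lapply(names(networks), function(s) {
    M <- networks[[s]]
    utils::write.table(M, file.path(out_dir, paste0("net_", s, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    list(site_id = s, n_plants = nrow(M), n_birds = ncol(M),
         total = sum(M), n_links = sum(M > 0))
  })
  jsonlite::write_json(meta, file.path(out_dir, "networks.json"),
                       auto_unbox = TRUE, digits = NA)
}

read_networks <- function(out_dir) {
  meta <- jsonlite::read_json(file.path(out_dir, "networks.json"),
                              simplifyVector = FALSE)
  nets <- list()
  for (m in meta) {
    M <- as.matrix(utils::read.table(
      file.path(out_dir, paste0("net_", m$site_id, ".tsv")),
      sep = "\t", header = TRUE, row.names = 1L, check.names = FALSE))
    storage.mode(M) <- "integer"
    attr(M, "site_id") <- m$site_id
    nets[[m$site_id]] <- M
  }
  nets
}

#' Run the full analysis pipeline
#'
#' @param config an [archipelago_config()] or a path to a YAML/JSON file of
#'   its fields.
#' @param out_dir output directory (created if needed).
#' @param stages subset of `simulate`, `build`, `metrics`, `nulls`,
#'   `robustness`, `sampling`, `stats`; stages not run read their inputs
#'   from `out_dir`.
#' @param null_reps Patefield ensemble size (study value 1000).
#' @param robustness_reps extinction-simulation repetitions (study value
#'   1000).
#' @param null_robustness_reps within-null-draw extinction repetitions,
#'   reduced to bound runtime.
#' @param null_modularity_restarts DIRTLPAwb+ restarts inside null draws
#'   (full restarts are used for the observed value).
#' @param modularity_restarts DIRTLPAwb+ restarts for observed networks.
#' @param target_days rarefaction target (study value: the minimum island
#'   effort, 414 camera-days).
#' @param rarefaction_reps subsamples per island.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the islands table, networks, metric and
#'   null tables, robustness, coverage, rarefaction, stats and SEM fits.
#' @export
run_all <- function(config, out_dir, stages = pipeline_stages,
                    null_reps = 1000L, robustness_reps = 1000L,
                    null_robustness_reps = 100L,
                    null_modularity_restarts = 2L,
                    modularity_restarts = 20L,
                    target_days = 414L, rarefaction_reps = 1000L,
                    quiet = FALSE) {
  if (is.character(config)) config <- read_archipelago_config(config)
  stopifnot(inherits(config, "archipelago_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  res <- list(config = config)

  stage_guard <- function(stage, site, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed",
           if (!is.null(site)) paste0(" at site ", site), ": ",
           conditionMessage(e), call. = FALSE))
  }

  if ("simulate" %in% stages) {
    say("simulate: ", config$n_islands, " islands")
    res$islands <- stage_guard("simulate", NULL, generate_archipelago(config))
    sys <- stage_guard("simulate", NULL,
                       generate_species_system(config, res$islands))
    res$traits <- sys$traits
    res$truth <- sys$truth
    res$events <- stage_guard("simulate", NULL,
                              generate_event_log(res$truth, res$islands,
                                                 config))
    ev_out <- res$events
    ev_out$timestamp <- format(ev_out$timestamp, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(ev_out, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(res$islands, file.path(out_dir, "islands.csv"),
                     row.names = FALSE)
    utils::write.csv(res$traits$birds, file.path(out_dir, "bird_traits.csv"),
                     row.names = FALSE)
    utils::write.csv(res$traits$plant_abundance,
                     file.path(out_dir, "plant_abundance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(knobs = list(nestedness = res$truth$nestedness_knob,
                        modularity = res$truth$modularity_knob),
           expected_events = as.list(res$truth$expected_events),
           plant_occ = res$truth$plant_occ, bird_occ = res$truth$bird_occ),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
  }

  need <- function(name, loader) {
    if (is.null(res[[name]])) res[[name]] <<- loader()
    res[[name]]
  }
  load_islands <- function() utils::read.csv(file.path(out_dir, "islands.csv"),
                                             stringsAsFactors = FALSE)
  load_events <- function() read_events(file.path(out_dir, "events.csv"))
  load_traits <- function() list(
    birds = utils::read.csv(file.path(out_dir, "bird_traits.csv"),
                            stringsAsFactors = FALSE),
    plant_abundance = utils::read.csv(file.path(out_dir,
                                                "plant_abundance.csv"),
                                      stringsAsFactors = FALSE))

  if ("build" %in% stages) {
    islands <- need("islands", load_islands)
    events <- need("events", load_events)
    say("build: independence filter + networks")
    indep <- stage_guard("build", NULL, filter_independent_events(events))
    res$independent_events <- indep
    nets <- list()
    for (s in islands$island_id) {
      ev <- indep[indep$island_id == s, , drop = FALSE]
      if (nrow(ev) == 0L) {
        say("build: site ", s, " has no events; excluded")
        next
      }
      nets[[s]] <- stage_guard("build", s, build_network(ev, s))
    }
    if (!length(nets)) stop("stage 'build' failed: no site produced a network",
                            call. = FALSE)
    res$networks <- nets
    write_networks(nets, out_dir)
  }

  if ("metrics" %in% stages) {
    nets <- need("networks", function() read_networks(out_dir))
    say("metrics: ", length(nets), " networks")
    rows <- list()
    res$partitions <- list()
    for (s in names(nets)) {
      M <- nets[[s]]
      part <- stage_guard("metrics", s,
                          dirt_lpa_wb_plus(M, n_restarts = modularity_restarts,
                                           seed = stage_seed(seed, "metrics",
                                                             match(s, names(nets)))))
      res$partitions[[s]] <- part
      wn <- if (nrow(M) == 1L && ncol(M) == 1L) NA_real_ else wnodf(M)
      rows[[s]] <- data.frame(
        site_id = s,
        metric = c("n_plants", "n_birds", "n_species", "n_links", "n_events",
                   "connectance", "modularity", "wnodf"),
        value = c(nrow(M), ncol(M), nrow(M) + ncol(M), sum(M > 0), sum(M),
                  connectance(M), part$Q, wn),
        stringsAsFactors = FALSE)
    }
    res$metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(res$partitions, function(p)
        list(Q = p$Q, row_labels = p$row_labels, col_labels = p$col_labels)),
      file.path(out_dir, "partitions.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("nulls" %in% stages || "robustness" %in% stages) {
    traits <- need("traits", load_traits)
    masses <- stats::setNames(traits$birds$body_mass_g,
                              traits$birds$bird_species)
    abund_of <- function(s) {
      pa <- traits$plant_abundance
      pa <- pa[pa$island_id == s, , drop = FALSE]
      stats::setNames(pa$abundance, pa$plant_species)
    }
  }

  if ("robustness" %in% stages) {
    nets <- need("networks", function() read_networks(out_dir))
    say("robustness: 4 scenarios x ", robustness_reps, " reps")
    rows <- list()
    for (s in names(nets)) {
      M <- nets[[s]]
      ab <- abund_of(s)
      # species seen interacting but missing from transect counts get
      # abundance 1 (detected at least once)
      ab <- c(ab, stats::setNames(rep(1, sum(!rownames(M) %in% names(ab))),
                                  rownames(M)[!rownames(M) %in% names(ab)]))
      for (sc in robustness_scenarios) {
        sim <- stage_guard("robustness", s,
                           simulate_robustness(M, sc, ab, masses,
                                               reps = robustness_reps,
                                               seed = stage_seed(seed, "robustness",
                                                                 match(s, names(nets)))))
        rows[[paste(s, sc)]] <- data.frame(
          site_id = s, scenario = sc, mean_R = sim$mean_R, sd_R = sim$sd_R,
          reps = robustness_reps, stringsAsFactors = FALSE)
      }
    }
    res$robustness <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.csv(res$robustness, file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
  }

  if ("nulls" %in% stages) {
    nets <- need("networks", function() read_networks(out_dir))
    say("nulls: ", null_reps, " Patefield draws per network")
    rows <- list()
    for (s in names(nets)) {
      M <- nets[[s]]
      ab <- abund_of(s)
      ab <- c(ab, stats::setNames(rep(1, sum(!rownames(M) %in% names(ab))),
                                  rownames(M)[!rownames(M) %in% names(ab)]))
      k <- match(s, names(nets))
      sweep_cap <- 2:max(2L, min(6L, nrow(M), ncol(M)))
      fns <- list(
        connectance = connectance,
        modularity = function(x)
          dirt_lpa_wb_plus(x, n_restarts = null_modularity_restarts,
                           module_sweep = sweep_cap)$Q)
      if (nrow(M) > 1L || ncol(M) > 1L) fns$wnodf <- wnodf
      for (sc in robustness_scenarios) {
        fns[[paste0("robustness_", sc)]] <- local({
          sc0 <- sc
          function(x) simulate_robustness(x, sc0, ab, masses,
                                          reps = null_robustness_reps)$mean_R
        })
      }
      set.seed(stage_seed(seed, "nulls", k))
      for (mn in names(fns)) {
        ns <- stage_guard("nulls", s,
                          null_ensemble(M, fns[[mn]], N = null_reps,
                                        metric = mn))
        ns$site_id <- s
        rows[[paste(s, mn)]] <- ns
      }
    }
    res$nulls <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.csv(res$nulls, file.path(out_dir, "nulls.csv"),
                     row.names = FALSE)
  }

  if ("sampling" %in% stages) {
    nets <- need("networks", function() read_networks(out_dir))
    islands <- need("islands", load_islands)
    events <- need("events", load_events)
    say("sampling: coverage + rarefaction to ", target_days, " camera-days")
    cov <- do.call(rbind, lapply(names(nets), function(s) {
      cv <- stage_guard("sampling", s, sample_coverage(nets[[s]]))
      data.frame(site_id = s, n = cv$n, f1 = cv$f1, f2 = cv$f2,
                 c_hat = cv$c_hat, stringsAsFactors = FALSE)
    }))
    res$coverage <- cov
    utils::write.csv(cov, file.path(out_dir, "coverage.csv"),
                     row.names = FALSE)
    rar <- list()
    for (s in names(nets)) {
      total <- islands$camera_days[islands$island_id == s]
      if (!length(total) || total <= target_days) next
      ev <- events[events$island_id == s, , drop = FALSE]
      rar[[s]] <- stage_guard("sampling", s,
                              rarefy_camera_days(ev, s, target_days,
                                                 reps = rarefaction_reps,
                                                 seed = stage_seed(seed, "sampling",
                                                                   match(s, names(nets))),
                                                 total_days = max(total,
                                                                  length(unique(camera_day_of(ev))))))
    }
    res$rarefaction <- if (length(rar))
      do.call(rbind, c(rar, list(make.row.names = FALSE))) else NULL
    if (!is.null(res$rarefaction))
      utils::write.csv(res$rarefaction, file.path(out_dir, "rarefaction.csv"),
                       row.names = FALSE)
  }

  if ("stats" %in% stages) {
    islands <- need("islands", load_islands)
    metrics <- need("metrics", function()
      utils::read.csv(file.path(out_dir, "metrics.csv"),
                      stringsAsFactors = FALSE))
    nulls <- need("nulls", function()
      utils::read.csv(file.path(out_dir, "nulls.csv"),
                      stringsAsFactors = FALSE))
    traits <- need("traits", load_traits)
    say("stats: regressions, SAR/IAR, connectivity, piecewise SEM")
    tab <- stage_guard("stats", NULL,
                       island_metric_table(islands, metrics, nulls))
    res$island_table <- tab
    utils::write.csv(tab, file.path(out_dir, "island_table.csv"),
                     row.names = FALSE)

    fits <- list()
    for (resp in c("n_species", "n_links", "n_plants", "n_birds",
                   "connectance_z", "modularity_z", "wnodf_z")) {
      if (!resp %in% names(tab)) next
      sub <- tab[!is.na(tab[[resp]]), , drop = FALSE]
      fits[[resp]] <- tryCatch(fit_metric_model(sub, resp),
                               error = function(e) NULL)
    }
    res$regressions <- fits
    res$sar_iar <- tryCatch(sar_iar_slopes(tab), error = function(e) NULL)
    res$area_isolation_cor <- pearson(log10(tab$area_ha),
                                      log10(tab$isolation_m))
    res$connectivity <- connectivity_indices(islands,
                                             traits$plant_abundance)
    utils::write.csv(res$connectivity, file.path(out_dir, "connectivity.csv"),
                     row.names = FALSE)

    res$sem <- list()
    sem_rows <- list()
    for (sc in robustness_scenarios) {
      rz <- paste0("robustness_", sc, "_z")
      if (!rz %in% names(tab)) next
      d <- tab[, c("log_area", "log_isolation", "connectance_z",
                   "modularity_z", "wnodf_z")]
      d$robustness_z <- tab[[rz]]
      d <- d[stats::complete.cases(d), , drop = FALSE]  # islands whose null
      # ensembles had zero spread carry undefined z and drop out
      fit <- tryCatch(piecewise_sem(default_sem_edges(), d),
                      error = function(e) NULL)
      if (is.null(fit)) next
      res$sem[[sc]] <- fit
      co <- fit$coefficients
      co$scenario <- sc
      sem_rows[[sc]] <- co
    }
    if (length(sem_rows))
      utils::write.csv(do.call(rbind, c(sem_rows,
                                        list(make.row.names = FALSE))),
                       file.path(out_dir, "sem_paths.csv"),
                       row.names = FALSE)
    reg_rows <- do.call(rbind, lapply(names(fits), function(r) {
      f <- fits[[r]]
      if (is.null(f)) return(NULL)
      data.frame(response = r, term = names(f$coefficients),
                 estimate = unname(f$coefficients),
                 p = unname(f$p_values), r_squared = f$r_squared,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(reg_rows))
      utils::write.csv(reg_rows, file.path(out_dir, "regressions.csv"),
                       row.names = FALSE)
  }

  manifest <- list(
    seed = seed, package = "frugnet",
    version = as.character(utils::packageVersion("frugnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    parameters = list(null_reps = null_reps,
                      robustness_reps = robustness_reps,
                      null_robustness_reps = null_robustness_reps,
                      target_days = target_days,
                      rarefaction_reps = rarefaction_reps),
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Assemble the per-island analysis table
#'
#' Joins island attributes with observed metrics and null-model z-scores
#' into one row per island, adding `log_area` and `log_isolation`.
#'
#' @param islands islands table.
#' @param metrics tidy metrics table (`site_id`, `metric`, `value`).
#' @param nulls tidy null-summary table from the pipeline.
#' @return wide per-island data frame.
#' @export
island_metric_table <- function(islands, metrics, nulls = NULL) {
  wide <- stats::reshape(metrics, idvar = "site_id", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  tab <- merge(islands, wide, by.x = "island_id", by.y = "site_id")
  if (!is.null(nulls)) {
    zt <- nulls[, c("site_id", "metric", "z")]
    zt$metric <- paste0(zt$metric, "_z")
    zw <- stats::reshape(zt, idvar = "site_id", timevar = "metric",
                         direction = "wide")
    names(zw) <- sub("^z\\.", "", names(zw))
    tab <- merge(tab, zw, by.x = "island_id", by.y = "site_id")
  }
  tab$log_area <- log10(tab$area_ha)
  tab$log_isolation <- log10(pmax(tab$isolation_m, 1))
  tab[order(tab$island_id), , drop = FALSE]
}

#' Headline summaries of a full interaction dataset
#'
#' Computes, from an event log and island table, the quantities a frugivory
#' study reports up front: total independent events, unique links, plant and
#' bird species totals, mean plants and birds per island network,
#' the area-isolation correlation, per-bird normalised-degree vs area
#' correlations for widespread species (present on more than half of the
#' islands), and the range of per-island sampling completeness.
#'
#' @param events raw event records (all sites).
#' @param islands island table (`island_id`, `area_ha`, `isolation_m`,
#'   optional `is_mainland`).
#' @return list of summaries.
#' @export
supplementary_summaries <- function(events, islands) {
  indep <- filter_independent_events(events)
  if (is.null(islands$is_mainland)) islands$is_mainland <- FALSE
  isl <- islands[!islands$is_mainland, , drop = FALSE]
  nets <- list()
  for (s in isl$island_id) {
    ev <- indep[indep$island_id == s, , drop = FALSE]
    if (nrow(ev)) nets[[s]] <- build_network(ev, s)
  }
  agg <- aggregate_networks(nets, "all_islands")
  deg <- list()
  n_isl <- length(nets)
  for (b in colnames(agg)) {
    on <- names(nets)[vapply(nets, function(M) b %in% colnames(M),
                             logical(1))]
    if (length(on) <= n_isl / 2 || length(on) < 3L) next  # not widespread
    nd <- vapply(on, function(s) normalized_degree(nets[[s]], b, "bird"),
                 numeric(1))
    ar <- log10(isl$area_ha[match(on, isl$island_id)])
    if (stats::sd(nd) == 0 || stats::sd(ar) == 0) next
    ct <- pearson(ar, nd)
    deg[[b]] <- data.frame(bird_species = b, n_islands = length(on),
                           r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  }
  deg <- if (length(deg))
    do.call(rbind, c(deg, list(make.row.names = FALSE))) else NULL
  cov <- vapply(nets, function(M) sample_coverage(M)$c_hat, numeric(1))
  list(
    n_events = nrow(indep),
    n_links = sum(agg > 0),
    n_plants = nrow(agg),
    n_birds = ncol(agg),
    mean_plants_per_network = mean(vapply(nets, nrow, numeric(1))),
    sd_plants_per_network = stats::sd(vapply(nets, nrow, numeric(1))),
    mean_birds_per_network = mean(vapply(nets, ncol, numeric(1))),
    sd_birds_per_network = stats::sd(vapply(nets, ncol, numeric(1))),
    area_isolation = if (nrow(isl) >= 3L)
      pearson(log10(isl$area_ha), log10(isl$isolation_m))
    else list(r = NA_real_, p = NA_real_),
    degree_area = deg,
    coverage_range = range(cov) * 100)
}

#' Command-line entry point
#'
#' Subcommands `simulate | build | metrics | nulls | robustness | sampling |
#' stats | all` with flags `--config <path>`, `--out <dir>`,
#' `--seed <int>` (overrides the config seed), `--reps <int>` (null and
#' robustness repetitions), `--quiet`.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return integer exit status: 0 on success, 2 on usage errors, 1 on
#'   runtime failure.
#' @export
frugnet_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: frugnet <subcommand> --config <yaml|json> --out <dir>",
    "                [--seed <int>] [--reps <int>] [--quiet]",
    "subcommands: simulate build metrics nulls robustness sampling stats all",
    sep = "\n")
  if (!length(argv) || argv[1L] %in% c("--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  sub <- argv[1L]
  if (!sub %in% c(pipeline_stages, "all")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  opts <- list(config = NULL, out = NULL, seed = NULL, reps = NULL,
               quiet = FALSE)
  i <- 2L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--quiet") {
      opts$quiet <- TRUE
      i <- i + 1L
      next
    }
    if (!a %in% c("--config", "--out", "--seed", "--reps")) {
      message("unknown flag: ", a, "\n", usage)
      return(invisible(2L))
    }
    if (i == length(argv)) {
      message("flag ", a, " needs a value\n", usage)
      return(invisible(2L))
    }
    opts[[sub("^--", "", a)]] <- argv[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$config) || is.null(opts$out)) {
    message("--config and --out are required\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- read_archipelago_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    reps <- if (!is.null(opts$reps)) as.integer(opts$reps) else 1000L
    stages <- if (sub == "all") pipeline_stages else sub
    run_all(cfg, opts$out, stages = stages, null_reps = reps,
            robustness_reps = reps, rarefaction_reps = reps,
            quiet = opts$quiet)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
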