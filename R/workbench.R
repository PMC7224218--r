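# Configuration-driven orchestration of the full study design:
#   synthetic world (or CSV inputs) -> pooled-background PCA ->
#   gridded COUE niche comparison -> conservatism permutation tests ->
#   n-dimensional hypervolume comparison -> reciprocal ENM ensembles.
# Every source of randomness is a sub-seed derived from the single
# global seed, so re-running a configuration reproduces every output
# byte for byte.

#' Study configuration
#'
#' Validates and freezes the parameters of a full study run.  Either a
#' synthetic `scenario` (a [niche_truth()] plus a
#' [background_config()]) or a set of input `files` (CSV paths:
#' `native_occ`, `invaded_occ`, `native_bg`, `invaded_bg`) must be
#' supplied.
#'
#' @param out_dir output directory (created if absent).
#' @param seed single global seed; all stage seeds derive from it.
#' @param scenario list with elements `truth` ([niche_truth()]) and
#'   `background` ([background_config()]).
#' @param files named list of CSV paths (alternative to `scenario`).
#' @param n_components PCA components retained for the COUE grid
#'   (first two are used for gridding).
#' @param grid_R grid resolution (default 100).
#' @param levels background-intersection percentiles (default 75, 100).
#' @param test_reps permutation repetitions (default 1000).
#' @param hv_dims hypervolume dimensionality (number of leading PCs;
#'   default `min(k, 3)`).
#' @param hv_n_random candidate points per hypervolume (default
#'   `max(10000, 500 * hv_dims)`).
#' @param enm_n_absence pseudo-absences per range (default 1000).
#' @param enm_n_repeats inner train/test repeats (default 10).
#' @param learners learner set for the ENM stage.
#' @return object of class `study_config`.
#' @export
study_config <- function(out_dir, seed = 1, scenario = NULL, files = NULL,
                         n_components = 2, grid_R = 100,
                         levels = c(75, 100), test_reps = 1000,
                         hv_dims = NULL, hv_n_random = NULL,
                         enm_n_absence = 1000, enm_n_repeats = 10,
                         learners = default_learners()) {
  stop_if(is.null(scenario) && is.null(files),
          "either a synthetic scenario or input files must be given")
  if (!is.null(files)) {
    need <- c("native_occ", "invaded_occ", "native_bg", "invaded_bg")
    missing <- setdiff(need, names(files))
    stop_if(length(missing) > 0,
            "files must name: ", paste(missing, collapse = ", "))
    absent <- need[!vapply(files[need], file.exists, logical(1))]
    stop_if(length(absent) > 0, "missing input file(s): ",
            paste(unlist(files[absent]), collapse = ", "))
  }
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario$truth, "niche_truth"),
              inherits(scenario$background, "background_config"))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scenario = scenario, files = files,
                 n_components = n_components, grid_R = grid_R,
                 levels = levels, test_reps = test_reps,
                 hv_dims = hv_dims, hv_n_random = hv_n_random,
                 enm_n_absence = enm_n_absence,
                 enm_n_repeats = enm_n_repeats, learners = learners),
            class = "study_config")
}

config_fingerprint <- function(cfg) {
  # identifies the analysis, not the run: output location excluded;
  # learner closures hash unstably and are represented by their names
  drop <- setdiff(names(cfg), c("learners", "out_dir"))
  fnv1a32(paste(utils::capture.output(utils::str(cfg[drop])),
                paste(names(cfg$learners), collapse = ","),
                collapse = "\n"))
}

#' Read a curated occurrence CSV
#'
#' Requires `species`, `lon`, `lat` columns; validates coordinates
#' (longitude in [-180, 180], latitude in [-90, 90]) and reports
#' offending line numbers.
#'
#' @param path CSV path.
#' @return occurrence data frame.
#' @export
read_occurrences <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(nrow(df) == 0, "empty occurrence file: ", path)
  need <- c("species", "lon", "lat")
  missing <- setdiff(need, names(df))
  stop_if(length(missing) > 0,
          "missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$lon) | !is.finite(df$lat) |
                 df$lon < -180 | df$lon > 180 |
                 df$lat < -90 | df$lat > 90)
  if (length(bad))
    stop("invalid coordinates at line(s): ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  df
}

#' Write an occurrence table as RFC-4180 CSV
#'
#' @param occ occurrence data frame.
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(niche_truth, x[c("centroid_native", "centroid_shift",
                           "niche_sd", "unfilling_frac",
                           "expansion_frac", "expansion_displacement",
                           "n_native", "n_invaded", "k", "seed")])
}

env_cols <- function(df) grep("^env[0-9]+$", names(df), value = TRUE)

#' Run the full study
#'
#' Executes, in order: data acquisition (synthetic simulation or CSV
#' input), pooled-background PCA, gridded COUE niche comparison,
#' niche equivalency and similarity tests, hypervolume comparison at
#' H_75/H_100, and the reciprocal ENM ensembles.  All tables, density
#' grids (ESRI ASCII) and a run log are written under `cfg$out_dir`;
#' every table carries the configuration fingerprint.  A stage failure
#' aborts with the stage name; outputs of completed stages are kept.
#'
#' @param cfg a [study_config()].
#' @return (invisibly) the report bundle: a list with the COUE
#'   metrics, test results, hypervolume comparisons and ENM table.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(cfg)
  logf <- file.path(cfg$out_dir, "run.log")
  cat(sprintf("nichechange run %s | seed %d | config %s\n",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), cfg$seed, fp),
      file = logf)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), cfg$out_dir),
           call. = FALSE))
  }
  stamp <- function(df) { df$config <- fp; df }
  out_csv <- function(df, name)
    utils::write.csv(stamp(df), file.path(cfg$out_dir, name),
                     row.names = FALSE)

  # -- data ---------------------------------------------------------
  dat <- stage("data", {
    if (!is.null(cfg$scenario)) {
      bgs <- make_env_backgrounds(cfg$scenario$background)
      sim <- simulate_species(cfg$scenario$truth, bgs)
      write_truth_json(cfg$scenario$truth,
                       file.path(cfg$out_dir, "truth.json"))
      write_occurrences(sim$native,
                        file.path(cfg$out_dir, "occ_native.csv"))
      write_occurrences(sim$invaded,
                        file.path(cfg$out_dir, "occ_invaded.csv"))
      list(occ_nat = sim$native, occ_inv = sim$invaded,
           bg_nat = bgs$native, bg_inv = bgs$invaded)
    } else {
      f <- cfg$files
      list(occ_nat = read_occurrences(f$native_occ),
           occ_inv = read_occurrences(f$invaded_occ),
           bg_nat = utils::read.csv(f$native_bg),
           bg_inv = utils::read.csv(f$invaded_bg))
    }
  })
  ev <- env_cols(dat$bg_nat)
  stop_if(length(ev) < 2, "backgrounds need env1..envk columns")

  # -- environmental space ------------------------------------------
  es <- stage("env_space", {
    model <- fit_env_space(dat$bg_nat[, ev], dat$bg_inv[, ev],
                           n_components = cfg$n_components)
    sc <- list(bg_nat = project_env(dat$bg_nat[, ev], model, k = 2),
               bg_inv = project_env(dat$bg_inv[, ev], model, k = 2),
               occ_nat = project_env(dat$occ_nat[, ev], model, k = 2),
               occ_inv = project_env(dat$occ_inv[, ev], model, k = 2))
    grid <- build_grid(sc$bg_nat, sc$bg_inv, R = cfg$grid_R)
    bd_nat <- background_density(sc$bg_nat, grid)
    bd_inv <- background_density(sc$bg_inv, grid)
    g_nat <- occurrence_density(sc$occ_nat, bd_nat, grid)
    g_inv <- occurrence_density(sc$occ_inv, bd_inv, grid)
    for (nm in c("g_nat", "g_inv")) {
      g <- get(nm)
      write_asc(g$z, file.path(cfg$out_dir, paste0("density_", nm, ".asc")),
                xll = grid$xlim[1], yll = grid$ylim[1],
                cellsize = grid$dx)
      write_asc(background_mask(g$bg, p = 100) * 1,
                file.path(cfg$out_dir, paste0("mask_i100_", nm, ".asc")),
                xll = grid$xlim[1], yll = grid$ylim[1],
                cellsize = grid$dx)
    }
    say("env_space: PC1+PC2 explain %.1f%% of pooled-background variance",
        100 * sum(model$var_frac[1:2]))
    list(model = model, scores = sc, grid = grid,
         g_nat = g_nat, g_inv = g_inv, bd_nat = bd_nat, bd_inv = bd_inv)
  })

  # -- COUE metrics --------------------------------------------------
  coue <- stage("coue", {
    cm <- coue_metrics(es$g_nat, es$g_inv, levels = cfg$levels)
    say("coue: D = %.3f, topology = %s", cm$schoener_D, cm$topology)
    cm
  })

  # -- conservatism tests -------------------------------------------
  tests <- stage("conservatism_tests", {
    eq <- equivalency_test(es$scores$occ_nat, es$scores$occ_inv,
                           es$bd_nat, es$bd_inv, es$grid,
                           n_reps = cfg$test_reps,
                           seed = derive_seed(cfg$seed, "tests"))
    s_both <- similarity_test(es$g_nat, es$g_inv, "both",
                              n_reps = cfg$test_reps,
                              seed = derive_seed(cfg$seed + 1, "tests"))
    s_inv <- similarity_test(es$g_nat, es$g_inv, "invaded",
                             n_reps = cfg$test_reps,
                             seed = derive_seed(cfg$seed + 2, "tests"))
    say("tests: equivalency P = %.4g; similarity N<->P P = %.4g, N->P P = %.4g",
        eq$p_value, s_both$p_value, s_inv$p_value)
    list(equivalency = eq, similarity_both = s_both,
         similarity_invaded = s_inv)
  })
  t1 <- as.data.frame(coue)
  t1 <- rbind(t1, data.frame(
    metric = c("schoener_D", "equivalency_P", "similarity_NP_P",
               "similarity_N2P_P", "centroid_shift_magnitude",
               "expansion_nonanalog"),
    level = "global",
    value = c(coue$schoener_D, tests$equivalency$p_value,
              tests$similarity_both$p_value,
              tests$similarity_invaded$p_value,
              coue$centroid_shift_magnitude, coue$expansion_nonanalog)))
  out_csv(t1, "table1_coue.csv")
  utils::write.csv(
    data.frame(scheme = c(rep("equivalency", cfg$test_reps),
                          rep("similarity-N<->P", cfg$test_reps),
                          rep("similarity-N->P", cfg$test_reps)),
               null_D = c(tests$equivalency$null_D,
                          tests$similarity_both$null_D,
                          tests$similarity_invaded$null_D)),
    file.path(cfg$out_dir, "null_distributions.csv"), row.names = FALSE)

  # -- hypervolumes --------------------------------------------------
  hv <- stage("hypervolume", {
    kk <- cfg$hv_dims %||% min(length(ev), 3)
    model <- es$model
    occ1 <- project_env(dat$occ_nat[, ev], model, k = kk)
    occ2 <- project_env(dat$occ_inv[, ev], model, k = kk)
    cmp <- lapply(c(75, 100), function(p) {
      h1 <- build_hypervolume(occ1, p = p, n_random = cfg$hv_n_random,
                              seed = derive_seed(cfg$seed, "hypervolume"))
      h2 <- build_hypervolume(occ2, p = p, n_random = cfg$hv_n_random,
                              seed = derive_seed(cfg$seed + 1, "hypervolume"))
      compare_hypervolumes(h1, h2)
    })
    names(cmp) <- c("H75", "H100")
    say("hypervolume: J(H75) = %.3f, J(H100) = %.3f",
        cmp$H75$jaccard, cmp$H100$jaccard)
    cmp
  })
  out_csv(rbind(as.data.frame(hv$H75), as.data.frame(hv$H100)),
          "table2_hypervolume.csv")

  # -- ENM -----------------------------------------------------------
  enm <- stage("enm", {
    n_abs <- cfg$enm_n_absence
    sub <- derive_seed(cfg$seed, "enm")
    pa_for <- function(occ, bg, label, s)
      make_pa_dataset(occ[, ev],
                      sample_pseudo_absences(bg, occ[, ev], n = n_abs,
                                             cell_size = 0.25,
                                             seed = s)[, ev],
                      label)
    pa_nat <- pa_for(dat$occ_nat, dat$bg_nat, "native", sub + 1)
    pa_inv <- pa_for(dat$occ_inv, dat$bg_inv, "invaded", sub + 2)
    pa_com <- make_pa_dataset(rbind(dat$occ_nat[, ev], dat$occ_inv[, ev]),
                              rbind(pa_nat$env[pa_nat$y == 0, ],
                                    pa_inv$env[pa_inv$y == 0, ]),
                              "combined")
    res <- reciprocal_enm(pa_nat, pa_inv, pa_com,
                          learners = cfg$learners,
                          n_repeats = cfg$enm_n_repeats, seed = sub)
    say("enm: %d evaluation rows", nrow(res$table))
    res
  })
  out_csv(enm$table, "table3_enm.csv")

  jsonlite::write_json(
    list(seed = cfg$seed, fingerprint = fp,
         n_components = cfg$n_components, grid_R = cfg$grid_R,
         levels = cfg$levels, test_reps = cfg$test_reps,
         package_version = as.character(utils::packageVersion("nichechange"))),
    file.path(cfg$out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  say("done")

  invisible(list(config = cfg, fingerprint = fp, coue = coue,
                 tests = tests, hypervolume = hv, enm = enm$table,
                 env_space = es))
}
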