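# Reciprocal-transfer experiment: train suitability ensembles on
# native, invaded and combined-range synthetic data with an injected
# niche shift, then evaluate each ensemble internally (its E_eval
# slice) and on the full presence/pseudo-absence dataset of the other
# range (E_inv / E_nat).  This turns the qualitative transferability
# result -- models transfer poorly across a niche shift, combined-range
# models transfer best -- into a measurable property.

#' Run one reciprocal-transfer experiment on synthetic ranges
#'
#' Builds a two-range world (`k` environmental dimensions), simulates
#' native occurrences from a Gaussian suitability kernel at the origin
#' and invaded occurrences from a kernel displaced by `shift` (in
#' niche-sd units along axis 1), assembles prevalence-balanced
#' presence/pseudo-absence datasets for the native, invaded and
#' combined ranges, fits TSS-weighted ensembles on each, and scores
#' every ensemble on its internal evaluation slice and on the transfer
#' datasets.
#'
#' @param shift niche centroid shift in niche-sd units (0 = niche
#'   conservatism).
#' @param n_presence presences per range.
#' @param n_absence pseudo-absences per range.
#' @param k environmental dimensionality (default 3).
#' @param n_repeats inner train/test repeats per learner (default 3;
#'   the full design uses 10).
#' @param learners learner set (default [default_learners()]).
#' @param seed RNG seed.
#' @return data frame with columns `train_range`, `eval_set`
#'   (`E_eval`, `E_inv`, `E_nat`), `auc`, `tss`.
#' @export
run_transfer_experiment <- function(shift = 2, n_presence = 150,
                                    n_absence = 300, k = 3,
                                    n_repeats = 3,
                                    learners = default_learners(),
                                    seed = 1) {
  cfg <- background_config(n_points = 4000, k = k, spread = 4,
                           seed = derive_seed(seed, "backgrounds"))
  bgs <- make_env_backgrounds(cfg)
  truth <- niche_truth(centroid_shift = c(shift, rep(0, k - 1)),
                       n_native = n_presence, n_invaded = n_presence,
                       k = k, seed = derive_seed(seed, "species"))
  sim <- simulate_species(truth, bgs)
  ev <- env_colnames(k)

  pa_for <- function(occ, bg, label, sub_seed) {
    abs_pts <- sample_pseudo_absences(bg, occ[, ev], n = n_absence,
                                      cell_size = 0.25, seed = sub_seed)
    make_pa_dataset(occ[, ev], abs_pts[, ev], label)
  }
  pa_nat <- pa_for(sim$native, bgs$native, "native", seed + 101)
  pa_inv <- pa_for(sim$invaded, bgs$invaded, "invaded", seed + 103)
  pa_com <- make_pa_dataset(rbind(sim$native[, ev], sim$invaded[, ev]),
                            rbind(pa_nat$env[pa_nat$y == 0, ],
                                  pa_inv$env[pa_inv$y == 0, ]),
                            "combined")

  reciprocal_enm(pa_nat, pa_inv, pa_com, learners = learners,
                 n_repeats = n_repeats, seed = seed)$table
}

#' Fit and reciprocally evaluate the three range ensembles
#'
#' Shared engine behind [run_transfer_experiment()] and the workbench:
#' fits one TSS-weighted ensemble per training dataset and scores each
#' on its internal E_eval slice and on the full presence/pseudo-absence
#' dataset of the other range(s).
#'
#' @param pa_nat,pa_inv,pa_com [make_pa_dataset()]s for the native,
#'   invaded and combined ranges.
#' @inheritParams run_transfer_experiment
#' @return list with `table` (train_range x eval_set AUC/TSS, plus the
#'   member-score ranges) and `ensembles`.
#' @export
reciprocal_enm <- function(pa_nat, pa_inv, pa_com,
                           learners = default_learners(), n_repeats = 3,
                           seed = 1) {
  fit_one <- function(pa, sub_seed) {
    plan <- split_dataset(pa, n_repeats = n_repeats, seed = sub_seed)
    ms <- suppressWarnings(fit_members(pa, plan, learners,
                                       seed = sub_seed))
    list(ens = build_ensemble(ms), eval = pa_subset(pa, plan$eval_idx),
         members = ms)
  }
  m_nat <- fit_one(pa_nat, seed + 211)
  m_inv <- fit_one(pa_inv, seed + 223)
  m_com <- fit_one(pa_com, seed + 227)

  member_rng <- function(m, what) {
    v <- vapply(m$members$members, function(x) x$scores[[what]],
                numeric(1))
    sprintf("%.2f-%.2f", min(v), max(v))
  }
  row <- function(train, set, m, pa) {
    s <- evaluate_model(m$ens, pa)
    data.frame(train_range = train, eval_set = set,
               auc = s$auc, tss = s$tss,
               member_auc_range = member_rng(m, "auc"),
               member_tss_range = member_rng(m, "tss"),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("native",   "E_eval", m_nat, m_nat$eval),
    row("native",   "E_inv",  m_nat, pa_inv),
    row("invaded",  "E_eval", m_inv, m_inv$eval),
    row("invaded",  "E_nat",  m_inv, pa_nat),
    row("combined", "E_eval", m_com, m_com$eval),
    row("combined", "E_inv",  m_com, pa_inv),
    row("combined", "E_nat",  m_com, pa_nat))
  list(table = tab,
       ensembles = list(native = m_nat$ens, invaded = m_inv$ens,
                        combined = m_com$ens))
}
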