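# Orchestration, file I/O and reproducibility of the report bundle.

test_that("occurrence CSV I/O validates and round-trips", {
  f <- tempfile(fileext = ".csv")
  occ <- data.frame(species = "x", lon = c(1.5, -10), lat = c(2.5, 80),
                    env1 = c(0.1, 0.2), stringsAsFactors = FALSE)
  write_occurrences(occ, f)
  back <- read_occurrences(f)
  expect_equal(back, occ)
  # second round trip is the identity
  f2 <- tempfile(fileext = ".csv")
  write_occurrences(back, f2)
  expect_equal(read_occurrences(f2), back)

  bad <- occ; bad$lat[2] <- 95
  write_occurrences(bad, f)
  expect_error(read_occurrences(f), "line\\(s\\): 3")
  writeLines("species,lon,lat", f)
  expect_error(read_occurrences(f), "empty")
  expect_error(read_occurrences(tempfile()), "no such file")
  nocol <- data.frame(a = 1)
  write.csv(nocol, f, row.names = FALSE)
  expect_error(read_occurrences(f), "missing column")
})

test_that("ESRI ASCII grids round-trip", {
  m <- matrix(rnorm(12), 3, 4)
  m[2, 2] <- NA
  f <- tempfile(fileext = ".asc")
  write_asc(m, f, xll = -5, yll = 10, cellsize = 0.5)
  r <- read_asc(f)
  expect_equal(r$mat, m, tolerance = 1e-9)
  expect_equal(r$xll, -5)
  expect_equal(r$yll, 10)
  expect_equal(r$cellsize, 0.5)
})

test_that("study configs are validated before any compute", {
  expect_error(study_config(tempdir()), "scenario or input files")
  expect_error(study_config(tempdir(),
                            files = list(native_occ = "nope.csv")),
               "files must name")
  expect_error(study_config(tempdir(),
                            files = list(native_occ = "a", invaded_occ = "b",
                                         native_bg = "c", invaded_bg = "d")),
               "missing input")
})

test_that("a zero-shift study recovers conservatism end to end, reproducibly", {
  scn <- list(truth = niche_truth(n_native = 250, n_invaded = 250, seed = 55),
              background = background_config(n_points = 1500, seed = 56))
  mk_cfg <- function(dir, ...) study_config(
    out_dir = dir, seed = 99, scenario = scn, grid_R = 50,
    test_reps = 49, enm_n_absence = 300, enm_n_repeats = 2, ...)
  d1 <- file.path(tempdir(), "study_a")
  b <- suppressMessages(run_study(mk_cfg(d1)))

  # conservatism world: high overlap, near-zero expansion, conservatism
  # inferred by the similarity tests (for two samples of one niche the
  # equivalency null holds exactly, so its p is uniform by design)
  expect_gt(b$coue$schoener_D, 0.5)
  expect_lt(b$coue$indices["expansion", "I100"], 0.1)
  expect_lte(b$tests$similarity_both$p_value, 0.05)
  expect_lte(b$tests$similarity_invaded$p_value, 0.05)
  expect_gt(b$tests$equivalency$p_value, 0)
  # sampling noise at the fringe can demote exact equality of the
  # occupied sets, but a zero-shift world must overlap heavily
  expect_true(b$coue$topology %in% c("overlap-complete", "partial-overlap"))

  # identical config + seed => byte-identical tables
  d2 <- file.path(tempdir(), "study_b")
  suppressMessages(run_study(mk_cfg(d2)))
  for (f in c("table1_coue.csv", "table2_hypervolume.csv", "table3_enm.csv",
              "occ_native.csv", "density_g_nat.asc")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  # tables carry the config fingerprint
  t1 <- read.csv(file.path(d1, "table1_coue.csv"))
  expect_true("config" %in% names(t1))
  expect_true(all(nchar(t1$config) > 0))

  # changing only hypervolume settings leaves the COUE table unchanged
  d3 <- file.path(tempdir(), "study_c")
  suppressMessages(run_study(mk_cfg(d3, hv_n_random = 12000)))
  a1 <- read.csv(file.path(d1, "table1_coue.csv"))
  a3 <- read.csv(file.path(d3, "table1_coue.csv"))
  expect_equal(a1$value, a3$value)
})

test_that("stage seeds derived from one global seed are distinct", {
  s <- vapply(c("backgrounds", "species", "coue", "tests", "hypervolume",
                "enm"), function(st) nichechange:::derive_seed(7, st),
              integer(1))
  expect_equal(length(unique(s)), length(s))
  expect_true(all(s >= 0 & s < 2^31))
})

test_that("a file-based study runs from CSV inputs", {
  bgs <- make_env_backgrounds(background_config(n_points = 900, seed = 77))
  sim <- simulate_species(niche_truth(n_native = 150, n_invaded = 150,
                                      seed = 78), bgs)
  dir <- file.path(tempdir(), "fileworld")
  dir.create(dir, showWarnings = FALSE)
  p <- function(x) file.path(dir, x)
  write_occurrences(sim$native, p("on.csv"))
  write_occurrences(sim$invaded, p("oi.csv"))
  write.csv(bgs$native, p("bn.csv"), row.names = FALSE)
  write.csv(bgs$invaded, p("bi.csv"), row.names = FALSE)
  cfg <- study_config(out_dir = p("out"), seed = 3,
                      files = list(native_occ = p("on.csv"),
                                   invaded_occ = p("oi.csv"),
                                   native_bg = p("bn.csv"),
                                   invaded_bg = p("bi.csv")),
                      grid_R = 40, test_reps = 19, enm_n_absence = 200,
                      enm_n_repeats = 2)
  b <- suppressMessages(run_study(cfg))
  expect_true(file.exists(p("out/table3_enm.csv")))
  expect_equal(nrow(b$enm), 7)
})
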