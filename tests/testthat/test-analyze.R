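test_that("the full pipeline writes consistent, refittable outputs", {
  sim <- sim_quick(n = 25, seed = 63, noise = 0.1)
  prefix <- file.path(withr::local_tempdir(), "run")
  writeLines(write_newick(sim$tree), paste0(prefix, ".in.nwk"))
  utils::write.table(data.frame(names(sim$dates$times), sim$dates$times),
                     paste0(prefix, ".dates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  rep <- analyze(paste0(prefix, ".in.nwk"), paste0(prefix, ".dates.tsv"),
                 best_root = TRUE, out_prefix = prefix)
  expect_true(all(file.exists(paste0(prefix, c(".rooted.nwk", ".rtt.tsv",
                                               ".diagnostics.tsv",
                                               ".stats.json")))))
  stats <- jsonlite::read_json(paste0(prefix, ".stats.json"),
                               simplifyVector = TRUE)
  # pipeline consistency: refitting from the emitted rtt TSV reproduces the
  # stats JSON slope/intercept
  tsv <- utils::read.delim(paste0(prefix, ".rtt.tsv"))
  refit <- fit_root_to_tip(stats::setNames(tsv$date, tsv$tip),
                           stats::setNames(tsv$distance, tsv$tip))
  expect_equal(stats$slope, refit$slope, tolerance = 1e-10)
  expect_equal(stats$intercept, refit$intercept, tolerance = 1e-10)
  expect_equal(stats$rooting$source, "best-fit")
  # determinism: a second identical run writes byte-identical tables
  prefix2 <- file.path(withr::local_tempdir(), "run2")
  analyze(paste0(prefix, ".in.nwk"), paste0(prefix, ".dates.tsv"),
          best_root = TRUE, out_prefix = prefix2)
  expect_identical(readLines(paste0(prefix, ".rtt.tsv")),
                   readLines(paste0(prefix2, ".rtt.tsv")))
  expect_identical(readLines(paste0(prefix, ".rooted.nwk")),
                   readLines(paste0(prefix2, ".rooted.nwk")))
})

test_that("best-root analysis recovers simulator truth end to end", {
  sim <- sim_quick(n = 30, seed = 65, noise = 0)
  rr <- random_reroot(sim$tree, seed = 7)
  rep <- analyze(rr$tree, sim$dates, best_root = TRUE)
  expect_equal(rep$fit$slope, sim$truth$rate, tolerance = 1e-8)
  expect_equal(rep$fit$x_intercept, sim$truth$root_time, tolerance = 1e-6)
})

test_that("isochronous mode reports a distance histogram, no regression", {
  sim <- sim_quick(n = 20, seed = 67, noise = 0.2)
  rep <- analyze(sim$tree, dates = NULL)
  expect_equal(rep$mode, "isochronous")
  expect_null(rep$fit)
  expect_true(sum(rep$distance_summary$counts) == 20)
  rep2 <- analyze(sim$tree, dates = NULL, best_root = TRUE)
  expect_lte(rep2$variance, rep$distance_summary$variance + 1e-15)
})

test_that("a negative slope analysis succeeds with a warning in the report", {
  # dates anti-correlated with divergence
  sim <- sim_quick(n = 15, seed = 69, noise = 0)
  d <- root_to_tip_distances(sim$tree)
  flipped <- tip_dates(stats::setNames(
    max(sim$dates$times) + min(sim$dates$times) - sim$dates$times,
    names(sim$dates$times)))
  rep <- analyze(sim$tree, flipped)
  expect_lt(rep$fit$slope, 0)
  expect_true(any(grepl("temporal signal", rep$warnings)))
})

test_that("missing dates fail by default and drop with drop_undated", {
  sim <- sim_quick(n = 10, seed = 71, noise = 0)
  short <- tip_dates(sim$dates$times[1:8])
  expect_error(analyze(sim$tree, short), "tip09.*tip10|tip10.*tip09")
  rep <- analyze(sim$tree, short, drop_undated = TRUE)
  expect_equal(rep$input$n_tips, 8)
  expect_true(any(grepl("dropped 2 undated", rep$warnings)))
})

test_that("validate_inputs reports problems as content, never as errors", {
  tr <- read_newick("((A:1,B:2):0.5,(C:1,D:1):1);")
  td <- tip_dates(c(A = 2000, B = 2001, E = 2002, F = 2003))
  rec <- validate_inputs(tr, td)
  expect_setequal(rec$missing_dates, c("C", "D"))
  expect_setequal(rec$extra_dates, c("E", "F"))
  expect_gt(length(rec$problems), 0)

  ok <- validate_inputs("((A:1,B:2):0.5,C:3);",
                        tip_dates(c(A = 1, B = 2, C = 3)))
  expect_length(ok$problems, 0)

  bad <- validate_inputs("((A:1,B:-2):0.5,C:3);")
  expect_true(any(grepl("negative", bad$problems)))
  expect_equal(bad$negative_edges, "B")

  nop <- validate_inputs("this is not a tree")
  expect_true(any(grepl("not parseable", nop$problems)))
})

test_that("the optional plot never breaks the analysis", {
  sim <- sim_quick(n = 12, seed = 73, noise = 0.1)
  prefix <- file.path(withr::local_tempdir(), "p")
  rep <- analyze(sim$tree, sim$dates, out_prefix = prefix, plot = TRUE)
  expect_s3_class(rep, "analysis_report")
  expect_true(file.exists(paste0(prefix, ".stats.json")))
})

test_that("the command-line wrapper runs the analyze workflow", {
  cli <- system.file("cli", "tiptempo.R", package = "tiptempo")
  skip_if(cli == "" || Sys.which("Rscript") == "")
  dir <- withr::local_tempdir()
  sim <- sim_quick(n = 12, seed = 75, noise = 0.05)
  writeLines(write_newick(sim$tree), file.path(dir, "t.nwk"))
  utils::write.table(data.frame(names(sim$dates$times), sim$dates$times),
                     file.path(dir, "d.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  out <- system2("Rscript", c(cli, "analyze", "--tree", file.path(dir, "t.nwk"),
                              "--dates", file.path(dir, "d.tsv"),
                              "--best-root", "--out", file.path(dir, "cli")),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status"), NULL)
  expect_true(file.exists(file.path(dir, "cli.stats.json")))
})
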