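test_that("self-consistency needs one prediction passing both strict thresholds", {
  expect_true(self_consistency(cbind(0.85, 1.5)))
  expect_false(self_consistency(rbind(c(0.85, 2.5), c(0.79, 1.0))))
  # boundary values fail under strict inequalities
  expect_false(self_consistency(cbind(0.8, 1.0)))
  expect_false(self_consistency(cbind(0.9, 2.0)))
  expect_error(self_consistency(matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("presets carry the published campaign thresholds", {
  m <- campaign_preset("mdm2")
  expect_equal(m$thresholds,
               list(ipae_max = 0.3, ddg_max = -50, sap_max = 35,
                    cms_min = 300))
  expect_equal(m$selection_size, 11L)
  g <- campaign_preset("gabarap")
  expect_equal(g$thresholds$ipae_max, 0.13)
  expect_equal(length(g$hotspots), 6L)
  r <- campaign_preset("rbta")
  expect_equal(r$thresholds$rmsd_pred_max, 1.5)
  expect_equal(length(r$hotspots), 7L)
  # mcl1 ships without numbers and refuses to filter unconfigured
  expect_error(apply_preset(data.frame(design_id = "d", ipae = 0.1,
                                       ddg = -60, sap = 10, cms = 400),
                            campaign_preset("mcl1")),
               "unset")
  m2 <- campaign_preset("mcl1", ipae_max = 0.35, ddg_max = -40,
                        sap_max = 40, cms_min = 250)
  expect_equal(apply_preset(data.frame(design_id = "d", ipae = 0.1,
                                       ddg = -60, sap = 10, cms = 400),
                            m2)$report$surviving, 1)
})

test_that("preset filtering is strict and attributes failures to the first failing metric", {
  recs <- data.frame(
    design_id = c("a", "b", "c", "d"),
    ipae = c(0.20, 0.35, 0.20, 0.20),
    ddg = c(-60, -60, -40, -60),
    sap = c(20, 20, 20, 40),
    cms = c(350, 350, 350, 350),
    stringsAsFactors = FALSE
  )
  res <- apply_preset(recs, campaign_preset("mdm2"))
  expect_equal(res$survivors$design_id, "a")
  expect_equal(res$report$failing_tally,
               list(ipae = 1L, ddg = 1L, sap = 1L, cms = 0L))
  expect_equal(res$report$input,
               res$report$surviving + sum(unlist(res$report$failing_tally)))

  # boundary values fail
  recs$ipae <- 0.3
  expect_equal(apply_preset(recs, campaign_preset("mdm2"))$report$surviving, 0)

  empty <- recs[0, ]
  r0 <- apply_preset(empty, campaign_preset("mdm2"))
  expect_equal(r0$report$input, 0)
  expect_equal(nrow(r0$survivors), 0)

  miss <- recs; miss$sap[2] <- NA
  expect_error(apply_preset(miss, campaign_preset("mdm2")), "sap")
})

test_that("tightening any threshold never grows the survivor set", {
  preset <- campaign_preset("mdm2")
  tab <- synth_metric_table(1000, preset, planted_pass_count = 320, seed = 15)
  base <- apply_preset(tab, preset)$survivors$design_id
  tighter <- list(
    campaign_preset("mdm2", ipae_max = 0.2),
    campaign_preset("mdm2", ddg_max = -60),
    campaign_preset("mdm2", sap_max = 25),
    campaign_preset("mdm2", cms_min = 400)
  )
  for (p in tighter) {
    surv <- apply_preset(tab, p)$survivors$design_id
    expect_true(all(surv %in% base))
    expect_lte(length(surv), length(base))
  }
})

test_that("ddG ranking is a stable ascending sort with id tie-breaks", {
  recs <- data.frame(design_id = c("z", "a", "m"),
                     ddg = c(-60, -55, -70), stringsAsFactors = FALSE)
  top <- rank_select(recs, "ddg", 2)
  expect_equal(top$design_id, c("m", "z"))
  expect_equal(nrow(rank_select(recs, "ddg", 0)), 0)
  expect_equal(nrow(rank_select(recs, "ddg", 99)), 3)
  tie <- data.frame(design_id = c("b", "a"), ddg = c(-50, -50))
  expect_equal(rank_select(tie, "ddg", 2)$design_id, c("a", "b"))
  expect_error(rank_select(recs, "nope", 1), "unknown ranking key")
})

test_that("per-cluster selection keeps the best designs of each cluster", {
  recs <- data.frame(
    design_id = sprintf("d%d", 1:6),
    ddg = c(-10, -50, -30, -60, -20, -40),
    cluster = c(1, 1, 2, 2, 3, 3),
    stringsAsFactors = FALSE
  )
  sel <- cluster_then_pick(recs, per_cluster = 1)
  expect_equal(sel$design_id, c("d2", "d4", "d6"))
  expect_equal(cluster_then_pick(recs, per_cluster = 5)$design_id,
               c("d2", "d1", "d4", "d3", "d6", "d5"))
  singles <- recs; singles$cluster <- 1:6
  expect_equal(sort(cluster_then_pick(singles)$design_id),
               sort(recs$design_id))
  bad <- recs; bad$cluster[2] <- NA
  expect_error(cluster_then_pick(bad), "unlabeled")
})

test_that("metric ingestion normalizes iPAE, reports malformed rows and round-trips", {
  tab <- synth_metric_table(10, campaign_preset("mdm2"),
                            planted_pass_count = 4, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics(tab, f)
  back <- ingest_metrics(f)
  for (m in c("plddt", "ipae", "ddg", "sap", "cms"))
    expect_equal(back[[m]], tab[[m]], tolerance = 1e-9)

  # raw interface PAE divided down to the normalized form
  raw <- tab; raw$ipae <- raw$ipae * 31
  write_metrics(raw, f)
  norm <- ingest_metrics(f, ipae_divisor = 31)
  expect_equal(norm$ipae, tab$ipae, tolerance = 1e-9)

  lines <- readLines(f)
  icol <- which(strsplit(lines[1], ",")[[1]] == "ddg")
  parts <- strsplit(lines[4], ",")[[1]]
  parts[icol] <- "broken"
  lines[4] <- paste(parts, collapse = ",")
  writeLines(lines, f)
  got <- ingest_metrics(f)
  expect_equal(nrow(got), 9)
  rej <- attr(got, "rejections")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "ddg")
})

test_that("funnel reports are deterministic for identical inputs", {
  preset <- campaign_preset("rbta")
  tab <- synth_metric_table(200, preset, planted_pass_count = 26, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics(tab, f)
  r1 <- apply_preset(ingest_metrics(f), preset)
  r2 <- apply_preset(ingest_metrics(f), preset)
  expect_identical(r1, r2)
  expect_equal(r1$report$surviving, 26)
})
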