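test_that("the bundled treatment table is the full 4x4x4 design", {
  tr <- load_fixture()
  expect_equal(nrow(tr), 64L)
  lv <- factor_levels()
  expect_setequal(unique(tr$d24_uM), lv$d24_uM)
  expect_setequal(unique(tr$kin_uM), lv$kin_uM)
  expect_setequal(unique(tr$snp_uM), lv$snp_uM)
  expect_equal(anyDuplicated(tr[c("d24_uM", "kin_uM", "snp_uM")]), 0L)
})

test_that("fixture values match the published summaries", {
  tr <- load_fixture()
  row <- tr[tr$d24_uM == 9.09 & tr$kin_uM == 4.65 & tr$snp_uM == 20, ]
  expect_equal(row$num_mean, 57.80)
  expect_equal(row$num_se, 0.21)
  expect_equal(row$emb_mean, 100)
  control <- tr[tr$d24_uM == 0 & tr$kin_uM == 0 & tr$snp_uM == 0, ]
  expect_true(all(control[-(1:3)] == 0))
  row2 <- tr[tr$d24_uM == 4.54 & tr$kin_uM == 4.65 & tr$snp_uM == 0, ]
  expect_equal(row2$emb_mean, 48.89)
  expect_equal(row2$emb_se, 5.88)
  expect_equal(observed_ideal(tr), c(emb = 100, num = 57.80))
})

test_that("load_fixture rejects corrupted tables", {
  tr <- load_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(tr[-1, ], tmp, row.names = FALSE)
  expect_error(load_fixture(tmp), "64 treatments")
  bad <- tr
  bad$cal_mean[5] <- 105
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_fixture(tmp), "rate mean")
  expect_error(load_fixture("/nonexistent/file.csv"), "not found")
})

test_that("replicate expansion reproduces every unclipped mean and SE", {
  tr <- load_fixture()
  expect_warning(reps <- expand_replicates(tr, 9, seed = 11), "clipping")
  expect_equal(nrow(reps), 576L)
  dev <- attr(reps, "clip_deviations")
  got <- summarize_replicates(reps)
  m <- merge(tr, got, by = c("d24_uM", "kin_uM", "snp_uM"),
             suffixes = c("", ".got"))
  for (resp in c("cal", "emb", "num")) {
    clipped <- dev$treatment[dev$response == resp]
    # merge() reorders rows; map clipped treatment indices to combinations
    clipped_keys <- paste(tr$d24_uM, tr$kin_uM, tr$snp_uM)[clipped]
    keys <- paste(m$d24_uM, m$kin_uM, m$snp_uM)
    ok <- !(keys %in% clipped_keys)
    mc <- paste0(resp, "_mean")
    sc <- paste0(resp, "_se")
    expect_lt(max(abs(m[[mc]][ok] - m[[paste0(mc, ".got")]][ok])), 1e-9)
    expect_lt(max(abs(m[[sc]][ok] - m[[paste0(sc, ".got")]][ok])), 1e-9)
  }
})

test_that("zero-SE treatments expand to constant replicates", {
  tr <- load_fixture()
  reps <- suppressWarnings(expand_replicates(tr, 9, seed = 4))
  sub <- reps[reps$d24_uM == 9.09 & reps$kin_uM == 4.65 & reps$snp_uM == 0, ]
  expect_equal(sub$emb_pct, rep(100, 9))
})

test_that("expansion is deterministic per seed and errors on n_reps < 2", {
  tr <- load_fixture()
  a <- suppressWarnings(expand_replicates(tr, 9, seed = 5))
  b <- suppressWarnings(expand_replicates(tr, 9, seed = 5))
  expect_identical(a, b)
  c3 <- suppressWarnings(expand_replicates(tr, 9, seed = 6))
  expect_false(identical(a$cal_pct, c3$cal_pct))
  expect_error(expand_replicates(tr, 1), "n_reps")
})

test_that("synthetic surface generator hits its peak and decays to zero", {
  cfg <- surface_config(noise_sd = c(cal = 0, emb = 0, num = 0))
  expect_equal(surface_truth(cfg, cfg$peak_location, "emb"),
               unname(cfg$peak_heights[["emb"]]))
  far <- cfg$peak_location + 100 * cfg$widths
  expect_lt(surface_truth(cfg, far, "num"), 1e-6)
  tab <- generate_surface(cfg, seed = 1)
  expect_equal(nrow(tab), 4 * 4 * 4 * 9)
  # noiseless: replicates within a cell are identical
  cell <- tab[tab$d24_uM == 9.09 & tab$kin_uM == 4.65 & tab$snp_uM == 20, ]
  expect_equal(length(unique(cell$emb_pct)), 1L)
})

test_that("summarize -> re-expand round trip preserves the means", {
  cfg <- surface_config(noise_sd = c(cal = 2, emb = 2, num = 0.5), n_reps = 5)
  tab <- generate_surface(cfg, seed = 2)
  s1 <- summarize_replicates(tab)
  reps2 <- suppressWarnings(expand_replicates(s1, n_reps = 5, seed = 3))
  s2 <- summarize_replicates(reps2)
  dev <- attr(reps2, "clip_deviations")
  keys1 <- paste(s1$d24_uM, s1$kin_uM, s1$snp_uM)
  for (resp in c("cal", "emb", "num")) {
    clipped_keys <- keys1[dev$treatment[dev$response == resp]]
    ok <- !(keys1 %in% clipped_keys)
    mc <- paste0(resp, "_mean")
    expect_lt(max(abs(s1[[mc]][ok] - s2[[mc]][ok])), 1e-9)
  }
})

test_that("surface config validates its inputs", {
  expect_error(surface_config(widths = c(1, -1, 2)), "widths")
  expect_error(surface_config(noise_sd = c(cal = -1, emb = 0, num = 0)),
               "noise_sd")
  expect_error(surface_config(levels = list(a = 1, b = 2, c = numeric(0))),
               "non-empty")
})

test_that("replicate CSV round trip preserves the table", {
  tab <- expanded_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_replicate_csv(tab, tmp)
  header <- readLines(tmp, n = 1)
  expect_identical(header, "d24_uM,kin_uM,snp_uM,cal_pct,emb_pct,num")
  back <- read_replicate_csv(tmp)
  expect_equal(back$cal_pct, tab$cal_pct, tolerance = 1e-12)
  expect_equal(back$rep_index, tab$rep_index)
})
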