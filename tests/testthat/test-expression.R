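# Ct plate processing: loading, interplate calibration, global-mean
# normalization, 2^-ddCt fold changes and the concordant dysregulation filter.

write_ct_file <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tf
}

ct_row <- function(plate, sample, rep, mirna, ct) {
  data.frame(plate_id = plate, sample_id = sample, replicate_id = rep,
             mirna_id = mirna, ct = ct, stringsAsFactors = FALSE)
}

test_that("Ct loader handles undetected markers and detection limit", {
  df <- rbind(ct_row("p1", "s1", "r1", "miR-1", "20"),
              ct_row("p1", "s1", "r1", "miR-2", "Undetermined"),
              ct_row("p1", "s1", "r1", "miR-3", ""),
              ct_row("p1", "s1", "r1", "miR-4", "38"))
  t <- load_ct(write_ct_file(df), detection_limit = 37)
  expect_equal(sum(is.na(t$ct)), 3)
  expect_equal(t$ct[t$mirna_id == "miR-1"], 20)

  dup <- rbind(ct_row("p1", "s1", "r1", "miR-1", "20"),
               ct_row("p1", "s1", "r1", "MIR-1", "21"))
  expect_error(load_ct(write_ct_file(dup)), "duplicate well key")
  expect_error(load_ct(write_ct_file(df[, -5])), "missing required column")
})

test_that("Ct tables round-trip through the writer", {
  df <- rbind(ct_row("p1", "s1", "r1", "miR-1", "20.5"),
              ct_row("p1", "s1", "r1", "miR-2", "Undetermined"),
              ct_row("p2", "s2", "r1", "miR-1", "25.25"))
  t <- load_ct(write_ct_file(df))
  out <- tempfile(fileext = ".tsv")
  write_ct(t, out)
  t2 <- load_ct(out)
  expect_equal(as.data.frame(t), as.data.frame(t2))
})

test_that("interplate calibration recovers plate offsets", {
  # single plate: offsets are zero, values unchanged
  one <- load_ct(write_ct_file(rbind(
    ct_row("p1", "s1", "r1", "miR-1", "30"),
    ct_row("p1", "s1", "r1", "cal", "20"))))
  c1 <- interplate_calibrate(one, "cal")
  expect_equal(c1$ct, 30)
  expect_equal(unname(attr(c1, "plate_offsets")), 0)

  # calibrator 20 and 22 -> offsets -1 and +1; ct 30 on plate 2 becomes 29
  two <- load_ct(write_ct_file(rbind(
    ct_row("p1", "s1", "r1", "miR-1", "25"),
    ct_row("p1", "s1", "r1", "cal", "20"),
    ct_row("p2", "s1", "r2", "miR-1", "30"),
    ct_row("p2", "s1", "r2", "cal", "22"))))
  c2 <- interplate_calibrate(two, "cal")
  expect_equal(c2$ct[c2$plate_id == "p2"], 29)
  expect_equal(c2$ct[c2$plate_id == "p1"], 26)
  expect_false("cal" %in% c2$mirna_id)

  # missing calibrator names the plate
  expect_error(interplate_calibrate(one, "nope"), "plate 'p1'")

  # injected random offsets recovered to machine precision (noise-free)
  spec <- synthetic_spec(n_nodes = 30, n_mirnas = 8, targets_per_mirna = 3,
                         ct_noise_sd = 0, seed = 21)
  plates <- generate_plates(spec, paste0("syn-miR-", 1:8))
  cal <- interplate_calibrate(plates, "UniSp3")
  gt <- attr(plates, "ground_truth")$plate_offsets
  est <- attr(cal, "plate_offsets")
  expect_equal(unname(est[names(gt)]), unname(gt), tolerance = 1e-12)
})

test_that("global-mean normalization centers each sample/replicate", {
  t <- load_ct(write_ct_file(rbind(
    ct_row("p1", "s1", "r1", "miR-1", "20"),
    ct_row("p1", "s1", "r1", "miR-2", "22"),
    ct_row("p1", "s1", "r1", "miR-3", "24"))))
  d <- global_mean_normalize(t)
  expect_equal(sort(d$ct), c(-2, 0, 2))

  allsame <- load_ct(write_ct_file(rbind(
    ct_row("p1", "s1", "r1", "miR-1", "20"),
    ct_row("p1", "s1", "r1", "miR-2", "20"))))
  expect_true(all(global_mean_normalize(allsame)$ct == 0))

  # shift invariance: adding a constant to every ct in a sample
  t2 <- t; t2$ct <- t2$ct + 3.7
  expect_equal(global_mean_normalize(t2)$ct, d$ct)

  undet <- load_ct(write_ct_file(rbind(
    ct_row("p1", "s1", "r1", "miR-1", "Undetermined"),
    ct_row("p1", "s1", "r1", "miR-2", "Undetermined"))))
  expect_error(global_mean_normalize(undet), "s1")
})

dct_from <- function(rows) global_mean_normalize(load_ct(write_ct_file(rows)))

test_that("2^-ddCt fold changes and undetected handling", {
  # two miRNAs, one shifted by -3 cycles in the case: folds 8 and baseline
  rows <- rbind(ct_row("p1", "ref", "r1", "miR-1", "23"),
                ct_row("p1", "ref", "r1", "miR-2", "25"),
                ct_row("p2", "case", "r1", "miR-1", "20"),
                ct_row("p2", "case", "r1", "miR-2", "25"))
  # global mean shifts by planted effect: use two-mirna algebra explicitly
  fct <- fold_changes(dct_from(rows), "ref", "case")
  # dCt ref: miR-1 -1, miR-2 +1; case: miR-1 -2.5, miR-2 +2.5
  expect_equal(fct$fc_consensus[fct$mirna == "miR-1"], 2^1.5)
  expect_equal(fct$fc_consensus[fct$mirna == "miR-2"], 2^-1.5)

  # ddCt 0 -> fold 1; reference vs itself is always fold 1
  self <- fold_changes(dct_from(rbind(
    ct_row("p1", "ref", "r1", "miR-1", "20"),
    ct_row("p1", "ref", "r1", "miR-2", "24"))), "ref", "ref")
  expect_true(all(self$fc_consensus == 1))
  expect_error(fold_changes(dct_from(rows), "ref", "missing"), "missing")
})

test_that("undetected wells floor, cap, or drop fold changes", {
  rows <- rbind(ct_row("p1", "ref", "r1", "miR-1", "20"),
                ct_row("p1", "ref", "r1", "miR-2", "Undetermined"),
                ct_row("p1", "ref", "r1", "miR-3", "24"),
                ct_row("p1", "ref", "r1", "miR-4", "Undetermined"),
                ct_row("p2", "case", "r1", "miR-1", "Undetermined"),
                ct_row("p2", "case", "r1", "miR-2", "20"),
                ct_row("p2", "case", "r1", "miR-3", "24"),
                ct_row("p2", "case", "r1", "miR-4", "Undetermined"))
  fct <- suppressMessages(fold_changes(dct_from(rows), "ref", "case"))
  expect_equal(fct$fc_consensus[fct$mirna == "miR-1"], 0) # lost in case
  expect_equal(fct$reg_class[fct$mirna == "miR-1"], "suppressor")
  expect_equal(fct$fc_consensus[fct$mirna == "miR-2"], 2^12) # gained
  expect_equal(fct$reg_class[fct$mirna == "miR-2"], "oncomiR")
  expect_false("miR-4" %in% fct$mirna) # undetected everywhere: dropped
  expect_true(fct$dysregulated[fct$mirna == "miR-1"])
})

test_that("concordance across replicates gates dysregulation", {
  rows <- rbind(
    # miR-1: fold 4 in both replicates -> dysregulated oncomiR
    ct_row("p1", "ref", "r1", "miR-1", "22"), ct_row("p1", "ref", "r1", "miR-2", "22"),
    ct_row("p2", "ref", "r2", "miR-1", "22"), ct_row("p2", "ref", "r2", "miR-2", "22"),
    ct_row("p3", "case", "r1", "miR-1", "18"), ct_row("p3", "case", "r1", "miR-2", "26"),
    ct_row("p4", "case", "r2", "miR-1", "18"), ct_row("p4", "case", "r2", "miR-2", "26"))
  fct <- fold_changes(dct_from(rows), "ref", "case")
  expect_true(all(fct$dysregulated))
  rf <- attr(fct, "replicate_folds")
  expect_equal(unname(rf["miR-1", ]), c(16, 16)) # ddCt -4 after global mean

  # discordant replicates are not dysregulated
  rows2 <- rbind(
    ct_row("p1", "ref", "r1", "miR-1", "22"), ct_row("p1", "ref", "r1", "miR-2", "22"),
    ct_row("p2", "ref", "r2", "miR-1", "22"), ct_row("p2", "ref", "r2", "miR-2", "22"),
    ct_row("p3", "case", "r1", "miR-1", "20"), ct_row("p3", "case", "r1", "miR-2", "24"),
    ct_row("p4", "case", "r2", "miR-1", "22.6"), ct_row("p4", "case", "r2", "miR-2", "21.4"))
  fct2 <- fold_changes(dct_from(rows2), "ref", "case")
  expect_false(any(fct2$dysregulated))

  # dysregulated implies |log10 fold| >= log10(2) in every replicate
  rf2 <- attr(fct, "replicate_folds")
  for (m in fct$mirna[fct$dysregulated]) {
    f <- rf2[m, !is.na(rf2[m, ])]
    expect_true(all(abs(log10(pmax(f, 1e-300))) >= log10(2) - 1e-12))
  }
})

test_that("dysregulation report counts classes, extremes and bins", {
  empty <- fold_changes(dct_from(rbind(
    ct_row("p1", "ref", "r1", "miR-1", "20"),
    ct_row("p1", "ref", "r1", "miR-2", "22"))), "ref", "ref")
  rep0 <- dysregulation_report(empty)
  expect_equal(rep0$n_dysregulated, 0)
  expect_equal(rep0$n_extreme, 0)

  # folds 4 (dysreg onco), 0.1 (dysreg supp, extreme), 1.5 (not dysreg)
  fct <- structure(
    data.frame(mirna = c("a", "b", "c"), fc_consensus = c(4, 0.1, 1.5),
               log10_fc = log10(c(4, 0.1, 1.5)), n_replicates = 1,
               dysregulated = c(TRUE, TRUE, FALSE),
               reg_class = c("oncomiR", "suppressor", "oncomiR"),
               flag = "", stringsAsFactors = FALSE),
    class = c("fold_change_table", "data.frame"), fc_cap = 2^12)
  rep1 <- dysregulation_report(fct, extreme_threshold = 8)
  expect_equal(rep1$n_dysregulated, 2)
  expect_equal(rep1$n_oncomirs, 1)
  expect_equal(rep1$n_suppressors, 1)
  expect_equal(rep1$n_extreme, 1) # 0.1 <= 1/8
  expect_equal(sum(rep1$log10_fc_bins$count), 3)
})

test_that("end-to-end shift invariance: plate constants cancel", {
  spec <- synthetic_spec(n_nodes = 30, n_mirnas = 12, targets_per_mirna = 3,
                         ct_noise_sd = 0.1,
                         planted_log2fc = c("syn-miR-1" = 2, "syn-miR-2" = -2),
                         seed = 5)
  plates <- generate_plates(spec, paste0("syn-miR-", 1:12))
  run <- function(t) {
    fold_changes(global_mean_normalize(interplate_calibrate(t, "UniSp3")),
                 "P69", "M12")
  }
  f1 <- run(plates)
  shifted <- plates
  shifted$ct <- shifted$ct + ifelse(shifted$plate_id == shifted$plate_id[1], 2.5, 0)
  f2 <- run(shifted)
  expect_equal(f1$fc_consensus, f2$fc_consensus, tolerance = 1e-9)
})
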