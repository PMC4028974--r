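# qPCR Ct processing: plate tables -> interplate calibration -> global-mean
# normalization -> 2^-ddCt fold changes with a concordant 2-fold
# dysregulation filter and oncomiR / tumor-suppressor classification.

new_ct_table <- function(df, detection_limit = 37, type = "ct") {
  rownames(df) <- NULL
  structure(df, class = c("ct_table", "data.frame"),
            detection_limit = detection_limit, value_type = type)
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf(
    "ct_table (%s values): %d wells, %d plates, %d samples, %d miRNAs, %d undetected\n",
    attr(x, "value_type"), nrow(x), length(unique(x$plate_id)),
    length(unique(x$sample_id)), length(unique(x$mirna_id)), sum(is.na(x$ct))))
  invisible(x)
}

ct_key <- function(df) {
  paste(df$plate_id, df$sample_id, df$replicate_id, df$mirna_id, sep = "\t")
}

#' Load a qPCR Ct plate table
#'
#' Reads a TSV with plate, sample, replicate, miRNA and Ct columns
#' (names configurable). Undetected assays — empty cells, "Undetermined", or
#' Ct at or above the detection limit — are kept with the undetected marker
#' (stored as NA Ct). Detected Ct values must lie in (0, 50) cycles and the
#' (plate, sample, replicate, miRNA) key must be unique.
#'
#' @param path TSV file.
#' @param plate_col,sample_col,replicate_col,mirna_col,ct_col column names.
#' @param detection_limit Ct at or above which an assay is treated as
#'   undetected (cycles; default 37).
#' @return a `ct_table` data.frame with columns plate_id, sample_id,
#'   replicate_id, mirna_id, ct (NA = undetected).
#' @export
load_ct <- function(path, plate_col = "plate_id", sample_col = "sample_id",
                    replicate_col = "replicate_id", mirna_col = "mirna_id",
                    ct_col = "ct", detection_limit = 37) {
  df <- read_tsv_file(path, colClasses = "character")
  need <- c(plate_col, sample_col, replicate_col, mirna_col, ct_col)
  for (col in need) {
    if (!col %in% names(df)) {
      stop_format("missing required column '", col, "' in ", path)
    }
  }
  out <- data.frame(plate_id = trimws(df[[plate_col]]),
                    sample_id = trimws(df[[sample_col]]),
                    replicate_id = trimws(df[[replicate_col]]),
                    mirna_id = normalize_mirna_id(df[[mirna_col]]),
                    stringsAsFactors = FALSE)
  raw <- trimws(df[[ct_col]])
  ct <- suppressWarnings(as.numeric(raw))
  undet_token <- raw == "" | tolower(raw) %in% c("undetermined", "na")
  ct[undet_token] <- NA_real_
  ct[!is.na(ct) & ct >= detection_limit] <- NA_real_
  if (any(!is.na(ct) & (ct <= 0 | ct >= 50))) {
    stop_format("Ct values outside (0, 50) cycles in ", path)
  }
  out$ct <- ct
  dup <- duplicated(ct_key(out))
  if (any(dup)) {
    stop_format("duplicate well key: ", ct_key(out)[which(dup)[1]])
  }
  new_ct_table(out, detection_limit = detection_limit)
}

#' Write a Ct table as TSV
#'
#' Undetected wells are written as "Undetermined".
#'
#' @param t a `ct_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ct <- function(t, path) {
  df <- as.data.frame(t)
  df$ct <- ifelse(is.na(df$ct), "Undetermined", format(df$ct, trim = TRUE))
  write_tsv_file(df, path)
}

#' Correct interplate variability with a spike-in calibrator
#'
#' For each plate, the offset is the plate's mean calibrator Ct minus the
#' grand mean of the per-plate calibrator means; every detected Ct on the
#' plate is reduced by that offset, and the calibrator rows are then dropped
#' from downstream analysis.
#'
#' @param t a `ct_table`.
#' @param calibrator_id the spike-in assay id, present and detected on every
#'   plate.
#' @return the calibrated `ct_table` (calibrator rows removed); the estimated
#'   per-plate offsets are stored in `attr(, "plate_offsets")`.
#' @export
interplate_calibrate <- function(t, calibrator_id) {
  cal_id <- normalize_mirna_id(calibrator_id)
  plates <- unique(t$plate_id)
  is_cal <- t$mirna_id == cal_id
  plate_means <- vapply(plates, function(p) {
    v <- t$ct[is_cal & t$plate_id == p]
    if (length(v) == 0 || anyNA(v)) {
      stop_arg("calibrator '", calibrator_id,
               "' missing or undetected on plate '", p, "'")
    }
    mean(v)
  }, numeric(1))
  offsets <- plate_means - mean(plate_means)
  out <- as.data.frame(t)[!is_cal, , drop = FALSE]
  out$ct <- out$ct - offsets[out$plate_id]
  res <- new_ct_table(out, detection_limit = attr(t, "detection_limit"))
  attr(res, "plate_offsets") <- offsets
  res
}

#' Global-mean normalization of Ct values
#'
#' dCt(miRNA, sample, replicate) = Ct - mean Ct over all detected miRNAs in
#' that (sample, replicate). Undetected wells propagate as undetected. The
#' calibrator must have been removed first ([interplate_calibrate()]): spike-
#' ins never enter the global mean.
#'
#' @param t a calibrated `ct_table`.
#' @return a `ct_table` whose `ct` column holds dCt values
#'   (`attr(, "value_type") == "dct"`).
#' @export
global_mean_normalize <- function(t) {
  df <- as.data.frame(t)
  grp <- paste(df$sample_id, df$replicate_id, sep = "\t")
  for (g in unique(grp)) {
    sel <- grp == g
    v <- df$ct[sel]
    if (all(is.na(v))) {
      stop_arg("no detected miRNAs in sample/replicate '",
               gsub("\t", "/", g), "'")
    }
    df$ct[sel] <- v - mean(v, na.rm = TRUE)
  }
  new_ct_table(df, detection_limit = attr(t, "detection_limit"), type = "dct")
}

new_fold_change_table <- function(df, replicate_folds, fc_cap) {
  rownames(df) <- NULL
  structure(df, class = c("fold_change_table", "data.frame"),
            replicate_folds = replicate_folds, fc_cap = fc_cap)
}

#' 2^-ddCt fold changes between two conditions
#'
#' Per replicate, ddCt = dCt(case) - dCt(reference) and fold = 2^-ddCt, so a
#' fold > 1 means higher expression in the case condition. Undetected-well
#' handling: case undetected with detected reference gives the floored fold 0
#' (reported 0.00); reference undetected with detected case gives a fold
#' capped at `fc_cap` (flagged); a replicate undetected in both conditions
#' contributes no fold, and a miRNA undetected everywhere is dropped with a
#' log entry. The consensus fold is the geometric mean of the finite,
#' positive replicate folds; floored/capped replicates are excluded from the
#' geometric mean when they agree in direction with the remaining replicates,
#' and a direction conflict leaves the consensus undefined (flagged, never
#' dysregulated). A miRNA whose defined replicates are all floored (capped)
#' has consensus 0 (`fc_cap`).
#'
#' The dysregulation flag is concordant: every defined replicate fold must be
#' >= `min_fold`, or every one <= 1/`min_fold`. Regulation class is
#' "oncomiR" for consensus > 1, "suppressor" for consensus < 1 (including 0),
#' and "unclassified" for consensus 1 or undefined.
#'
#' @param dct a dCt `ct_table` from [global_mean_normalize()].
#' @param reference_sample,case_sample sample ids.
#' @param fc_cap cap for reference-undetected folds (default 2^12, flagged).
#' @param min_fold concordant dysregulation threshold (default 2).
#' @return a `fold_change_table` with columns mirna, fc_consensus, log10_fc,
#'   n_replicates, dysregulated, reg_class, flag; per-replicate folds are in
#'   `attr(, "replicate_folds")`.
#' @export
fold_changes <- function(dct, reference_sample, case_sample,
                         fc_cap = 2^12, min_fold = 2) {
  df <- as.data.frame(dct)
  for (s in c(reference_sample, case_sample)) {
    if (!s %in% df$sample_id) stop_arg("sample '", s, "' not in table")
  }
  ref <- df[df$sample_id == reference_sample, ]
  cas <- df[df$sample_id == case_sample, ]
  reps <- sort(unique(c(ref$replicate_id, cas$replicate_id)))
  mirnas <- sort(unique(c(ref$mirna_id, cas$mirna_id)))
  lookup <- function(d) {
    v <- matrix(NA_real_, length(mirnas), length(reps),
                dimnames = list(mirnas, reps))
    idx <- cbind(match(d$mirna_id, mirnas), match(d$replicate_id, reps))
    v[idx] <- d$ct
    v
  }
  vr <- lookup(ref)
  vc <- lookup(cas)
  folds <- matrix(NA_real_, length(mirnas), length(reps),
                  dimnames = list(mirnas, reps))
  both <- !is.na(vr) & !is.na(vc)
  folds[both] <- 2^(-(vc[both] - vr[both]))
  folds[is.na(vc) & !is.na(vr)] <- 0        # lost in case: floored
  folds[!is.na(vc) & is.na(vr)] <- fc_cap   # gained in case: capped
  folds[!is.na(folds) & folds > fc_cap] <- fc_cap

  rows <- lapply(seq_along(mirnas), function(i) {
    f <- folds[i, ]
    f <- f[!is.na(f)]
    if (length(f) == 0) return(NULL) # undetected everywhere: dropped
    finite <- f[f > 0 & f < fc_cap]
    extreme <- f[f == 0 | f == fc_cap]
    flag <- ""
    if (length(finite) > 0) {
      consensus <- exp(mean(log(finite)))
      if (length(extreme) > 0) {
        agree <- all((extreme == 0) == (consensus < 1))
        if (agree) {
          flag <- if (any(extreme == 0)) "floored_replicate" else "capped_replicate"
        } else {
          consensus <- NA_real_
          flag <- "replicate_direction_conflict"
        }
      }
    } else if (all(f == 0)) {
      consensus <- 0
      flag <- "floored"
    } else if (all(f == fc_cap)) {
      consensus <- fc_cap
      flag <- "capped"
    } else {
      consensus <- NA_real_
      flag <- "replicate_direction_conflict"
    }
    dys <- !is.na(consensus) &&
      (all(f >= min_fold) || all(f <= 1 / min_fold))
    cls <- if (is.na(consensus) || consensus == 1) "unclassified"
           else if (consensus > 1) "oncomiR" else "suppressor"
    data.frame(mirna = mirnas[i],
               fc_consensus = consensus,
               log10_fc = if (!is.na(consensus) && consensus > 0)
                 log10(consensus) else NA_real_,
               n_replicates = length(f),
               dysregulated = dys,
               reg_class = cls,
               flag = flag,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0) {
    log_msg("expression", dropped, " miRNAs undetected in every well dropped")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(mirna = character(), fc_consensus = numeric(),
                      log10_fc = numeric(), n_replicates = integer(),
                      dysregulated = logical(), reg_class = character(),
                      flag = character())
  }
  new_fold_change_table(out, replicate_folds = folds[out$mirna, , drop = FALSE],
                        fc_cap = fc_cap)
}

#' Summarize dysregulation across miRNAs
#'
#' Counts dysregulated miRNAs, their split into oncomiRs (higher in the case
#' condition) and suppressors (lost in the case condition), the extreme
#' subset with fold >= `extreme_threshold` or <= 1/`extreme_threshold`, and a
#' binned frequency distribution of log10 consensus folds.
#'
#' @param fct a `fold_change_table`.
#' @param extreme_threshold fold magnitude defining the extreme subset
#'   (default 8).
#' @param bin_width histogram bin width on the log10 fold scale (default
#'   0.25).
#' @return list with n_mirnas, n_dysregulated, n_oncomirs, n_suppressors,
#'   n_extreme, and `log10_fc_bins` (data.frame bin_mid, count).
#' @export
dysregulation_report <- function(fct, extreme_threshold = 8, bin_width = 0.25) {
  dys <- fct[fct$dysregulated, , drop = FALSE]
  fc <- dys$fc_consensus
  extreme <- sum(fc >= extreme_threshold | fc <= 1 / extreme_threshold,
                 na.rm = TRUE)
  lf <- fct$log10_fc[is.finite(fct$log10_fc)]
  if (length(lf) > 0) {
    lo <- floor(min(lf) / bin_width) * bin_width
    hi <- ceiling(max(lf) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    h <- hist(lf, breaks = breaks, plot = FALSE)
    bins <- data.frame(bin_mid = h$mids, count = h$counts)
  } else {
    bins <- data.frame(bin_mid = numeric(), count = integer())
  }
  list(n_mirnas = nrow(fct),
       n_dysregulated = nrow(dys),
       n_oncomirs = sum(dys$reg_class == "oncomiR"),
       n_suppressors = sum(dys$reg_class == "suppressor"),
       n_extreme = extreme,
       log10_fc_bins = bins)
}

#' Write a fold-change report as TSV
#'
#' Per-replicate folds, consensus, log10 fold, dysregulation flag and class.
#'
#' @param fct a `fold_change_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fold_changes <- function(fct, path) {
  rf <- attr(fct, "replicate_folds")
  df <- as.data.frame(fct)
  if (!is.null(rf) && nrow(df) > 0) {
    rep_df <- as.data.frame(rf[df$mirna, , drop = FALSE])
    names(rep_df) <- paste0("fc_", colnames(rf))
    df <- cbind(df[, "mirna", drop = FALSE], rep_df,
                df[, setdiff(names(df), "mirna"), drop = FALSE])
  }
  write_tsv_file(df, path)
}
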