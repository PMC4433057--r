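# Reliability and agreement analysis of an examination study: repetition
# means/SDs (repeatability), inter-rater ICC(3,k), Bland-Altman agreement,
# and validity flags against literature reference RoM ranges.
#
# Decision rules used throughout the reporting layer: ICC(3,k) >= 0.8 is an
# acceptable level of reliability; an absolute Bland-Altman mean difference
# below 5 degrees is an acceptable systematic difference.

#' Mean and SD of one repetition set
#'
#' Sample mean and sample SD (n-1 denominator) of the repeated values of one
#' subject x rater x examination cell.
#'
#' @param values repetition values, degrees (length >= 2).
#' @return list `mean`, `sd`.
#' @export
rep_mean_sd <- function(values) {
  if (length(values) < 2L)
    stop("at least 2 repetitions are required for a within-repetition SD")
  list(mean = mean(values), sd = stats::sd(values))
}

.sheet_value_col <- function(sheet) {
  vc <- intersect(c("measured_rom_deg", "rating_deg", "value"), names(sheet))
  if (!length(vc))
    stop("sheet must have a 'measured_rom_deg', 'rating_deg' or 'value' column")
  vc[1]
}

#' Repeatability table (mean within-repetition SD)
#'
#' The intra-rater repeatability summary: per examination angle family
#' (joint x nomenclature, sides pooled) and source, the mean over subjects,
#' raters and sides of the within-repetition SD of the repeated values.
#'
#' @param measurement_sheet long sheet with columns subject, rater,
#'   angle_id, rep and `measured_rom_deg`.
#' @param examiner_sheet same layout with `rating_deg`; optional.
#' @param catalog a `rom_catalog`, used to group angle ids into families.
#' @return data.frame: `joint`, `nomenclature`, `mode`,
#'   `mean_sd_measurements` and (if given) `mean_sd_examiners`, degrees.
#' @export
repeatability_table <- function(measurement_sheet, examiner_sheet = NULL,
                                catalog = load_catalog()) {
  per_angle_sd <- function(sheet) {
    vc <- .sheet_value_col(sheet)
    cells <- stats::aggregate(sheet[[vc]],
                              by = sheet[c("subject", "rater", "angle_id")],
                              FUN = stats::sd)
    names(cells)[4] <- "sd"
    cells
  }
  fam <- function(a) {
    e <- lookup_examination(catalog, a)
    paste(e$joint, e$nomenclature, sep = " | ")
  }
  m <- per_angle_sd(measurement_sheet)
  m$family <- vapply(m$angle_id, fam, "")
  out <- stats::aggregate(list(mean_sd_measurements = m$sd),
                          by = list(family = m$family), FUN = mean)
  if (!is.null(examiner_sheet)) {
    e <- per_angle_sd(examiner_sheet)
    e$family <- vapply(e$angle_id, fam, "")
    ee <- stats::aggregate(list(mean_sd_examiners = e$sd),
                           by = list(family = e$family), FUN = mean)
    out <- merge(out, ee, by = "family", all = TRUE)
  }
  parts <- strsplit(out$family, " | ", fixed = TRUE)
  out$joint <- vapply(parts, `[[`, "", 1L)
  out$nomenclature <- vapply(parts, `[[`, "", 2L)
  first_id <- vapply(out$family, function(f) {
    ids <- names(catalog$examinations)
    ids[vapply(ids, fam, "") == f][1]
  }, "")
  out$mode <- vapply(first_id, function(a)
    lookup_examination(catalog, a)$mode, "")
  out[order(out$mode == "passive", out$joint),
      c("joint", "nomenclature", "mode", "mean_sd_measurements",
        grep("mean_sd_examiners", names(out), value = TRUE))]
}

#' Subjects x raters rating table for one examination angle
#'
#' Builds the n x k matrix of per-subject repetition means that feeds the
#' ICC and Bland-Altman analyses. Subjects with any missing cell for this
#' angle are dropped row-wise and counted.
#'
#' @param sheet long sheet (subject, rater, angle_id, rep, value column).
#' @param angle_id the examination angle to tabulate.
#' @param source label, `"measurement"` or `"examiner"` (defaults from the
#'   value column found).
#' @return a `rom_rating_table`: `angle_id`, `source`, `values` (n x k),
#'   `subject_ids`, `rater_ids`, `n_dropped`.
#' @export
rating_table <- function(sheet, angle_id, source = NULL) {
  vc <- .sheet_value_col(sheet)
  if (is.null(source))
    source <- if (vc == "rating_deg") "examiner" else "measurement"
  rows <- sheet[sheet$angle_id == angle_id, , drop = FALSE]
  if (!nrow(rows)) stop("no sheet rows for angle '", angle_id, "'")
  cells <- stats::aggregate(rows[[vc]], by = rows[c("subject", "rater")],
                            FUN = mean)
  names(cells)[3] <- "value"
  raters <- sort(unique(cells$rater))
  subjects <- sort(unique(cells$subject))
  m <- matrix(NA_real_, length(subjects), length(raters),
              dimnames = list(subjects, raters))
  m[cbind(match(cells$subject, subjects), match(cells$rater, raters))] <-
    cells$value
  complete <- stats::complete.cases(m)
  dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("rating table needs at least 2 complete subjects and 2 raters")
  structure(list(angle_id = angle_id, source = source, values = m,
                 subject_ids = subjects[complete], rater_ids = raters,
                 n_dropped = dropped), class = "rom_rating_table")
}

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed model, average-measures consistency ICC: from the two-way
#' ANOVA mean squares of the n x k table (BMS between subjects, JMS between
#' raters, EMS residual), `ICC(3,k) = (BMS - EMS) / BMS`. Negative estimates
#' are reported as computed (display layers may floor at 0 with a flag).
#'
#' @param table a [rating_table()] or plain n x k numeric matrix.
#' @return a `rom_icc`: `icc_3k`, `bms`, `jms`, `ems`, `n`, `k`,
#'   `acceptable` (`icc_3k >= 0.8`), `undefined` (no between-subject
#'   variance), `angle_id`, `source`.
#' @export
icc_3k <- function(table) {
  m <- if (inherits(table, "rom_rating_table")) table$values else
    as.matrix(table)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2L, k >= 2L, !anyNA(m))
  grand <- mean(m)
  subj_means <- rowMeans(m); rater_means <- colMeans(m)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_resid <- ss_total - ss_subj - ss_rater
  bms <- ss_subj / (n - 1)
  jms <- ss_rater / (k - 1)
  ems <- ss_resid / ((n - 1) * (k - 1))
  undefined <- bms <= .Machine$double.eps * max(1, abs(ss_total))
  icc <- if (undefined) NaN else (bms - ems) / bms
  if (!undefined && icc < 0)
    warning("negative ICC(3,k) estimate (", round(icc, 3),
            ") for angle '", if (inherits(table, "rom_rating_table"))
              table$angle_id else "<matrix>", "'")
  structure(list(
    angle_id = if (inherits(table, "rom_rating_table")) table$angle_id else NA,
    source = if (inherits(table, "rom_rating_table")) table$source else NA,
    icc_3k = icc, bms = bms, jms = jms, ems = ems, n = n, k = k,
    acceptable = isTRUE(icc >= 0.8), undefined = undefined),
    class = "rom_icc")
}

#' Bland-Altman agreement of one rater pair
#'
#' Per-subject difference (first minus second) against per-subject mean,
#' with the mean difference MDiff and the 95% limits of agreement
#' `MDiff +/- 1.96 * SD(differences)`. `|MDiff| < 5` degrees counts as an
#' acceptable systematic difference (strict inequality).
#'
#' @param table a [rating_table()] (or n x k matrix with column names).
#' @param pair length-2 vector naming the two rater columns, first minus
#'   second.
#' @return a `rom_bland_altman`: `mdiff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `points` (subject, mean, diff), `mdiff_acceptable`, `rater_pair`.
#' @export
bland_altman <- function(table, pair) {
  m <- if (inherits(table, "rom_rating_table")) table$values else
    as.matrix(table)
  pair <- as.character(pair)
  if (!all(pair %in% colnames(m)))
    stop("rater pair (", paste(pair, collapse = ", "),
         ") not present in the table")
  a <- m[, pair[1]]; b <- m[, pair[2]]
  d <- a - b; av <- (a + b) / 2
  mdiff <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    angle_id = if (inherits(table, "rom_rating_table")) table$angle_id else NA,
    rater_pair = pair, mdiff = mdiff, sd_diff = sd_diff,
    loa_low = mdiff - 1.96 * sd_diff, loa_high = mdiff + 1.96 * sd_diff,
    points = data.frame(subject = rownames(m) %||% seq_len(nrow(m)),
                        mean = av, diff = d, row.names = NULL),
    mdiff_acceptable = abs(mdiff) < 5), class = "rom_bland_altman")
}

#' Bland-Altman agreement panel for one examination angle
#'
#' The 3 x 3 (for k = 3) plot panel layout: first each rater's examiner
#' rating versus the same rater's measurement, then every combination of
#' measurement results, then every combination of examiner ratings
#' (k + 2 * choose(k, 2) comparisons in that order).
#'
#' @param meas_table [rating_table()] of the measurements.
#' @param exam_table [rating_table()] of the examiner ratings (same subjects
#'   and raters).
#' @return list of `rom_bland_altman`, each tagged with a `comparison` field
#'   (`"examiner_vs_measurement"`, `"measurement_pair"`, `"examiner_pair"`).
#' @export
agreement_panel <- function(meas_table, exam_table) {
  stopifnot(inherits(meas_table, "rom_rating_table"),
            inherits(exam_table, "rom_rating_table"))
  if (!identical(dim(meas_table$values), dim(exam_table$values)) ||
      !identical(meas_table$subject_ids, exam_table$subject_ids))
    stop("measurement and examiner tables must cover identical subjects")
  k <- ncol(meas_table$values)
  raters <- meas_table$rater_ids
  out <- list()
  for (r in seq_len(k)) {  # examiner vs own measurement
    joint <- cbind(exam_table$values[, r], meas_table$values[, r])
    colnames(joint) <- c(paste0("Ex", raters[r]), paste0("Meas", raters[r]))
    rownames(joint) <- rownames(meas_table$values)
    ba <- bland_altman(joint, colnames(joint))
    ba$angle_id <- meas_table$angle_id
    ba$comparison <- "examiner_vs_measurement"
    out[[length(out) + 1L]] <- ba
  }
  pair_block <- function(tab, prefix, label) {
    m <- tab$values
    colnames(m) <- paste0(prefix, raters)
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      ba <- bland_altman(m, colnames(m)[c(i, j)])
      ba$angle_id <- tab$angle_id
      ba$comparison <- label
      out[[length(out) + 1L]] <<- ba
    }
  }
  pair_block(meas_table, "Meas", "measurement_pair")
  pair_block(exam_table, "Ex", "examiner_pair")
  out
}

#' Validity flags against reference RoM ranges
#'
#' Compares a cohort-mean RoM to the two literature references of the
#' catalog entry: the range of expectable RoM in healthy adults
#' (ref_range_1) and the minimum expectation of the screening methodology
#' (ref_range_2). Boundaries are inclusive ("within").
#'
#' @param means named vector `angle_id -> cohort mean RoM`, degrees.
#' @param catalog a `rom_catalog`.
#' @return data.frame `angle_id`, `mean_deg`, `flag_ref1`, `flag_ref2`
#'   (each `"below"`, `"within"` or `"above"`).
#' @export
validity_flags <- function(means, catalog = load_catalog()) {
  flag <- function(x, lo, hi) {
    if (x < lo) "below" else if (x > hi) "above" else "within"
  }
  out <- data.frame(angle_id = names(means), mean_deg = as.numeric(means),
                    flag_ref1 = NA_character_, flag_ref2 = NA_character_)
  for (i in seq_len(nrow(out))) {
    e <- lookup_examination(catalog, out$angle_id[i])
    out$flag_ref1[i] <- flag(out$mean_deg[i], e$ref_range_1[1],
                             e$ref_range_1[2])
    out$flag_ref2[i] <- flag(out$mean_deg[i], e$ref_range_2, e$ref_range_2)
  }
  out
}

#' @export
print.rom_icc <- function(x, ...) {
  cat("ICC(3,k) = ", formatC(x$icc_3k, digits = 3, format = "f"),
      " (BMS ", formatC(x$bms, digits = 2, format = "f"),
      ", EMS ", formatC(x$ems, digits = 2, format = "f"),
      ", n = ", x$n, ", k = ", x$k, ")",
      if (isTRUE(x$acceptable)) " [acceptable]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.rom_bland_altman <- function(x, ...) {
  cat("Bland-Altman ", paste(x$rater_pair, collapse = " - "),
      ": MDiff = ", formatC(x$mdiff, digits = 2, format = "f"),
      " deg, LOA [", formatC(x$loa_low, digits = 2, format = "f"), ", ",
      formatC(x$loa_high, digits = 2, format = "f"), "]\n", sep = "")
  invisible(x)
}
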