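#' Cohort simulation specification
#'
#' Default parameters regenerate the study conditions: 12 patients with
#' diplopia versus 18 without, total complex volumes log-normal with group
#' medians/IQRs from the published comparison table (1023.3 (875.7-1750.5)
#' vs 804.6 (755.1-923.4) mm^3), heights linked to volume through a cube-root
#' law, visual-field MD and duction-restriction frequencies from the baseline
#' table.  Group order everywhere: `(diplopia, control)`.
#'
#' The log-normal is parameterized so the *population* median equals the
#' group median and the quartile ratio matches the group IQR
#' (`sdlog = log(q3/q1) / (2 * qnorm(0.75))`); only two log-normal parameters
#' exist, so the individual quartiles are matched through their ratio.
#'
#' @param n_diplopia,n_control Group sizes.
#' @param volume_median_by_group Total-volume medians, mm^3.
#' @param volume_iqr_by_group List of two `c(q1, q3)` intervals, mm^3.
#' @param height_median_by_group Height medians, mm.
#' @param md_distribution_by_group List of two `c(location, scale)` pairs, dB.
#' @param restriction_probability_by_group Probability of >= 1 restricted
#'   duction per group.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(
    n_diplopia = 12L, n_control = 18L,
    volume_median_by_group = c(1023.3, 804.6),
    volume_iqr_by_group = list(c(875.7, 1750.5), c(755.1, 923.4)),
    height_median_by_group = c(5.3, 4.6),
    md_distribution_by_group = list(c(-6.9, 5.71), c(-12.17, 4.67)),
    restriction_probability_by_group = c(10 / 12, 6 / 18),
    seed = 1L) {
  if (n_diplopia < 1 || n_control < 1)
    .stop2("group sizes must be >= 1", class = "bq_input")
  for (iq in volume_iqr_by_group)
    if (iq[1] >= iq[2] || any(iq <= 0))
      .stop2("infeasible IQR: lower bound must be positive and below the upper",
             class = "bq_input")
  if (any(volume_median_by_group <= 0) || any(height_median_by_group <= 0))
    .stop2("medians must be positive", class = "bq_input")
  p <- restriction_probability_by_group
  if (any(p < 0) || any(p > 1))
    .stop2("restriction probabilities must lie in [0, 1]", class = "bq_input")
  structure(list(
    n_diplopia = as.integer(n_diplopia), n_control = as.integer(n_control),
    volume_median_by_group = volume_median_by_group,
    volume_iqr_by_group = volume_iqr_by_group,
    height_median_by_group = height_median_by_group,
    md_distribution_by_group = md_distribution_by_group,
    restriction_probability_by_group = p,
    seed = as.integer(seed)), class = "cohort_sim_spec")
}

# auxiliary per-group distributions not governed by the sim spec: demographic
# and pressure summaries from the baseline table, strand/extra-fluid rates
.cohort_aux <- list(
  age = list(c(66.5, 9.0), c(67.8, 7.4)),
  iop_pre = list(c(21.9, 7.3), c(20.4, 5.0)),
  iop_6wk = list(c(17.7, 8.1), c(15.5, 7.7)),
  iop_3mo = list(c(17.1, 5.3), c(16.8, 6.7)),
  iop_mri = list(c(13.4, 4.0), c(11.3, 2.3)),
  time_since_surgery = list(c(3.6, 1.4), c(5.3, 2.9)),
  p_od = c(4 / 12, 12 / 18),
  p_male = c(7 / 12, 10 / 18),
  p_free_plate = c(7 / 12, 8 / 18),
  p_strands = c(0.75, 0.88),
  p_extra_fluid = c(1 / 12, 8 / 18),
  inner_fraction = c(492.3 / (492.3 + 228.6), 304.9 / (304.9 + 234.8)),
  plate_volume = c(280, 15))

#' Simulate a per-patient cohort table
#'
#' Draws one row per patient with the full record schema used by
#' [compare_groups()]: group label, compartment volumes (total log-normal,
#' plate near-constant, remainder split between inner and outer bleb),
#' height via a cube-root link with log-normal noise, visual-field MD, IOP at
#' four timepoints, duction restriction, and categorical covariates.  The
#' merged flag is set for the largest complexes, mirroring the observation
#' that large blebs touch at the plate edges.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A data.frame, one row per patient, diplopia rows first.
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  z75 <- stats::qnorm(0.75)
  one_group <- function(g, n) {
    med <- spec$volume_median_by_group[g]
    iq <- spec$volume_iqr_by_group[[g]]
    sdlog <- log(iq[2] / iq[1]) / (2 * z75)
    total <- rlnorm(n, meanlog = log(med), sdlog = sdlog)
    plate <- pmin(rnorm(n, .cohort_aux$plate_volume[1],
                        .cohort_aux$plate_volume[2]),
                  0.45 * total)
    rest <- total - plate
    frac <- rbeta(n, .cohort_aux$inner_fraction[g] * 30,
                  (1 - .cohort_aux$inner_fraction[g]) * 30)
    inner <- rest * frac
    outer <- rest - inner
    h_med <- spec$height_median_by_group[g]
    height <- h_med * (total / med)^(1 / 3) * exp(rnorm(n, 0, 0.06))
    md <- spec$md_distribution_by_group[[g]]
    restricted <- rbinom(n, 1, spec$restriction_probability_by_group[g]) == 1
    restriction_total <- ifelse(
      restricted, pmax(10, 0.02 * total + rgamma(n, shape = 3, scale = 5)), 0)
    aux <- function(nm) rnorm(n, .cohort_aux[[nm]][[g]][1],
                              .cohort_aux[[nm]][[g]][2])
    data.frame(
      diplopia = g == 1L,
      eye = ifelse(runif(n) < .cohort_aux$p_od[g], "OD", "OS"),
      age = round(aux("age"), 1),
      sex = ifelse(runif(n) < .cohort_aux$p_male[g], "M", "F"),
      volume_inner = inner, volume_outer = outer, volume_plate = plate,
      volume_total = total, height = height,
      merged = total > 1300,
      large_bleb = classify_large_bleb(total),
      md_study = pmin(rnorm(n, md[1], md[2]), 2),
      md_fellow = pmin(rnorm(n, -3.2, 2.5), 2),
      iop_pre = aux("iop_pre"), iop_6wk = aux("iop_6wk"),
      iop_3mo = aux("iop_3mo"), iop_mri = aux("iop_mri"),
      restricted = restricted,
      restriction_total = restriction_total,
      strands_visible = runif(n) < .cohort_aux$p_strands[g],
      extra_fluid = runif(n) < .cohort_aux$p_extra_fluid[g],
      surgical_technique = ifelse(runif(n) < .cohort_aux$p_free_plate[g],
                                  "free", "sutured"),
      time_since_surgery = pmax(aux("time_since_surgery"), 0.5))
  }
  out <- rbind(one_group(1L, spec$n_diplopia), one_group(2L, spec$n_control))
  out <- cbind(id = sprintf("P%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Write a cohort table as CSV
#'
#' @param cohort Data frame from [simulate_cohort()] or [read_cohort()].
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a per-patient cohort table
#'
#' Reads CSV or XLSX (the deposited supplementary spreadsheet format; XLSX
#' needs the readxl package).  A column mapping translates foreign headers to
#' the canonical record fields, either as a named character vector
#' (`c(field = "source column")`) or as a path to a JSON file with the same
#' shape.  Rows violating basic invariants (negative volumes or heights,
#' unparseable group label) are rejected with row-level messages; the
#' remainder is returned, with rejected row numbers in `attr(, "rejected")`.
#'
#' @param path CSV or XLSX file.
#' @param mapping Optional column mapping (named vector or JSON path).
#' @return Validated data.frame of patient records.
#' @export
read_cohort <- function(path, mapping = NULL) {
  if (!file.exists(path))
    .stop2("file not found: %s", path, class = "bq_input")
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      .stop2("reading %s needs the readxl package", ext, class = "bq_input")
    as.data.frame(readxl::read_excel(path))
  } else read.csv(path, stringsAsFactors = FALSE)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping))
    mapping <- unlist(jsonlite::read_json(mapping, simplifyVector = TRUE))
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(tab))
    if (length(missing_src))
      .stop2("mapping refers to absent column(s): %s",
             paste(missing_src, collapse = ", "), class = "bq_schema")
    names(tab)[match(unname(mapping), names(tab))] <- names(mapping)
  }
  mandatory <- c("diplopia", "volume_total")
  absent <- setdiff(mandatory, names(tab))
  if (length(absent))
    .stop2("mandatory column(s) missing: %s", paste(absent, collapse = ", "),
           class = "bq_schema")
  if (!is.logical(tab$diplopia)) {
    v <- tolower(as.character(tab$diplopia))
    tab$diplopia <- v %in% c("true", "1", "yes", "y", "diplopia")
    tab$diplopia[!(v %in% c("true", "1", "yes", "y", "diplopia",
                            "false", "0", "no", "n", "control"))] <- NA
  }
  bad <- which(is.na(tab$diplopia))
  for (col in intersect(c("volume_inner", "volume_outer", "volume_plate",
                          "volume_total", "height"), names(tab))) {
    neg <- which(is.finite(tab[[col]]) & tab[[col]] < 0)
    if (length(neg)) {
      message(sprintf("rejecting row(s) %s: negative %s",
                      paste(neg, collapse = ", "), col))
      bad <- union(bad, neg)
    }
  }
  if (length(bad)) {
    out <- tab[-bad, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rejected") <- sort(bad)
    out
  } else tab
}

# variable -> test mapping used by the study
.comparison_plan <- function() {
  rbind(
    data.frame(variable = c("age", "iop_pre", "iop_6wk", "iop_3mo", "iop_mri",
                            "time_since_surgery"),
               test = "t"),
    data.frame(variable = c("sex", "eye", "surgical_technique", "restricted",
                            "strands_visible", "extra_fluid", "large_bleb"),
               test = "fisher"),
    data.frame(variable = c("md_study", "md_fellow", "volume_total",
                            "volume_inner", "volume_outer", "height"),
               test = "mann_whitney"))
}

.fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), sd(x))
.fmt_med_iqr <- function(x) {
  m <- median_iqr(x)
  sprintf("%.1f (%.1f–%.1f)", m$median, m$q1, m$q3)
}
.fmt_n_pct <- function(x) sprintf("%d (%.0f%%)", sum(x), 100 * mean(x))

#' Group comparisons and correlations for a cohort
#'
#' Regenerates the study's two summary panels from a per-patient table:
#' per-group summaries with the published test mapping (unpaired t for age,
#' IOP and follow-up time; Fisher exact for counts; Mann-Whitney for
#' visual field, volumes and height), plus the reported Spearman correlations
#' (diplopia against total volume and height; total motility restriction
#' against total volume; volume and height against each IOP timepoint).
#' No multiplicity adjustment is applied, matching the original analysis
#' (each variable tested separately at alpha = 0.05).  Output is invariant to
#' the row order of the cohort.
#'
#' @param cohort Data frame with a logical `diplopia` column; variables
#'   absent from the table are skipped with a warning.
#' @return List of two data.frames, `comparisons` (variable, per-group
#'   summary, test, statistic, p) and `correlations` (x, y, n, rho, p), class
#'   `bleb_group_comparison`.
#' @export
compare_groups <- function(cohort) {
  if (!"diplopia" %in% names(cohort) || !is.logical(cohort$diplopia))
    .stop2("cohort needs a logical 'diplopia' column", class = "bq_schema")
  cohort <- cohort[order(!cohort$diplopia), , drop = FALSE]  # row-order invariance
  g1 <- cohort[cohort$diplopia, , drop = FALSE]
  g2 <- cohort[!cohort$diplopia, , drop = FALSE]

  rows <- list()
  plan <- .comparison_plan()
  for (i in seq_len(nrow(plan))) {
    v <- plan$variable[i]
    if (!v %in% names(cohort)) {
      warning(sprintf("variable '%s' absent from cohort; skipped", v))
      next
    }
    a <- g1[[v]]; b <- g2[[v]]
    res <- switch(plan$test[i],
      t = {
        r <- unpaired_t(a, b)
        list(s1 = .fmt_mean_sd(a), s2 = .fmt_mean_sd(b),
             stat = r$t, p = r$p)
      },
      fisher = {
        av <- if (is.logical(a)) a else a == sort(unique(c(a, b)))[1]
        bv <- if (is.logical(b)) b else b == sort(unique(c(a, b)))[1]
        r <- fisher_exact(matrix(c(sum(av), sum(!av), sum(bv), sum(!bv)), 2))
        list(s1 = .fmt_n_pct(av), s2 = .fmt_n_pct(bv),
             stat = r$odds_ratio, p = r$p)
      },
      mann_whitney = {
        r <- mann_whitney(a, b)
        list(s1 = .fmt_med_iqr(a), s2 = .fmt_med_iqr(b),
             stat = r$U, p = r$p)
      })
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = plan$test[i],
      diplopia = res$s1, control = res$s2,
      statistic = res$stat, p = res$p)
  }
  comparisons <- do.call(rbind, rows)

  cor_pairs <- list(
    c("diplopia", "volume_total"), c("diplopia", "height"),
    c("restriction_total", "volume_total"),
    c("volume_total", "iop_pre"), c("volume_total", "iop_6wk"),
    c("volume_total", "iop_3mo"), c("volume_total", "iop_mri"),
    c("height", "iop_pre"), c("height", "iop_6wk"),
    c("height", "iop_3mo"), c("height", "iop_mri"))
  crows <- list()
  for (pr in cor_pairs) {
    if (!all(pr %in% names(cohort))) next
    x <- cohort[[pr[1]]]
    y <- cohort[[pr[2]]]
    if (is.logical(x)) x <- as.numeric(x)   # diplopia coded 1, control 0
    r <- tryCatch(spearman_cor(x, y), error = function(e) NULL)
    if (is.null(r)) next
    crows[[length(crows) + 1L]] <- data.frame(
      x = pr[1], y = pr[2], n = r$n, rho = r$rho, p = r$p)
  }
  structure(list(comparisons = comparisons,
                 correlations = do.call(rbind, crows)),
            class = "bleb_group_comparison")
}

#' @export
print.bleb_group_comparison <- function(x, ...) {
  cat("Group comparisons (diplopia vs control):\n")
  print(x$comparisons, row.names = FALSE, digits = 3)
  if (!is.null(x$correlations)) {
    cat("\nSpearman correlations:\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
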