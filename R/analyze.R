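#' Analyze one recording end to end
#'
#' Reads a recording (EDF or delimited text), extracts the full qEEG
#' feature set with [subjectFeatures()], compares it against the bundled
#' normative equations, and writes the results — a long-format feature CSV
#' (`subject, feature, value`), a per-subject JSON, a deviation report, and
#' the exact configuration used — into `outDir`.
#'
#' @param input path to a recording, or a [MonopolarRecording-class].
#' @param age subject age in years.
#' @param config a [qeegConfig()].
#' @param outDir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param fs sampling rate for text inputs without an embedded rate.
#' @param subject subject identifier used in the output files.
#' @return The [SubjectFeatures-class], invisibly when writing.
#' @export
qeegAnalyze <- function(input, age, config = qeegConfig(), outDir = NULL,
                        fs = NULL, subject = "subject1") {
  rec <- if (is(input, "MonopolarRecording")) input
         else readRecording(input, fs = fs, age = age)
  feats <- subjectFeatures(rec, age = age, config = config)
  if (is.null(outDir)) return(feats)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fv <- featureVector(feats)
  write.csv(data.frame(subject = subject, feature = names(fv),
                       value = unname(fv)),
            file.path(outDir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(subject = subject, age = age, features = as.list(fv)),
    file.path(outDir, "features.json"), auto_unbox = TRUE, digits = NA)
  write.csv(deviationReport(feats),
            file.path(outDir, "deviation_report.csv"), row.names = FALSE)
  writeQeegConfig(config, file.path(outDir, "config.yaml"))
  invisible(feats)
}

# group means +/- SEM of one feature column within a data.frame split
.meanSem <- function(x) c(mean = mean(x), sem = sd(x) / sqrt(length(x)))

#' Cohort-level normative analysis
#'
#' Runs [subjectFeatures()] over a cohort of recordings and produces the
#' normative summaries: whole-cohort regional band means with paired
#' left/right comparisons (via [pairedCompare()]), per-age-group means with
#' band-structure orderings, freshly fitted normative age regressions
#' (cubic for PDR frequency and spectral entropy, offset-exponential for
#' posterior amplitude), and a stats report. All tables are written to
#' `outDir` along with the configuration.
#'
#' @param inputs either a list of [MonopolarRecording-class] objects or a
#'   character vector of file paths.
#' @param ages numeric vector of subject ages (required for file inputs
#'   without embedded age).
#' @param config a [qeegConfig()].
#' @param outDir output directory; `NULL` to skip writing.
#' @param fs sampling rate for text inputs.
#' @return List with `features` (list of [SubjectFeatures-class]), `table`
#'   (feature data.frame), `cohortMeans`, `groupMeans`, `orderings`,
#'   `comparisons`, and `equations`.
#' @export
qeegCohort <- function(inputs, ages = NULL, config = qeegConfig(),
                       outDir = NULL, fs = NULL) {
  if (length(inputs) < 5L) stop("cohort analysis needs at least 5 subjects")
  recs <- lapply(inputs, function(x)
    if (is(x, "MonopolarRecording")) x else readRecording(x, fs = fs))
  if (is.null(ages)) ages <- vapply(recs, subjectAge, 0)
  if (any(!is.finite(ages))) stop("ages missing for some subjects")
  rates <- vapply(recs, samplingRate, 0)
  if (length(unique(rates)) != 1L)
    stop("heterogeneous sampling rates across the cohort: ",
         paste(unique(rates), collapse = ", "))
  features <- mapply(function(r, a) subjectFeatures(r, age = a, config = config),
                     recs, ages, SIMPLIFY = FALSE)
  tab <- featureTable(features)
  groups <- assignAgeGroup(tab$age)
  bands <- names(config$bands)
  lobes <- c("F", "PO", "T")

  cell <- function(rows, region, band)
    tab[rows, paste("logPS", region, band, sep = ".")]

  # whole-cohort regional means + paired symmetric-lobe comparisons
  cohortMeans <- do.call(rbind, lapply(lobes, function(lb)
    do.call(rbind, lapply(bands, function(b) {
      l <- cell(TRUE, paste0(lb, "_left"), b)
      r <- cell(TRUE, paste0(lb, "_right"), b)
      cmp <- pairedCompare(l, r)
      data.frame(lobe = lb, band = b,
                 mean_left = mean(l), sem_left = sd(l) / sqrt(length(l)),
                 mean_right = mean(r), sem_right = sd(r) / sqrt(length(r)),
                 p = cmp$p.value, test = cmp$test)
    }))))

  # per-age-group means and structure orderings
  groupMeans <- do.call(rbind, lapply(levels(groups), function(g) {
    rows <- groups == g
    if (!any(rows)) return(NULL)
    do.call(rbind, lapply(lobes, function(lb)
      do.call(rbind, lapply(c("left", "right"), function(h)
        do.call(rbind, lapply(bands, function(b)
          data.frame(lobe = lb, age_group = g, hemisphere = h, band = b,
                     n = sum(rows),
                     mean = mean(cell(rows, paste(lb, h, sep = "_"), b)))))))))
  }))
  orderings <- do.call(rbind, lapply(unique(groupMeans$age_group), function(g)
    do.call(rbind, lapply(lobes, function(lb)
      do.call(rbind, lapply(c("left", "right"), function(h) {
        sel <- groupMeans[groupMeans$age_group == g & groupMeans$lobe == lb &
                          groupMeans$hemisphere == h, ]
        m <- setNames(sel$mean, sel$band)
        data.frame(lobe = lb, age_group = g, hemisphere = h,
                   structure = paste(structureOrdering(m), collapse = ","))
      }))))))

  # fresh normative fits from this cohort
  eqFeatures <- c("pdr.freq.left", "pdr.freq.right",
                  paste0("sse.", c("F", "PO", "T"), "_left"),
                  paste0("sse.", c("F", "PO", "T"), "_right"))
  equations <- lapply(eqFeatures, function(f)
    fitNormative(tab$age, tab[[f]], degree = 3L, feature = f))
  ampEqs <- lapply(c("pdr.amp.left", "pdr.amp.right"), function(f)
    tryCatch(fitNormative(tab$age, tab[[f]], kind = "exp_decay", feature = f),
             error = function(e) NULL))
  equations <- c(equations, ampEqs[!vapply(ampEqs, is.null, TRUE)])
  names(equations) <- vapply(equations, function(e) e@feature, "")

  out <- list(features = features, table = tab, cohortMeans = cohortMeans,
              groupMeans = groupMeans, orderings = orderings,
              comparisons = cohortMeans[, c("lobe", "band", "p", "test")],
              equations = equations)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(outDir, "feature_table.csv"), row.names = FALSE)
    write.csv(cohortMeans, file.path(outDir, "cohort_means.csv"),
              row.names = FALSE)
    write.csv(groupMeans, file.path(outDir, "group_means.csv"),
              row.names = FALSE)
    write.csv(orderings, file.path(outDir, "structure_orderings.csv"),
              row.names = FALSE)
    jsonlite::write_json(lapply(equations, function(e)
      list(feature = e@feature, kind = e@kind,
           coefficients = e@coefficients, r = e@r, n = e@n,
           age_range = e@ageRange)),
      file.path(outDir, "normative_fits.json"), auto_unbox = TRUE,
      digits = NA)
    writeQeegConfig(config, file.path(outDir, "config.yaml"))
  }
  out
}
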