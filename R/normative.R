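#' Group per-channel features by lobe and hemisphere
#'
#' Averages channel-level values (logPS band areas, spectral entropy, ...)
#' over each region's channel slots: the arithmetic mean of the three lobe
#' channels, and of the nine hemisphere slots in which the posterior
#' temporal-occipital channel is counted twice (`hemispherePolicy =
#' "unique"` averages the 8 distinct channels instead).
#'
#' @param values named numeric vector (per channel) or channel x k matrix.
#' @param grouping `"lobes"`, `"hemispheres"`, or `"all"`.
#' @param hemispherePolicy `"slots"` (default) or `"unique"`.
#' @return region vector or region x k matrix of means.
#' @export
groupFeatures <- function(values, grouping = c("all", "lobes", "hemispheres"),
                          hemispherePolicy = c("slots", "unique")) {
  grouping <- match.arg(grouping)
  hemispherePolicy <- match.arg(hemispherePolicy)
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, ncol = 1L, dimnames = list(names(values), NULL))
       else as.matrix(values)
  regions <- lobeGrouping(grouping)
  out <- matrix(NA_real_, nrow = length(regions), ncol = ncol(m),
                dimnames = list(names(regions), colnames(m)))
  for (r in names(regions)) {
    ch <- regions[[r]]
    if (startsWith(r, "H_") && hemispherePolicy == "unique") ch <- unique(ch)
    missing <- setdiff(unique(ch), rownames(m))
    if (length(missing))
      stop("missing channel(s) for region ", r, ": ",
           paste(missing, collapse = ", "))
    out[r, ] <- colMeans(m[ch, , drop = FALSE])
  }
  if (vec) setNames(out[, 1L], rownames(out)) else out
}

#' Assign normative age group
#'
#' Partition of the age axis used by the normative tables: ages below 20 map
#' to `"<20"`, the closed interval [20, 50] to `"20-50"`, and ages above 50
#' to `">50"`. A warning is issued outside the 10-74 y range over which the
#' normative data were collected.
#'
#' @param age numeric vector of ages in years.
#' @return Factor with levels `"<20"`, `"20-50"`, `">50"`.
#' @export
assignAgeGroup <- function(age) {
  if (any(!is.finite(age)) || any(age < 0))
    stop("ages must be non-negative and finite")
  if (any(age < 10 | age > 74))
    warning("age(s) outside the 10-74 y normative range")
  grp <- ifelse(age < 20, "<20", ifelse(age <= 50, "20-50", ">50"))
  factor(grp, levels = c("<20", "20-50", ">50"))
}

#' Band-structure ordering
#'
#' Ranks the four band values of a region (logPS means, or the four band
#' coherences) from highest to lowest. Exact ties are reported jointly,
#' labelled `"a/b"` in the order the tied bands appear in the input.
#'
#' @param means named numeric vector of four band values.
#' @param tol values closer than this are treated as tied (default 0: exact
#'   equality only).
#' @return Character vector of ranked labels, tied labels joined by `"/"`.
#' @examples
#' structureOrdering(c(alpha = 1.57, beta = 1.13, delta = 1.00, theta = 0.87))
#' @export
structureOrdering <- function(means, tol = 0) {
  stopifnot(!is.null(names(means)), all(is.finite(means)))
  ord <- order(-means, seq_along(means))
  sorted <- means[ord]
  groups <- cumsum(c(TRUE, diff(sorted) < -tol))
  as.character(tapply(names(sorted), groups, paste, collapse = "/"))
}

#' Evaluate a normative age-regression equation
#'
#' Polynomials are evaluated as `sum(coef_i * age^i)`; the exponential kind
#' as a decaying `a + b * exp(-c * age)`, whose large-age asymptote is its
#' offset `a`.
#'
#' @param eq a [NormativeEquation-class].
#' @param age numeric vector of ages in years.
#' @param warn warn when `age` lies outside the equation's validity range.
#' @return Predicted feature values.
#' @export
evaluateNormative <- function(eq, age, warn = TRUE) {
  stopifnot(is(eq, "NormativeEquation"))
  if (warn && any(age < eq@ageRange[1L] | age > eq@ageRange[2L]))
    warning(sprintf("age outside the equation's validity range %g-%g y",
                    eq@ageRange[1L], eq@ageRange[2L]))
  co <- eq@coefficients
  switch(eq@kind,
    polynomial = {
      powers <- outer(age, seq_along(co) - 1, `^`)
      drop(powers %*% co)
    },
    exp_decay = co[1L] + co[2L] * exp(-co[3L] * age),
    stop("unknown equation kind: ", eq@kind))
}

#' Fit a normative age-regression from a cohort
#'
#' Least-squares fit of a feature against age: a raw polynomial of the given
#' degree (default quadratic, the standard choice for these normative
#' curves), or an offset-exponential `a + b * exp(-c * age)` fitted by
#' Levenberg-Marquardt. The fit correlation `r = cor(observed, fitted)` and
#' its one-tailed significance via [correlationTTest()] are attached.
#'
#' @param age ages in years, or a list of [SubjectFeatures-class] (then
#'   `values` is the feature name, see [featureVector()]).
#' @param values feature values (numeric), or the feature name when `age` is
#'   a cohort list.
#' @param degree polynomial degree (0-3).
#' @param kind `"polynomial"` or `"exp_decay"`.
#' @param feature label stored in the returned equation.
#' @return A [NormativeEquation-class] with attribute `"p"` (one-tailed
#'   significance of r).
#' @export
fitNormative <- function(age, values, degree = 2L,
                         kind = c("polynomial", "exp_decay"),
                         feature = "feature") {
  kind <- match.arg(kind)
  if (is.list(age) && !is.numeric(age)) {
    cohort <- age
    stopifnot(is.character(values), length(values) == 1L)
    feature <- values
    tab <- featureTable(cohort)
    if (!feature %in% colnames(tab))
      stop("unknown feature: ", feature)
    values <- tab[[feature]]
    age <- tab$age
  }
  stopifnot(length(age) == length(values))
  n <- length(age)
  if (kind == "polynomial") {
    if (n < degree + 2) stop("need at least degree + 2 subjects")
    if (degree > 0 && length(unique(age)) <= degree)
      stop("design is rank-deficient: too few distinct ages")
    co <- if (degree == 0L) {
      fit <- NULL
      mean(values)
    } else {
      X <- outer(age, 0:degree, `^`)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) stop("design is rank-deficient")
      drop(qr.coef(qrX, values))
    }
    fitted <- drop(outer(age, seq_along(co) - 1, `^`) %*% co)
  } else {
    if (n < 5) stop("need at least 5 subjects for the exponential fit")
    start <- list(a = min(values), b = max(values) - min(values), c = 0.05)
    fit <- minpack.lm::nlsLM(values ~ a + b * exp(-c * age), start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- unname(coef(fit))
    fitted <- predict(fit)
  }
  r <- if (sd(fitted) < 1e-12 || sd(values) < 1e-12) 0 else cor(values, fitted)
  eq <- new("NormativeEquation", feature = feature, kind = kind,
            coefficients = unname(co), r = r, n = as.numeric(n),
            ageRange = range(age))
  attr(eq, "p") <- if (abs(r) < 1) correlationTTest(r, n)$p.value else 0
  eq
}

#' Bundled normative equations
#'
#' Loads the machine-readable bundle of normative age-regression equations
#' shipped with the package: the posterior dominant rhythm frequency cubic,
#' the left/right posterior amplitude offset-exponentials (decaying form),
#' and the six regional spectral-entropy cubics, each with its fit
#' correlation, cohort size, and validity age range.
#'
#' @param path path to a bundle JSON; default the installed bundle.
#' @return Named list of [NormativeEquation-class] objects.
#' @export
normativeBundle <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "normative_equations.json",
                        package = "qeegnorm", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  eqs <- lapply(raw$equations, function(e)
    new("NormativeEquation", feature = e$feature, kind = e$kind,
        coefficients = as.numeric(unlist(e$coefficients)),
        r = as.numeric(e$r %||% NA_real_), n = as.numeric(e$n %||% NA_real_),
        ageRange = as.numeric(unlist(e$age_range))))
  names(eqs) <- vapply(raw$equations, `[[`, "", "feature")
  eqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normative group-mean reference tables
#'
#' Reference tables of the normative cohort behind the bundled equations
#' (N = 37; age groups <20 / 20-50 / >50 with N = 7 / 25 / 5):
#' `logPSGroupMeans()` gives the per-age-group regional logPS means and
#' SEMs, `logPSCohortMeans()` the whole-cohort means, and
#' `coherenceGroupMeans()` the per-age-group regional band coherences.
#'
#' @return A data.frame.
#' @name normative-tables
NULL

.extdataTable <- function(file) {
  path <- system.file("extdata", file, package = "qeegnorm", mustWork = TRUE)
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' @rdname normative-tables
#' @export
logPSGroupMeans <- function() .extdataTable("logps_group_means.csv")

#' @rdname normative-tables
#' @export
logPSCohortMeans <- function() .extdataTable("logps_cohort_means.csv")

#' @rdname normative-tables
#' @export
coherenceGroupMeans <- function() .extdataTable("coherence_group_means.csv")

#' Age-group sizes of the normative cohort
#' @return Named numeric vector, subjects per age group.
#' @export
normativeGroupSizes <- function() c("<20" = 7, "20-50" = 25, ">50" = 5)

#' Deviation report against the normative equations
#'
#' Compares a subject's features with the bundled (or user-fitted) normative
#' equations at the subject's age. When a reference cohort is supplied, the
#' deviation is also expressed in residual standard-deviation units of that
#' cohort's fit.
#'
#' @param features a [SubjectFeatures-class].
#' @param bundle named list of [NormativeEquation-class] (default the
#'   shipped bundle).
#' @param cohort optional list of [SubjectFeatures-class] used to estimate
#'   residual SDs.
#' @return data.frame with columns feature, observed, predicted, deviation,
#'   and (if `cohort` given) z.
#' @export
deviationReport <- function(features, bundle = normativeBundle(),
                            cohort = NULL) {
  stopifnot(is(features, "SubjectFeatures"))
  fv <- featureVector(features)
  common <- intersect(names(bundle), names(fv))
  if (!length(common)) stop("no bundle equation matches the feature names")
  age <- features@age
  pred <- vapply(bundle[common], evaluateNormative, 0, age = age, warn = FALSE)
  out <- data.frame(feature = common, observed = unname(fv[common]),
                    predicted = unname(pred),
                    deviation = unname(fv[common] - pred),
                    stringsAsFactors = FALSE)
  if (!is.null(cohort)) {
    tab <- featureTable(cohort)
    out$z <- NA_real_
    for (i in seq_along(common)) {
      f <- common[i]
      if (!f %in% colnames(tab)) next
      resid <- tab[[f]] - evaluateNormative(bundle[[f]], tab$age, warn = FALSE)
      s <- sd(resid)
      if (is.finite(s) && s > 0) out$z[i] <- out$deviation[i] / s
    }
  }
  out
}
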