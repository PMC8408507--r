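#' Fit the control-population covariate regression per region
#'
#' For every region, regresses raw volume on age, sex, total intracranial
#' volume and scanner field strength by ordinary least squares using
#' noncarrier controls only (carriers are excluded even when their volumes
#' look normal). The residual SD uses the unbiased n - p denominator.
#' Covariates that are constant in the fitting sample (e.g. a single field
#' strength) are dropped with a warning rather than producing a singular
#' design.
#'
#' @param cohort cohort table (see [generate_cohort()] / [read_cohort()]).
#' @param regions region columns to fit; defaults to the cohort's
#'   `regions` attribute.
#' @return object of class `control_model`: per-region coefficient vectors
#'   (`(Intercept)`, `age`, `sex_male`, `tiv`, `field_3t`), per-region
#'   residual SD `sigma`, the covariates retained, and the fitting n.
#' @export
fit_control_model <- function(cohort, regions = NULL) {
  regions <- regions %||% attr(cohort, "regions")
  if (is.null(regions)) stop("no region columns identified; pass `regions`")
  ctl <- cohort[cohort$group == "noncarrier", , drop = FALSE]
  X <- control_design(ctl)
  if (anyNA(X)) stop("missing covariates in control records")
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                        function(v) length(unique(v)) > 1L))
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    warning("dropping constant covariate(s) in control fit: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (nrow(X) < p + 2L) stop("need at least ", p + 2L, " controls")
  qx <- qr(X)
  if (qx$rank < p) stop("singular control design after covariate screening")
  coefs <- list()
  sig <- numeric(length(regions))
  full_names <- c("(Intercept)", "age", "sex_male", "tiv", "field_3t")
  for (i in seq_along(regions)) {
    r <- regions[i]
    if (is.null(ctl[[r]])) stop("region column missing from cohort: ", r)
    beta <- qr.coef(qx, ctl[[r]])
    res <- ctl[[r]] - drop(X %*% beta)
    sig[i] <- sqrt(sum(res^2) / (nrow(X) - p))
    if (sig[i] <= 0) stop("zero residual SD for region ", r)
    full <- stats::setNames(rep(0, length(full_names)), full_names)
    full[colnames(X)] <- beta
    coefs[[r]] <- full
  }
  structure(list(coefficients = coefs,
                 sigma = stats::setNames(sig, regions),
                 covariates = setdiff(colnames(X), "(Intercept)"),
                 dropped = dropped, n = nrow(X), source = "fitted"),
            class = "control_model")
}

# Design matrix for the covariate regression; sex and field strength are
# two-level 0/1 indicators (the coding cancels in prediction).
control_design <- function(df) {
  cbind("(Intercept)" = 1,
        age = df$age,
        sex_male = as.numeric(df$sex == "male"),
        tiv = df$tiv,
        field_3t = as.numeric(df$field_strength == 3))
}

#' @export
print.control_model <- function(x, ...) {
  cat("control covariate model (", x$source, "): ",
      length(x$coefficients), " regions, covariates: ",
      paste(x$covariates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sign-flipped covariate-corrected z-scores
#'
#' Propagates a fitted control model to any records and returns
#' `z = -(observed - predicted) / residual SD` per region, so that z-scores
#' are positive and increase with atrophy severity. The transformation is
#' applied identically to controls and carriers; on the fitting controls
#' the columns have mean 0 and (under the fitting n - p convention) SD 1.
#'
#' @param cohort cohort table carrying all model covariates and every
#'   modeled region column.
#' @param model a `control_model` from [fit_control_model()] or
#'   [true_control_model()].
#' @param regions regions to score (default: every region in the model
#'   that is present in the cohort must be exactly the model's region set;
#'   a region present in the cohort's region attribute but absent from the
#'   model is an error).
#' @return object of class `zscore_matrix`: numeric matrix `z`
#'   (subject-visits x regions) plus `meta` (all metadata columns).
#' @export
zscore <- function(cohort, model, regions = NULL) {
  stopifnot(inherits(model, "control_model"))
  regions <- regions %||% attr(cohort, "regions") %||%
    names(model$coefficients)
  extra <- setdiff(regions, names(model$coefficients))
  if (length(extra)) {
    stop("region(s) present in records but absent from model: ",
         paste(extra, collapse = ", "))
  }
  X <- control_design(cohort)
  if (anyNA(X)) stop("missing covariates in records")
  z <- matrix(NA_real_, nrow(cohort), length(regions),
              dimnames = list(NULL, regions))
  for (r in regions) {
    if (is.null(cohort[[r]])) stop("region column missing from records: ", r)
    beta <- model$coefficients[[r]]
    pred <- drop(X %*% beta[colnames(X)])
    z[, r] <- -(cohort[[r]] - pred) / model$sigma[[r]]
  }
  meta_cols <- intersect(META_COLS, names(cohort))
  structure(list(z = z, meta = cohort[, meta_cols, drop = FALSE]),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("z-score matrix:", nrow(x$z), "subject-visits x", ncol(x$z),
      "regions\n")
  invisible(x)
}

#' Mean and SD of control z-scores under the fitting convention
#'
#' Column means (plain) and SDs computed with the same n - p denominator
#' used for the residual SD, so that the fitting controls come out at
#' exactly mean 0 and SD 1.
#'
#' @param zmat a `zscore_matrix` restricted to (or containing) the fitting
#'   controls.
#' @param model the `control_model` used for scoring (provides n and p).
#' @return data.frame with `region`, `mean`, `sd`.
#' @export
control_z_summary <- function(zmat, model) {
  ctl <- zmat$meta$group == "noncarrier"
  z <- zmat$z[ctl, , drop = FALSE]
  p <- length(model$covariates) + 1L
  data.frame(region = colnames(z),
             mean = colMeans(z),
             sd = sqrt(colSums(z^2) / (nrow(z) - p)),
             row.names = NULL)
}

#' Serialize / restore a control model as JSON
#' @param model a `control_model`.
#' @param path file path.
#' @return `read_control_model` returns the restored `control_model`.
#' @export
write_control_model <- function(model, path) {
  jsonlite::write_json(list(
    coefficients = lapply(model$coefficients, as.list),
    sigma = as.list(model$sigma),
    covariates = model$covariates,
    dropped = model$dropped,
    n = model$n, source = model$source
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_control_model
#' @export
read_control_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    coefficients = lapply(j$coefficients, unlist),
    sigma = unlist(j$sigma),
    covariates = as.character(unlist(j$covariates)),
    dropped = as.character(unlist(j$dropped)),
    n = j$n %||% NA_integer_, source = j$source
  ), class = "control_model")
}
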