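# Descriptor-based regression models and Govardovskii A1 template spectra.

# Published coefficient sets mapping chromophore descriptors to lambda-max.
# The three-term blue-cone model is stored in the sign-resolved form: the
# Angle 3 product enters with coefficient -17.052 directly (evaluating it as
# "minus a negative product" instead yields a physically impossible ~4933 nm
# and is inconsistent with the model's own published example outputs).
.REGRESSION_MODELS <- list(
  rh2 = list(name = "rh2_two_term", intercept = 475.628,
             terms = c(torsion15_median = -8.720, rmsf_auc = 34.925)),
  sws2 = list(name = "sws2_three_term", intercept = 2677.5348,
              terms = c(angle3_median = -17.052, torsion3_median = 5.1634,
                        torsion12_median = 2.3642))
)

#' Retrieve a registered regression model
#'
#' @param opsin_class `"rh2"` or `"sws2"`.
#' @param path Optional JSON file with fields `name`, `intercept`, `terms`
#'   (named coefficients over descriptor fields), overriding the registered
#'   coefficients.
#' @return List with `name`, `intercept`, `terms`.
#' @export
regression_model <- function(opsin_class = c("rh2", "sws2"), path = NULL) {
  if (!is.null(path)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    stopifnot(all(c("intercept", "terms") %in% names(m)))
    m$terms <- unlist(m$terms)
    return(m)
  }
  .REGRESSION_MODELS[[match.arg(opsin_class)]]
}

.eval_model <- function(model, d, pigment_id) {
  vals <- vapply(names(model$terms), function(f) {
    v <- d[[f]]
    if (is.null(v) || is.na(v)) {
      stop("descriptor '", f, "' missing for model ", model$name)
    }
    v
  }, numeric(1))
  lambda <- model$intercept + sum(model$terms * vals)
  .new_prediction(pigment_id, sub("_.*$", "", model$name), lambda,
                  "regression",
                  notes = sprintf("%s(%s)", model$name,
                                  paste(sprintf("%s=%g", names(vals), vals),
                                        collapse = ", ")))
}

#' Predict RH2 lambda-max from chromophore descriptors
#'
#' Evaluates the two-term model
#' `lambda-max = 475.628 - 8.720 * Torsion15 + 34.925 * RMSF(LYS+RET)`.
#' Raw model output is returned unclipped; values outside 300-650 nm carry
#' an `"out_of_range"` flag, since the model is only valid near its training
#' descriptor ranges.
#'
#' @param d A `descriptor_set` with `torsion15_median` and `rmsf_auc`.
#' @return A `spectral_prediction` (`method = "regression"`).
#' @export
predict_rh2 <- function(d) {
  .eval_model(regression_model("rh2"), d, d$pigment_id)
}

#' Predict SWS2 lambda-max from chromophore descriptors
#'
#' Evaluates the three-term model
#' `lambda-max = 2677.5348 - 17.052 * Angle3 + 5.1634 * Torsion3 +
#' 2.3642 * Torsion12` (sign-resolved; see the methods vignette).
#'
#' @param d A `descriptor_set` with `angle3_median`, `torsion3_median`,
#'   `torsion12_median`.
#' @return A `spectral_prediction` (`method = "regression"`).
#' @export
predict_sws2 <- function(d) {
  .eval_model(regression_model("sws2"), d, d$pigment_id)
}

#' Predict lambda-max for a table of descriptor sets
#'
#' Dispatches each descriptor set to the model of its `opsin_class`
#' attribute (or an explicit class vector).
#'
#' @param descriptors List of `descriptor_set` objects (e.g. from
#'   [read_descriptors_tsv()]).
#' @param classes Optional character vector of classes (`"rh2"`/`"sws2"`).
#' @return List of `spectral_prediction` objects.
#' @export
predict_from_descriptors <- function(descriptors, classes = NULL) {
  if (inherits(descriptors, "descriptor_set")) descriptors <- list(descriptors)
  if (is.null(classes)) {
    classes <- vapply(descriptors, function(d) {
      cl <- attr(d, "opsin_class")
      if (is.null(cl)) NA_character_ else cl
    }, character(1))
  }
  if (anyNA(classes)) stop("opsin class unknown for some descriptor sets")
  Map(function(d, cl) {
    switch(cl, rh2 = predict_rh2(d), sws2 = predict_sws2(d),
           stop("no registered regression model for class '", cl, "'"))
  }, descriptors, classes)
}

#' Govardovskii A1 visual-pigment template spectrum
#'
#' Generates the standard A1-based dark absorbance spectrum for a pigment of
#' given lambda-max: the alpha band
#' `1 / (exp(A (a - x)) + exp(B (b - x)) + exp(C (c - x)) + D)` with
#' `x = lambda-max / lambda`, `A = 69.7`, `B = 28`, `b = 0.922`,
#' `C = -14.9`, `c = 1.104`, `D = 0.674` and
#' `a = 0.8795 + 0.0459 exp(-(lambda-max - 300)^2 / 11940)`, plus the beta
#' band `A_beta exp(-((lambda - lambda_beta) / b_beta)^2)` with
#' `A_beta = 0.26`, `lambda_beta = 189 + 0.315 lambda-max`,
#' `b_beta = -40.5 + 0.195 lambda-max`. The sum is normalized to peak 1.
#'
#' Note that the full published template is not unimodal for mid- and
#' long-wave pigments: the beta (cis) band contributes a genuine secondary
#' bump near 350-370 nm of relative height up to ~0.26, and for
#' ultraviolet pigments it can pull the composite maximum about 1 nm short
#' of the nominal lambda-max. Set `beta_band = FALSE` for the bare
#' alpha-band main spectrum, which is unimodal and peaks on the grid point
#' nearest lambda-max.
#'
#' @param lambda_max Peak wavelength in nm, in `[300, 650]`.
#' @param grid Ascending wavelength grid in nm (default 300-700, 1 nm).
#' @param beta_band Include the beta-band term (default TRUE).
#' @return An `absorbance_spectrum`: data frame with `wavelength_nm` and
#'   `absorbance`, `lambda_max` attribute.
#' @export
govardovskii_template <- function(lambda_max, grid = 300:700,
                                  beta_band = TRUE) {
  stopifnot(lambda_max >= 300, lambda_max <= 650)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted ascending")
  if (lambda_max < min(grid) || lambda_max > max(grid)) {
    warning("grid does not cover lambda_max = ", lambda_max)
  }
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lam_b <- 189 + 0.315 * lambda_max
  b_b <- -40.5 + 0.195 * lambda_max
  beta <- if (beta_band) 0.26 * exp(-((grid - lam_b) / b_b)^2) else 0
  s <- alpha + beta
  s <- s / max(s)
  structure(data.frame(wavelength_nm = as.numeric(grid), absorbance = s),
            lambda_max = lambda_max,
            class = c("absorbance_spectrum", "data.frame"))
}

#' Normalized template spectra for a panel of predictions
#'
#' One Govardovskii A1 template per pigment on a shared grid, as a tidy
#' table. Predictions without a numeric lambda-max are skipped with a
#' warning.
#'
#' @param predictions List of `spectral_prediction` objects (or a named
#'   numeric vector of lambda-max values).
#' @param grid Shared wavelength grid in nm.
#' @return Tidy data frame with columns `pigment_id`, `wavelength_nm`,
#'   `absorbance`.
#' @export
spectrum_panel <- function(predictions, grid = 300:700) {
  if (is.numeric(predictions)) {
    ids <- names(predictions)
    if (is.null(ids)) ids <- paste0("pigment", seq_along(predictions))
    predictions <- Map(function(id, lm) list(pigment_id = id, lambda_max = lm),
                       ids, predictions)
  }
  if (inherits(predictions, "spectral_prediction")) {
    predictions <- list(predictions)
  }
  out <- lapply(predictions, function(p) {
    if (is.na(p$lambda_max)) {
      warning("skipping ", p$pigment_id, ": no numeric lambda-max")
      return(NULL)
    }
    sp <- govardovskii_template(p$lambda_max, grid)
    data.frame(pigment_id = p$pigment_id,
               wavelength_nm = sp$wavelength_nm, absorbance = sp$absorbance)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(pigment_id = character(), wavelength_nm = numeric(),
                      absorbance = numeric()))
  }
  do.call(rbind, out)
}
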