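# Rule-based lambda-max assignment from tuning-site profiles.

#' Load the registered spectral-tuning rule table
#'
#' Each row registers one substitution at one bovine-numbered site: the
#' ancestral residue, the substituted residue, and the additive shift in nm.
#' The LWS rows implement the classical five-sites rule; the RH1 rows carry
#' well-characterized rod-opsin substitutions used for annotation and a
#' flagged approximate estimate. The packaged defaults can be overridden
#' with a user TSV of the same layout.
#'
#' @param path Optional TSV with columns `class`, `site`, `ancestral`,
#'   `substituted`, `delta_nm`, `citation`.
#' @return Data frame of rules.
#' @export
tuning_rule_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tuning_rule_table.tsv",
                        package = "salmopsin", mustWork = TRUE)
  }
  rt <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("class", "site", "ancestral", "substituted", "delta_nm")
  if (!all(need %in% names(rt))) {
    stop("rule table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(rt$delta_nm))) stop("non-finite delta_nm in rule table")
  rt
}

.new_prediction <- function(pigment_id, opsin_class, lambda_max, method,
                            notes = character(), flags = character()) {
  if (!is.na(lambda_max) && (lambda_max < 300 || lambda_max > 650)) {
    flags <- union(flags, "out_of_range")
  }
  structure(list(pigment_id = pigment_id, opsin_class = opsin_class,
                 lambda_max = lambda_max, method = method,
                 chromophore = "A1", notes = notes, flags = flags),
            class = "spectral_prediction")
}

#' @export
print.spectral_prediction <- function(x, ...) {
  lm <- if (is.na(x$lambda_max)) "no numeric lambda-max" else
    sprintf("lambda-max = %.2f nm", x$lambda_max)
  cat("<spectral_prediction> ", x$pigment_id, " (", x$opsin_class, ", ",
      x$method, ", A1): ", lm, "\n", sep = "")
  if (length(x$notes)) cat("  notes: ", paste(x$notes, collapse = "; "),
                           "\n", sep = "")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "),
                           "\n", sep = "")
  invisible(x)
}

#' Ultraviolet rule for SWS1 pigments (site 86)
#'
#' Phenylalanine at bovine site 86 marks an ultraviolet-sensitive SWS1
#' pigment with lambda-max 360 nm; any other residue marks a violet-shifted
#' pigment for which no numeric value is assigned by this rule.
#'
#' @param profile A `tuning_site_profile` containing site 86.
#' @return A `spectral_prediction` (`method = "rule_based"`).
#' @export
predict_sws1 <- function(profile) {
  if (!"86" %in% names(profile)) stop("profile must contain site 86")
  r <- profile[["86"]]
  if (r == "-") stop("site 86 unalignable ('-') in ",
                     attr(profile, "pigment_id"))
  if (r == "F") {
    .new_prediction(attr(profile, "pigment_id"), "sws1", 360, "rule_based",
                    notes = "F86: UVS, lambda-max 360 nm")
  } else {
    .new_prediction(attr(profile, "pigment_id"), "sws1", NA_real_,
                    "rule_based",
                    notes = sprintf(
                      "%s86: violet-shifted (non-UVS), not numerically predicted", r))
  }
}

#' Additive five-sites rule for LWS pigments
#'
#' Starts from 560 nm for the ancestral state S164/H181/Y261/T269/A292 and
#' adds the registered shift for each substitution found (S164A, H181Y,
#' Y261F, T269A, A292S; all blue-shifting). Residues matching neither state
#' are skipped with a warning note; sites recorded `"-"` are skipped and the
#' prediction flagged `"incomplete"`.
#'
#' @param profile A `tuning_site_profile` over sites 164, 181, 261, 269, 292.
#' @param rules Rule table (see [tuning_rule_table()]).
#' @param base_lambda Ancestral-state lambda-max in nm.
#' @return A `spectral_prediction` (`method = "rule_based"`); `notes` records
#'   each rule firing.
#' @export
predict_lws_five_site <- function(profile, rules = tuning_rule_table(),
                                  base_lambda = 560) {
  need <- c("164", "181", "261", "269", "292")
  if (!all(need %in% names(profile))) {
    stop("profile must contain sites ", paste(need, collapse = ", "))
  }
  rt <- rules[rules$class == "lws", ]
  lambda <- base_lambda
  notes <- character()
  flags <- character()
  for (s in need) {
    r <- profile[[s]]
    row <- rt[rt$site == as.integer(s), ]
    if (r == "-") {
      flags <- union(flags, "incomplete")
      notes <- c(notes, sprintf("site %s unalignable, skipped", s))
    } else if (r == row$ancestral) {
      # ancestral state, no shift
    } else if (r == row$substituted) {
      lambda <- lambda + row$delta_nm
      notes <- c(notes, sprintf("%s%s%s: %+g nm", row$ancestral, s, r,
                                row$delta_nm))
    } else {
      notes <- c(notes, sprintf("site %s residue %s unknown to rule, skipped",
                                s, r))
      warning("site ", s, " residue ", r, " unknown to the five-sites rule")
    }
  }
  if (!length(notes)) notes <- "ancestral S164/H181/Y261/T269/A292: 560 nm"
  p <- .new_prediction(attr(profile, "pigment_id"), "lws", lambda,
                       "rule_based", notes = notes, flags = flags)
  if (lambda < 500 || lambda > 575) {
    p$flags <- union(p$flags, "out_of_class_range")
  }
  p
}

#' E122Q green/blue classifier for RH2 pigments
#'
#' Glutamate at bovine site 122 marks a green-shifted RH2 pigment
#' (lambda-max above ~495 nm), glutamine a blue-shifted one (below ~495 nm);
#' the substitution alone accounts for roughly 15 nm of shift.
#'
#' @param profile A `tuning_site_profile` containing site 122.
#' @return `"green_shifted"` or `"blue_shifted"`.
#' @export
classify_rh2_e122q <- function(profile) {
  if (!"122" %in% names(profile)) stop("profile must contain site 122")
  r <- profile[["122"]]
  switch(r,
         E = "green_shifted",
         Q = "blue_shifted",
         stop("site 122 residue '", r, "' is neither E nor Q"))
}

#' Annotated report over the 27 RH1 tuning sites
#'
#' Lists the residue at each rod-opsin site with a literature annotation for
#' the well-characterized substitutions (D83N, E122Q, A164S, F261Y, A269T,
#' A292S) and their shift direction. A numeric lambda-max is reported only as
#' a best-effort estimate (500 nm base plus registered shifts) and flagged
#' `"approximate"`: no complete additive rule set over all 27 sites exists.
#'
#' @param profile A `tuning_site_profile` over RH1 sites (may be a subset).
#' @param rules Rule table (see [tuning_rule_table()]).
#' @param base_lambda Baseline rod-pigment lambda-max in nm.
#' @return An `rh1_report`: list with `sites` (data frame `site`, `residue`,
#'   `annotation`) and `prediction` (a flagged `spectral_prediction`).
#' @export
report_rh1_sites <- function(profile, rules = tuning_rule_table(),
                             base_lambda = 500) {
  rt <- rules[rules$class == "rh1", ]
  ref <- bovine_rhodopsin()$protein
  sites <- as.integer(names(profile))
  lambda <- base_lambda
  notes <- character()
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[i]
    r <- as.character(profile[[i]])
    bov <- substr(ref, s, s)
    ann <- ""
    row <- rt[rt$site == s, ]
    if (nrow(row) == 1L && r == row$substituted) {
      dir <- if (row$delta_nm < 0) "blue-shift" else "red-shift"
      ann <- sprintf("%s%d%s, %s (%+g nm)", row$ancestral, s, r, dir,
                     row$delta_nm)
    } else if (r != "-" && r != bov) {
      ann <- sprintf("non-bovine residue (%s%d%s), shift uncharacterized",
                     bov, s, r)
    }
    data.frame(site = s, residue = r, annotation = ann)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(), residue = character(),
               annotation = character())
  for (i in seq_len(nrow(rt))) {
    s <- as.character(rt$site[i])
    if (s %in% names(profile) && profile[[s]] == rt$substituted[i]) {
      lambda <- lambda + rt$delta_nm[i]
      notes <- c(notes, sprintf("%s%s%s: %+g nm", rt$ancestral[i], s,
                                rt$substituted[i], rt$delta_nm[i]))
    }
  }
  if (!length(notes)) notes <- "no registered substitutions fired"
  pred <- .new_prediction(attr(profile, "pigment_id"), "rh1", lambda,
                          "rule_based", notes = notes,
                          flags = "approximate")
  structure(list(sites = df, prediction = pred), class = "rh1_report")
}

#' @export
print.rh1_report <- function(x, ...) {
  cat("<rh1_report> ", x$prediction$pigment_id, ": ",
      nrow(x$sites), " sites\n", sep = "")
  ann <- x$sites[nzchar(x$sites$annotation), ]
  if (nrow(ann)) print(ann, row.names = FALSE)
  print(x$prediction)
  invisible(x)
}

#' Write spectral predictions as TSV
#'
#' Columns: `pigment_id`, `opsin_class`, `lambda_max_nm`, `method`,
#' `chromophore`, `flags`, `notes`.
#'
#' @param predictions A `spectral_prediction` or list of them.
#' @param path Output file (or connection).
#' @return The assembled data frame, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  if (inherits(predictions, "spectral_prediction")) {
    predictions <- list(predictions)
  }
  df <- do.call(rbind, lapply(predictions, function(p) {
    data.frame(pigment_id = p$pigment_id, opsin_class = p$opsin_class,
               lambda_max_nm = p$lambda_max, method = p$method,
               chromophore = p$chromophore,
               flags = paste(p$flags, collapse = ","),
               notes = paste(p$notes, collapse = "; "))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
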