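## Promoter characterization: normalized fluorescence, fold induction /
## fold repression, Hill dose-response fits, and the speedometer
## (edit-distance versus fold-induction) representation of sequence and
## functional diversity.

#' Blank-corrected, density-normalized fluorescence
#'
#' `(gfp_raw - blank_gfp) / (od600 - blank_od)`.
#'
#' @param gfp_raw raw fluorescence (arbitrary units).
#' @param od600 culture optical density.
#' @param blank_gfp,blank_od blank-well readings.
#' @export
normalize_fluorescence <- function(gfp_raw, od600, blank_gfp = 0, blank_od = 0) {
  if (any(od600 <= blank_od))
    stop("od600 must exceed the blank OD for normalization")
  (gfp_raw - blank_gfp) / (od600 - blank_od)
}

#' Fold induction: induced over uninduced normalized fluorescence
#'
#' When vectors (cell populations) are supplied, medians are taken first.
#' @param norm_induced,norm_uninduced normalized fluorescence values.
#' @export
fold_induction <- function(norm_induced, norm_uninduced) {
  den <- median(norm_uninduced)
  if (den == 0) stop("uninduced fluorescence median is zero")
  median(norm_induced) / den
}

#' Fold repression: expression without aTF over repressed expression
#' @param norm_no_atf,norm_with_atf normalized fluorescence values.
#' @export
fold_repression <- function(norm_no_atf, norm_with_atf) {
  den <- median(norm_with_atf)
  if (den == 0) stop("repressed fluorescence median is zero")
  median(norm_no_atf) / den
}

#' Per-clone induction summary
#'
#' @param records expression records (see [read_expression_csv()]); dose
#'   rows beyond the uninduced and maximal-induction conditions are
#'   ignored here.
#' @param reference_clone optional clone_id of a constitutive reference;
#'   when given, normalized values are also reported as percent of its
#'   uninduced+induced mean activity.
#' @param blank_gfp,blank_od blank readings.
#' @return data.frame: clone_id, norm_uninduced, norm_induced,
#'   fold_induction (and percent_of_constitutive when a reference is
#'   named).
#' @export
induction_summary <- function(records, reference_clone = NULL,
                              blank_gfp = 0, blank_od = 0) {
  records$norm <- normalize_fluorescence(records$gfp_raw, records$od600,
                                         blank_gfp, blank_od)
  per_clone <- function(df) {
    un <- df$norm[df$condition == "uninduced"]
    top <- df[df$condition == "induced", , drop = FALSE]
    ind <- top$norm[top$ligand_conc == max(top$ligand_conc)]
    data.frame(norm_uninduced = median(un), norm_induced = median(ind),
               fold_induction = fold_induction(ind, un))
  }
  parts <- lapply(split(records, records$clone_id), per_clone)
  out <- cbind(clone_id = names(parts), do.call(rbind, parts))
  rownames(out) <- NULL
  if (!is.null(reference_clone)) {
    if (!reference_clone %in% out$clone_id)
      stop(sprintf("reference clone '%s' absent from the records", reference_clone))
    ref <- out$norm_induced[out$clone_id == reference_clone]
    out$percent_of_constitutive <- 100 * out$norm_induced / ref
  }
  out
}

#' Fit a Hill dose-response curve
#'
#' Nonlinear least squares of `y = y0 + vmax * L^n / (km^n + L^n)` with a
#' basal term, multi-start initialization over a log-spaced Km grid and
#' n in {0.5, 1, 2, 4}, and bounds y0 >= 0, vmax > 0, km > 0,
#' 0 < n <= 10. By construction the fitted curve satisfies
#' `y(km) - y0 = vmax / 2`.
#'
#' @param ligand_concs ligand concentrations (uM), including 0.
#' @param responses normalized fluorescence, same length (replicates appear
#'   as repeated concentrations).
#' @param fix_y0 optionally pin the basal term (e.g. 0 after background
#'   subtraction); free by default.
#' @return object of class `hill_fit`: v_max, k_m, hill_n, y0,
#'   residual_sse, converged, plus the data.
#' @export
fit_hill <- function(ligand_concs, responses, fix_y0 = NULL) {
  stopifnot(length(ligand_concs) == length(responses))
  if (length(unique(ligand_concs)) < 4L)
    stop("at least 4 distinct concentrations are required")
  if (!any(ligand_concs == 0))
    stop("a zero-ligand (uninduced) point is required")
  dat <- data.frame(L = ligand_concs, y = responses)
  pos <- sort(unique(dat$L[dat$L > 0]))
  km_grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 4L))
  n_grid <- c(0.5, 1, 2, 4)
  y0_start <- if (is.null(fix_y0)) max(min(dat$y), 1e-9) else fix_y0
  vmax_start <- max(max(dat$y) - y0_start, 1e-6)
  best <- NULL
  for (km0 in km_grid) for (n0 in n_grid) {
    fit <- tryCatch({
      if (is.null(fix_y0)) {
        minpack.lm::nlsLM(
          y ~ y0 + vmax * L^n / (km^n + L^n), data = dat,
          start = list(y0 = y0_start, vmax = vmax_start, km = km0, n = n0),
          lower = c(y0 = 0, vmax = 1e-12, km = 1e-12, n = 1e-3),
          upper = c(y0 = Inf, vmax = Inf, km = Inf, n = 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ fix_y0 + vmax * L^n / (km^n + L^n), data = dat,
          start = list(vmax = vmax_start, km = km0, n = n0),
          lower = c(vmax = 1e-12, km = 1e-12, n = 1e-3),
          upper = c(vmax = Inf, km = Inf, n = 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(v_max = NA_real_, k_m = NA_real_, hill_n = NA_real_,
                          y0 = if (is.null(fix_y0)) NA_real_ else fix_y0,
                          residual_sse = NA_real_, converged = FALSE,
                          data = dat),
                     class = "hill_fit"))
  }
  cf <- coef(best$fit)
  structure(list(v_max = unname(cf["vmax"]), k_m = unname(cf["km"]),
                 hill_n = unname(cf["n"]),
                 y0 = if (is.null(fix_y0)) unname(cf["y0"]) else fix_y0,
                 residual_sse = best$sse, converged = TRUE, data = dat),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: did not converge\n")
  } else {
    cat(sprintf("Hill fit: Vmax %.4g, Km %.4g uM, n %.3g, y0 %.4g (SSE %.4g)\n",
                x$v_max, x$k_m, x$hill_n, x$y0, x$residual_sse))
  }
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, ligand_concs, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  object$y0 + object$v_max * ligand_concs^object$hill_n /
    (object$k_m^object$hill_n + ligand_concs^object$hill_n)
}

#' Levenshtein (edit) distance
#'
#' Standard unit-cost dynamic programming over substitutions, insertions
#' and deletions.
#' @param a,b character vectors (recycled).
#' @export
levenshtein <- function(a, b) {
  d <- adist(a, b)
  if (length(a) == length(b) && length(a) > 1L) diag(d) else as.vector(d)
}

#' Speedometer coordinates: sequence diversity versus fold induction
#'
#' Radial coordinate: edit distance of every operator to a reference
#' (by default the operator with the highest fold induction); angular
#' coordinate: fold induction.
#'
#' @param sequences operator sequences.
#' @param fold_inductions matching fold-induction values.
#' @param reference reference sequence; default the highest-fold-induction
#'   operator.
#' @return data.frame: sequence, radial (edit distance), angular (fold
#'   induction).
#' @export
speedometer_coordinates <- function(sequences, fold_inductions,
                                    reference = NULL) {
  stopifnot(length(sequences) == length(fold_inductions))
  reference <- reference %||% sequences[which.max(fold_inductions)]
  data.frame(sequence = sequences,
             radial = as.vector(adist(sequences, reference)),
             angular = fold_inductions,
             stringsAsFactors = FALSE)
}
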