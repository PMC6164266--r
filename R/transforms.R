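#' Covariate transformation specification
#'
#' Which ancillary covariates enter the linear predictor and how they are
#' transformed.  Count-like covariates with point masses near zero (fire
#' counts, primary emissions, roadway length) are log-transformed with an
#' offset of 1; all covariates except the response and AOD are then
#' z-standardised with parameters fitted on the training records so the
#' same scaling can be replayed at prediction time.  Optionally an
#' AOD-by-temperature interaction column is appended (using the
#' z-transformed temperature).
#'
#' @param names Ordered character vector of covariate column names.
#' @param log_set Covariates to log(x + offset) transform.
#' @param z_set Covariates to z-standardise (default: all in \code{names}).
#' @param interaction_aod_temp Add an AOD x temperature interaction column?
#' @param temp_name Name of the temperature column (needed for the
#'   interaction).
#' @param log_offset Offset added before the log (default 1).
#' @return Object of class \code{covariate_spec}.
#' @export
covariate_spec <- function(names,
                           log_set = intersect(c("fire", "emission", "road"),
                                               names),
                           z_set = names,
                           interaction_aod_temp = "temp" %in% names,
                           temp_name = "temp",
                           log_offset = 1) {
  if (!all(log_set %in% names) || !all(z_set %in% names)) {
    stop("covariate_spec: transform sets must be subsets of 'names'")
  }
  if (interaction_aod_temp && !(temp_name %in% names)) {
    stop("covariate_spec: AOD x temperature interaction requires column '",
         temp_name, "'")
  }
  structure(list(names = names, log_set = log_set, z_set = z_set,
                 interaction_aod_temp = interaction_aod_temp,
                 temp_name = temp_name, log_offset = log_offset),
            class = "covariate_spec")
}

#' Apply covariate transforms, fitting the scaling parameters
#'
#' @param panel Data frame containing the covariate columns of \code{spec}.
#' @param spec A \code{\link{covariate_spec}}.
#' @param fitted Optional transform parameters from a previous call (as in
#'   the \code{transform} element of the result); when supplied, the stored
#'   means/SDs are replayed instead of refitted, which is how prediction
#'   and held-out data must be scaled.
#' @return List with \code{panel} (transformed copy) and \code{transform}
#'   (fitted parameters, reusable via \code{fitted}).
#' @export
apply_transforms <- function(panel, spec, fitted = NULL) {
  stopifnot(inherits(spec, "covariate_spec"))
  missing_cols <- setdiff(spec$names, names(panel))
  if (length(missing_cols)) {
    stop("apply_transforms: missing covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- panel
  for (v in spec$log_set) {
    if (any(out[[v]] + spec$log_offset <= 0, na.rm = TRUE)) {
      stop("apply_transforms: log transform of '", v,
           "' undefined (values <= -offset)")
    }
    out[[v]] <- log(out[[v]] + spec$log_offset)
  }
  if (is.null(fitted)) {
    center <- scale <- stats::setNames(numeric(length(spec$z_set)), spec$z_set)
    for (v in spec$z_set) {
      center[v] <- mean(out[[v]], na.rm = TRUE)
      scale[v] <- stats::sd(out[[v]], na.rm = TRUE)
      if (!is.finite(scale[v]) || scale[v] == 0) {
        stop("apply_transforms: covariate '", v,
             "' has zero variance; cannot z-transform")
      }
    }
    fitted <- list(center = center, scale = scale)
  }
  for (v in spec$z_set) {
    out[[v]] <- (out[[v]] - fitted$center[v]) / fitted$scale[v]
  }
  list(panel = out, transform = fitted)
}

#' Invert fitted covariate transforms
#'
#' Maps a transformed panel back to the original covariate scale; round
#' trips with \code{\link{apply_transforms}} to floating-point accuracy.
#'
#' @param panel Transformed data frame.
#' @param spec The \code{\link{covariate_spec}} used.
#' @param fitted The \code{transform} element returned by
#'   \code{\link{apply_transforms}}.
#' @export
invert_transforms <- function(panel, spec, fitted) {
  out <- panel
  for (v in spec$z_set) {
    out[[v]] <- out[[v]] * fitted$scale[v] + fitted$center[v]
  }
  for (v in spec$log_set) {
    out[[v]] <- exp(out[[v]]) - spec$log_offset
  }
  out
}
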