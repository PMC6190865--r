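#' Define a condition-weight model
#'
#' A model, in the sense used for Bayesian model selection over evoked
#' responses, is a named mapping from experimental condition labels to
#' dimensionless covariate weights. The weights encode the hypothesised
#' ordering of response amplitudes across conditions; they enter the
#' per-voxel GLM as a single (mean-centred) regressor.
#'
#' @param name Character scalar, model name.
#' @param weights Named numeric vector: one weight per condition label.
#' @return An object of class `bms_model_spec`.
#' @examples
#' model_spec("Opposition", c(UP = 1, AP = 2, UU = 2, AU = 3))
#' @export
model_spec <- function(name, weights) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(weights) || is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("`weights` must be a named numeric vector (condition -> weight).", call. = FALSE)
  }
  if (anyDuplicated(names(weights))) {
    stop("duplicate condition labels in `weights`.", call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("all weights must be finite.", call. = FALSE)
  }
  if (length(unique(weights)) < 2L) {
    stop("a model needs at least two distinct weights; otherwise it is a pure intercept.",
         call. = FALSE)
  }
  structure(list(name = name, weights = weights), class = "bms_model_spec")
}

#' @export
print.bms_model_spec <- function(x, ...) {
  cat("<bms_model_spec> ", x$name, "\n", sep = "")
  print(x$weights)
  invisible(x)
}

#' Standard attention-by-prediction models
#'
#' Convenience constructors for the two competing hypotheses about how
#' attention modulates responses to predicted and unpredicted auditory
#' stimuli, over the four conditions UP (unattended predicted),
#' AP (attended predicted), UU (unattended unpredicted) and
#' AU (attended unpredicted). The Opposition model orders conditions
#' `[1, 2, 2, 3]` (attention boosts responses to predicted and unpredicted
#' stimuli alike); the Interaction model orders them `[1, 4, 2, 3]`
#' (attention boosts predicted stimuli most).
#'
#' @param conditions Character vector of length 4 giving the labels used for
#'   the four conditions, in the order UP, AP, UU, AU.
#' @return A `bms_model_spec`.
#' @export
opposition_model <- function(conditions = c("UP", "AP", "UU", "AU")) {
  stopifnot(length(conditions) == 4L)
  model_spec("Opposition", setNames(c(1, 2, 2, 3), conditions))
}

#' @rdname opposition_model
#' @export
interaction_model <- function(conditions = c("UP", "AP", "UU", "AU")) {
  stopifnot(length(conditions) == 4L)
  model_spec("Interaction", setNames(c(1, 4, 2, 3), conditions))
}

#' Build a two-column GLM design matrix from trial labels
#'
#' Maps each trial's condition label to the model's covariate weight,
#' mean-centres the resulting covariate, scales it to unit sample variance,
#' and appends an intercept column. Centring makes the effect regressor
#' orthogonal to the intercept so the intercept absorbs the baseline;
#' variance scaling equalises the complexity (Occam) penalty across
#' competing models whose weight vectors have different norms — without it,
#' the model with the smaller covariate norm is spuriously favoured at
#' pure-noise voxels.
#'
#' @param condition_labels Character vector, one label per trial.
#' @param spec A [model_spec()].
#' @param scale Scale the centred covariate to unit variance (default TRUE).
#' @return A list of class `bms_design` with elements `matrix`
#'   (trials x 2, columns `effect` and `intercept`), `regressor_names`,
#'   and `covariate_raw` (the unscaled per-trial weights).
#' @examples
#' build_design(c("UP", "AP", "UU", "AU"), opposition_model())
#' @export
build_design <- function(condition_labels, spec, scale = TRUE) {
  stopifnot(inherits(spec, "bms_model_spec"))
  condition_labels <- as.character(condition_labels)
  if (length(condition_labels) == 0L) {
    stop("no trials: `condition_labels` is empty.", call. = FALSE)
  }
  unknown <- setdiff(unique(condition_labels), names(spec$weights))
  if (length(unknown) > 0L) {
    stop("condition label(s) not mapped by model '", spec$name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  covariate <- unname(spec$weights[condition_labels])
  centred <- covariate - mean(covariate)
  if (all(abs(centred) < 1e-12)) {
    stop("degenerate design for model '", spec$name,
         "': covariate is constant across trials after centring.", call. = FALSE)
  }
  if (scale) centred <- centred / stats::sd(centred)
  X <- cbind(effect = centred, intercept = rep(1, length(centred)))
  structure(list(matrix = X, regressor_names = colnames(X), model_name = spec$name,
                 covariate_raw = covariate),
            class = "bms_design")
}
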