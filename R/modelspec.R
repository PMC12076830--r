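#' Declare one Bayesian mixed-effects model
#'
#' A declarative description of a model: which table it is fit to, the data
#' filter, the fixed-effects formula (dummy coding with the canonical
#' reference levels non-autistic / UK / mental; the word factor uses a
#' deviation contrast), the crossed random-effects structure and the prior
#' set. Continuous covariates named in `z_covariates` are re-standardised
#' within the filtered dataset that actually enters the model.
#'
#' @param name Model name (e.g. "UK.1").
#' @param response Response column.
#' @param fixed Right-hand-side formula string for the fixed effects.
#' @param data One of "trials", "animations", "cv" — which canonical table
#'   the model consumes.
#' @param filter Named list of column = value constraints applied first.
#' @param random List of random terms; each element is
#'   `list(group = <column>, intercept = TRUE, slopes = "main" | "full" |
#'   "none" | character())` where "main" gives slopes for every main-effect
#'   predictor column and "full" for every fixed-effect column.
#' @param priors A [prior_set()].
#' @param z_covariates Character: covariates to z-standardise within the
#'   filtered data (maps z-column -> raw column).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name, response, fixed, data = "trials",
                       filter = list(), random = list(),
                       priors = prior_set(),
                       z_covariates = character()) {
  stopifnot(is.character(name), is.character(fixed),
            data %in% c("trials", "animations", "cv"),
            inherits(priors, "prior_set"))
  for (r in random)
    if (is.null(r$group)) stop_config("every random term needs a group column")
  structure(list(name = name, response = response, fixed = fixed,
                 data = data, filter = filter, random = random,
                 priors = priors, z_covariates = z_covariates),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  flt <- if (length(x$filter))
    paste(names(x$filter), unlist(x$filter), sep = "=", collapse = ", ")
  else "none"
  cat(sprintf("Model %s: %s ~ %s\n  data: %s; filter: %s\n",
              x$name, x$response, x$fixed, x$data, flt))
  for (r in x$random)
    cat(sprintf("  random: %s (intercept=%s, slopes=%s)\n", r$group,
                isTRUE(r$intercept), paste(r$slopes, collapse = "+")))
  invisible(x)
}

# Contrast assignment: treatment coding against canonical reference levels
# everywhere, deviation (sum-to-zero) contrast for the word factor.
model_contrasts <- function(data) {
  cl <- vapply(data, is.factor, logical(1))
  contrasts <- lapply(names(data)[cl], function(nm) {
    if (nm == "word") stats::contr.sum else stats::contr.treatment
  })
  names(contrasts) <- names(data)[cl]
  contrasts[vapply(names(contrasts),
                   function(nm) nlevels(data[[nm]]) >= 2, logical(1))]
}

apply_filter <- function(table, filter) {
  for (nm in names(filter)) {
    if (!nm %in% names(table))
      stop_config("filter column '%s' absent from table", nm)
    table <- table[as.character(table[[nm]]) %in% filter[[nm]], , drop = FALSE]
  }
  if (!nrow(table)) stop_config("data filter leaves no rows")
  table
}

# Fixed-term labels of order 1 (main effects) in a fixed formula.
main_effect_terms <- function(fixed) {
  tt <- stats::terms(stats::as.formula(paste("~", fixed)))
  attr(tt, "term.labels")[attr(tt, "order") == 1]
}

#' Build fixed- and random-effects design matrices for a model
#'
#' Applies the spec's data filter, re-standardises covariates within the
#' filtered rows, and constructs the dummy / deviation-contrast design
#' matrix plus one (index, Z) pair per random term. Dummy columns are 0 at
#' the reference level; deviation-contrast columns for the 6-level word
#' factor number 5 and take value -1 at the omitted level.
#'
#' @param spec A [model_spec()].
#' @param table The canonical table the spec's `data` slot names.
#' @return List with `y`, `X`, `random` (per term: `group`, `index`,
#'   `levels`, `Z`), the filtered `data`, and `z_transforms`.
#' @export
build_design_matrices <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  data <- apply_filter(as.data.frame(table), spec$filter)

  # re-standardise covariates within the modelled dataset
  z_transforms <- list()
  for (zcol in names(spec$z_covariates)) {
    raw <- spec$z_covariates[[zcol]]
    if (!raw %in% names(data))
      stop_config("covariate '%s' absent from table", raw)
    m <- mean(data[[raw]]); s <- stats::sd(data[[raw]])
    if (s == 0) stop_config("covariate '%s' is constant after filtering", raw)
    data[[zcol]] <- (data[[raw]] - m) / s
    z_transforms[[zcol]] <- c(center = m, scale = s)
  }
  for (nm in names(data))
    if (is.factor(data[[nm]])) data[[nm]] <- droplevels(data[[nm]])

  fml <- stats::as.formula(paste("~", spec$fixed))
  vars <- all.vars(fml)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop_config("model terms absent from table: %s",
                paste(missing_vars, collapse = ", "))
  contrasts <- model_contrasts(data[vars])
  X <- stats::model.matrix(fml, data, contrasts.arg = contrasts)

  random <- lapply(spec$random, function(r) {
    if (!r$group %in% names(data))
      stop_config("random grouping column '%s' absent from table", r$group)
    g <- factor(data[[r$group]])
    slope_cols <- character()
    no_slopes <- is.null(r$slopes) || identical(r$slopes, "none") ||
      length(r$slopes) == 0
    if (no_slopes) {
      Zs <- matrix(nrow = nrow(data), ncol = 0)
    } else if (identical(r$slopes, "full")) {
      slope_cols <- setdiff(colnames(X), "(Intercept)")
      Zs <- X[, slope_cols, drop = FALSE]
    } else {
      terms_r <- if (identical(r$slopes, "main")) main_effect_terms(spec$fixed)
                 else r$slopes
      # drop slope terms that are constant within the filtered data
      terms_r <- terms_r[vapply(terms_r, function(tm) {
        v <- data[[tm]]
        is.null(v) || length(unique(v)) > 1
      }, logical(1))]
      if (length(terms_r)) {
        Zf <- stats::as.formula(paste("~", paste(terms_r, collapse = "+")))
        Zs <- stats::model.matrix(Zf, data,
                                  contrasts.arg = model_contrasts(
                                    data[all.vars(Zf)]))
        Zs <- Zs[, setdiff(colnames(Zs), "(Intercept)"), drop = FALSE]
      } else Zs <- matrix(nrow = nrow(data), ncol = 0)
    }
    Z <- if (isTRUE(r$intercept))
      cbind("(Intercept)" = rep(1, nrow(data)), Zs) else Zs
    if (!ncol(Z)) stop_config("random term '%s' has no columns", r$group)
    list(group = r$group, index = as.integer(g), levels = levels(g), Z = Z)
  })

  if (!spec$response %in% names(data))
    stop_config("response '%s' absent from table", spec$response)
  list(y = data[[spec$response]], X = X, random = random, data = data,
       z_transforms = z_transforms, contrasts = contrasts)
}
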