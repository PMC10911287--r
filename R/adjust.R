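#' Residual-based adjustment to a common body size
#'
#' Fits a linear model of a response (oxygen uptake, organ mass, ...) on a body
#' size covariate (mass or lean mass) plus an optional group factor, and maps
#' each individual to the common reference size by adding its residual to the
#' model prediction for its group at the reference:
#' `adjusted_i = prediction(group_i, ref) + residual_i`. This compensates for
#' deviations from 1:1 scaling that ratio-based indices silently assume.
#' Residuals are always applied on the response scale; with `link = "log"` the
#' model is fit on `log(response)` (for right-skewed responses) but predictions
#' are back-transformed before the residual is added.
#'
#' With a constant covariate the model is singular; the fit falls back to group
#' means with a warning (adjusted values then equal the observations).
#'
#' @param response numeric response, one value per individual.
#' @param covariate body size covariate (positive; kg for masses).
#' @param groups optional group labels (factor or character).
#' @param ref reference covariate value at which all individuals are compared
#'   (a warning is issued when it lies outside the observed range).
#' @param link `"identity"` or `"log"`.
#' @param data optional data.frame in which `response`, `covariate` and
#'   `groups` are evaluated.
#' @return An object of class `mass_adjust`: the underlying [stats::lm()] fit
#'   plus per-individual adjusted values and group means at the reference.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @examples
#' set.seed(1)
#' mass <- runif(30, 0.1, 0.2)
#' mo2 <- 2 + 40 * mass + rnorm(30, 0, 0.5)
#' fit <- mass_adjust(mo2, mass, ref = 0.146)
#' coef(fit)
#' head(adjusted(fit))
#' @export
mass_adjust <- function(response, covariate, groups = NULL, ref,
                        link = c("identity", "log"), data = NULL) {
  link <- match.arg(link)
  if (!is.null(data)) {
    response <- eval(substitute(response), data, parent.frame())
    covariate <- eval(substitute(covariate), data, parent.frame())
    groups <- eval(substitute(groups), data, parent.frame())
  }
  response <- as.numeric(response)
  covariate <- as.numeric(covariate)
  n <- length(response)
  if (length(covariate) != n) stop("response and covariate lengths differ")
  if (any(covariate <= 0)) stop("covariate must be positive")
  if (n < 3L) stop("need at least 3 individuals to fit an adjustment model")
  if (link == "log" && any(response <= 0)) {
    stop("log link requires positive responses")
  }
  if (ref < min(covariate) || ref > max(covariate)) {
    warning("reference value ", ref, " lies outside the observed covariate range")
  }
  has_groups <- !is.null(groups)
  if (has_groups) {
    groups <- factor(groups)
    if (length(groups) != n) stop("groups length differs from response")
    if (nlevels(groups) < 2L) has_groups <- FALSE
  }
  d <- data.frame(.y = if (link == "log") log(response) else response,
                  .x = covariate)
  if (has_groups) d$.g <- groups
  form <- if (has_groups) .y ~ .x + .g else .y ~ .x
  singular <- stats::sd(covariate) == 0
  if (!singular) {
    fit <- stats::lm(form, data = d)
    singular <- anyNA(stats::coef(fit))
  }
  if (singular) {
    warning("singular adjustment fit (constant covariate); falling back to group means")
    gm <- if (has_groups) c(tapply(response, groups, mean)) else mean(response)
    pred_ref <- if (has_groups) unname(gm[as.character(groups)]) else rep(gm, n)
    adjusted <- as.numeric(pred_ref + (response - pred_ref))
    fit <- NULL
  } else {
    nd <- data.frame(.x = rep(ref, n))
    if (has_groups) nd$.g <- groups
    pred_ref <- stats::predict(fit, newdata = nd)
    pred_own <- stats::predict(fit)
    if (link == "log") {
      pred_ref <- exp(pred_ref)
      pred_own <- exp(pred_own)
    }
    adjusted <- unname(pred_ref + (response - pred_own))
  }
  grp <- if (has_groups) groups else factor(rep("all", n))
  structure(
    list(fit = fit, link = link, ref = ref,
         response = response, covariate = covariate,
         groups = if (has_groups) groups else NULL,
         adjusted = adjusted,
         group_means = c(tapply(adjusted, grp, mean)),
         singular = singular),
    class = "mass_adjust")
}

#' Adjusted values from a mass-adjustment fit
#' @param object a [mass_adjust()] object.
#' @return Numeric vector of size-adjusted responses.
#' @export
adjusted <- function(object) {
  stopifnot(inherits(object, "mass_adjust"))
  object$adjusted
}

#' @export
print.mass_adjust <- function(x, ...) {
  cat(sprintf("<mass_adjust> %d individuals, link = %s, ref = %g\n",
              length(x$response), x$link, x$ref))
  if (!is.null(x$fit)) {
    b <- stats::coef(x$fit)
    cat(sprintf("  slope on covariate: %.4g%s\n", b[".x"],
                if (x$link == "log") " (log scale)" else ""))
  } else {
    cat("  singular fit: group-mean fallback\n")
  }
  cat("  group means at reference:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

#' @export
summary.mass_adjust <- function(object, ...) {
  cat(sprintf("Residual size adjustment to reference %g (%s link)\n",
              object$ref, object$link))
  if (!is.null(object$fit)) print(summary(object$fit))
  cat("\nAdjusted group means at reference:\n")
  print(object$group_means)
  invisible(object)
}

#' @export
coef.mass_adjust <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::coef(object$fit)
}

#' @export
fitted.mass_adjust <- function(object, ...) {
  if (is.null(object$fit)) return(object$adjusted)
  f <- stats::predict(object$fit)
  if (object$link == "log") exp(f) else unname(f)
}

#' @export
residuals.mass_adjust <- function(object, ...) {
  object$response - fitted(object)
}

#' Predict from a mass-adjustment model
#'
#' Model predictions on the response scale at new covariate (and group)
#' values; defaults to the reference size for each fitted individual.
#'
#' @param object a [mass_adjust()] fit.
#' @param covariate new covariate values.
#' @param groups new group labels (required when the model has groups).
#' @param ... unused.
#' @return Predicted responses.
#' @export
predict.mass_adjust <- function(object, covariate = NULL, groups = NULL, ...) {
  if (is.null(object$fit)) {
    stop("singular fallback fit has no prediction model")
  }
  if (is.null(covariate)) covariate <- rep(object$ref, length(object$response))
  nd <- data.frame(.x = as.numeric(covariate))
  if (!is.null(object$groups)) {
    if (is.null(groups)) {
      if (length(covariate) == length(object$response)) groups <- object$groups
      else stop("groups must be supplied for a grouped model")
    }
    nd$.g <- factor(groups, levels = levels(object$groups))
  }
  p <- stats::predict(object$fit, newdata = nd)
  if (object$link == "log") exp(p) else unname(p)
}

#' @export
plot.mass_adjust <- function(x, ...) {
  grp <- if (is.null(x$groups)) factor(rep("all", length(x$response))) else x$groups
  cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")[as.integer(grp)]
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$covariate, x$response, col = cols, pch = 16,
                 xlab = "covariate", ylab = "observed", main = "raw", ...)
  graphics::plot(x$covariate, x$adjusted, col = cols, pch = 16,
                 xlab = "covariate", ylab = "adjusted",
                 main = sprintf("adjusted to ref = %g", x$ref), ...)
  graphics::abline(h = x$group_means, lty = 3)
  invisible(x)
}

#' Size-adjusted somatic index
#'
#' Organ mass as a percentage of body size after residual adjustment to a
#' common size: an `organ ~ size (+ group)` linear model is fitted, each fish's
#' residual is added to its group's prediction at `ref_size`, and the adjusted
#' organ mass is divided by `ref_size` and multiplied by 100. Use body mass as
#' the size (same units as organ mass) for mass-based indices, or length for
#' length-based ones (e.g. intestine length against a reference standard
#' length).
#'
#' @param organ_mass per-fish organ mass (or length), numeric.
#' @param body_size per-fish body mass or length, same units as `ref_size`.
#' @param groups optional treatment labels.
#' @param ref_size common reference size.
#' @param link passed to [mass_adjust()].
#' @return An object of class `somatic_index`: per-fish `si` (%), adjusted
#'   organ masses, group means, and the underlying [mass_adjust()] fit.
#' @export
somatic_index <- function(organ_mass, body_size, groups = NULL, ref_size,
                          link = c("identity", "log")) {
  if (any(organ_mass < 0)) stop("organ masses must be non-negative")
  if (any(body_size <= 0)) stop("body sizes must be positive")
  fit <- mass_adjust(organ_mass, body_size, groups = groups, ref = ref_size,
                     link = link)
  si <- 100 * adjusted(fit) / ref_size
  grp <- if (is.null(groups)) factor(rep("all", length(si))) else factor(groups)
  structure(list(si = si, adjusted_organ = adjusted(fit),
                 group_means = c(tapply(si, grp, mean)), ref_size = ref_size,
                 fit = fit),
            class = "somatic_index")
}

#' @export
print.somatic_index <- function(x, ...) {
  cat(sprintf("<somatic_index> %d fish, reference size %g\n",
              length(x$si), x$ref_size))
  cat("  group means (%):\n")
  print(round(x$group_means, 4))
  invisible(x)
}
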