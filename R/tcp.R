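# Logit tumor control probability model on mean absorbed dose.

#' Logit TCP model
#'
#' Tumor control probability as a logistic function of mean absorbed dose:
#' `TCP(D) = 1 / (1 + exp(-(D - midpoint) / slope))`. The default parameters
#' are a documented placeholder pair shaped like published Y-90 lesion
#' dose-response fits (TCP = 0.5 near 200 Gy, rising over roughly 100-400 Gy);
#' they are NOT coefficients from any specific study and should be replaced
#' with an institutional fit for real planning.
#'
#' @param midpoint_dose Dose in Gy at which TCP = 0.5.
#' @param slope Logit scale parameter in Gy, positive; smaller is steeper.
#' @return Object of class `tcp_model`.
#' @export
tcp_model <- function(midpoint_dose = 200, slope = 50) {
  if (!is.numeric(midpoint_dose) || midpoint_dose <= 0) {
    stop("midpoint_dose must be positive", call. = FALSE)
  }
  if (!is.numeric(slope) || slope <= 0) {
    stop("slope must be positive", call. = FALSE)
  }
  structure(list(midpoint_dose = midpoint_dose, slope = slope),
            class = "tcp_model")
}

#' @export
print.tcp_model <- function(x, ...) {
  cat(sprintf("Logit TCP model: midpoint %.1f Gy, slope %.1f Gy\n",
              x$midpoint_dose, x$slope))
  invisible(x)
}

#' Tumor control probability at a dose
#'
#' @param dose Mean absorbed dose in Gy (vectorized), >= 0.
#' @param model A [tcp_model()].
#' @return Probabilities in (0, 1).
#' @export
tcp <- function(dose, model = tcp_model()) {
  stopifnot(inherits(model, "tcp_model"))
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  stats::plogis((dose - model$midpoint_dose) / model$slope)
}

#' Fit a logit TCP model to binary response data
#'
#' Maximum-likelihood logistic regression of control outcome on mean dose
#' (via [stats::glm()]), reparameterized to midpoint/slope form. Intended for
#' parameter-recovery checks of the curve machinery; clinical fits need
#' follow-up-time handling beyond this scope.
#'
#' @param doses Mean absorbed doses, Gy.
#' @param responses Binary outcomes (0/1 or logical), 1 = controlled.
#' @return A [tcp_model()].
#' @export
fit_tcp <- function(doses, responses) {
  responses <- as.numeric(responses)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (length(doses) < 10) {
    stop("need at least 10 observations to fit a TCP curve", call. = FALSE)
  }
  if (!all(responses %in% c(0, 1))) {
    stop("responses must be binary (0/1)", call. = FALSE)
  }
  if (length(unique(responses)) < 2) {
    stop("both outcome classes must be present to fit a TCP curve",
         call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm(responses ~ doses, family = stats::binomial("logit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("complete separation: dose perfectly predicts outcome; cannot fit",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (fit$deviance < 1e-6) {
    stop("complete separation: dose perfectly predicts outcome; cannot fit",
         call. = FALSE)
  }
  b <- stats::coef(fit)
  if (!all(is.finite(b)) || b[2] <= 0) {
    stop(sprintf("fitted dose coefficient is %s; TCP must increase with dose",
                 format(b[2])), call. = FALSE)
  }
  tcp_model(midpoint_dose = unname(-b[1] / b[2]), slope = unname(1 / b[2]))
}
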