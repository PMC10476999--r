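#' Hybrid loss configuration
#'
#' Bundles the two loss components and their mixing coefficients:
#' `L_hybrid = alpha1 * L_WP + alpha2 * L_HF`. Both coefficients default to
#' 1; at least one must be positive.
#'
#' @param alpha1 non-negative weight of the patch loss component.
#' @param alpha2 non-negative weight of the high-frequency component.
#' @param weight_config a [weight_config()] for the patch loss.
#' @param r0,filter_kind high-pass mask parameters (see
#'   [make_highpass_mask()]).
#' @param hf_distance `"l1"` (default) or `"l2"` for the frequency term.
#' @return an object of class `hybrid_config`.
#' @export
hybrid_config <- function(alpha1 = 1, alpha2 = 1,
                          weight_config = ldctloss::weight_config(),
                          r0 = 0.1, filter_kind = "ideal",
                          hf_distance = "l1") {
  if (alpha1 < 0 || alpha2 < 0) stop("alpha1 and alpha2 must be non-negative")
  if (alpha1 + alpha2 <= 0) stop("at least one of alpha1, alpha2 must be positive")
  if (!inherits(weight_config, "weight_config"))
    stop("`weight_config` must be a weight_config object")
  structure(list(alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
                 weight_config = weight_config, r0 = r0,
                 filter_kind = match.arg(filter_kind, c("ideal", "gaussian")),
                 hf_distance = match.arg(hf_distance, c("l1", "l2"))),
            class = "hybrid_config")
}

#' Hybrid patch + frequency loss
#'
#' Evaluates the full training loss
#' `alpha1 * WPLoss + alpha2 * HFLoss` for one image pair (see [wp_loss()]
#' and [hf_loss()]). Both components are positively homogeneous of degree 1
#' in the image pair and the patch weights are scale invariant, so
#' `hybrid(a x, a y) = a * hybrid(x, y)` for `a > 0`. During training the
#' patch weights and the frequency mask are held constant: the loss is
#' differentiable in the generated pixels except on the measure-zero tie
#' set of the absolute values (where the subgradient 0 is used).
#'
#' @param generated,target matrices or `ct_image`s of identical shape, in
#'   the same value domain (losses are conventionally computed on
#'   NORMALIZED images during training).
#' @param config a [hybrid_config()].
#' @return an object of class `loss_report`: list with `wp_loss`,
#'   `hf_loss`, `hybrid_loss`, `alpha1`, `alpha2` and the per-patch
#'   diagnostics `patch_grid`.
#' @export
hybrid_loss <- function(generated, target, config = hybrid_config()) {
  if (!inherits(config, "hybrid_config"))
    stop("`config` must be a hybrid_config object")
  wp <- wp_loss(generated, target, config$weight_config, detail = TRUE)
  hf <- hf_loss(generated, target, r0 = config$r0, kind = config$filter_kind,
                distance = config$hf_distance)
  structure(list(wp_loss = wp$loss, hf_loss = hf,
                 hybrid_loss = config$alpha1 * wp$loss + config$alpha2 * hf,
                 alpha1 = config$alpha1, alpha2 = config$alpha2,
                 patch_grid = wp$patch_grid),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report wp=%.6g hf=%.6g hybrid=%.6g (alpha1=%g, alpha2=%g)>\n",
              x$wp_loss, x$hf_loss, x$hybrid_loss, x$alpha1, x$alpha2))
  invisible(x)
}

#' @rdname hybrid_loss
#' @param report a `loss_report`.
#' @return `loss_report_json()` returns a JSON string of the scalar losses
#'   and per-patch diagnostics, for structured logging.
#' @export
loss_report_json <- function(report) {
  if (!inherits(report, "loss_report")) stop("`report` must be a loss_report")
  jsonlite::toJSON(unclass(report), dataframe = "columns", auto_unbox = TRUE,
                   digits = NA)
}

#' Gradient of the hybrid loss with respect to the generated image
#'
#' Analytic gradient combining [wp_loss_grad()] and [hf_loss_grad()] with
#' the configured mixing coefficients, with patch weights and the frequency
#' mask treated as constants.
#'
#' @inheritParams hybrid_loss
#' @return a matrix of the same shape as the inputs.
#' @export
hybrid_loss_grad <- function(generated, target, config = hybrid_config()) {
  g <- .as_pixels(generated); t <- .as_pixels(target)
  grad <- matrix(0, nrow(g), ncol(g))
  if (config$alpha1 > 0)
    grad <- grad + config$alpha1 * wp_loss_grad(g, t, config$weight_config)
  if (config$alpha2 > 0)
    grad <- grad + config$alpha2 *
      hf_loss_grad(g, t, r0 = config$r0, kind = config$filter_kind,
                   distance = config$hf_distance)
  grad
}
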